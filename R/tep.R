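# TMS-evoked potential (TEP) analysis: epoch averaging, component
# time-of-interest amplitudes, and pre/post x group contrasts.

#' Canonical TEP component definitions
#'
#' The five canonical components with their polarities and default time
#' windows of interest (TOIs, ms post pulse): N45 \[35, 55\], P60 \[55, 70\],
#' N75 \[70, 90\], N100 \[90, 130\], P180 \[150, 250\]. The N75 window is
#' anchored on the 60-90 ms range conventionally attributed to that
#' component; all windows are user-overridable.
#'
#' @return data frame (name, polarity, lo_ms, hi_ms)
#' @export
tep_components <- function() {
  data.frame(
    name = c("N45", "P60", "N75", "N100", "P180"),
    polarity = c(-1, 1, -1, -1, 1),
    lo_ms = c(35, 55, 70, 90, 150),
    hi_ms = c(55, 70, 90, 130, 250),
    stringsAsFactors = FALSE
  )
}

#' Average TEP waveform
#'
#' Pointwise mean and standard error across pulse epochs, per channel.
#'
#' @param epochs an `epoch_set` with condition `"tep"`
#' @param min_epochs minimum epoch count (default 10)
#' @return object of class `tep_waveform`: `mean` and `se` (channels x time),
#'   `times` (s), `n_epochs`, `excluded_samples`
#' @export
average_tep <- function(epochs, min_epochs = 10) {
  if (epochs$condition != "tep") stop("average_tep() expects TEP epochs")
  ne <- n_epochs(epochs)
  if (ne < min_epochs) stop("too few epochs: ", ne, " < ", min_epochs)
  d <- epochs$data
  mu <- rowMeans(d, dims = 2)
  se <- sqrt(pmax(rowMeans(d^2, dims = 2) - mu^2, 0) / (ne - 1))
  structure(list(mean = mu, se = se, times = epochs$times, n_epochs = ne,
                 excluded_samples = epochs$excluded_samples,
                 subject = epochs$subject, session = epochs$session),
            class = "tep_waveform")
}

#' @export
print.tep_waveform <- function(x, ...) {
  cat(sprintf("<tep_waveform> %d ch x %d samples, %d epochs\n",
              nrow(x$mean), ncol(x$mean), x$n_epochs))
  invisible(x)
}

#' TEP component TOI amplitudes
#'
#' Mean amplitude of the averaged waveform over each component's time window
#' of interest at one channel, excluding artifact-flagged samples. With
#' `mode = "peak"` the most extreme value in the component's polarity is
#' returned instead.
#'
#' @param waveform a `tep_waveform`
#' @param components component table (default [tep_components()])
#' @param channel channel label (default F4, under the stimulation target)
#' @param mode `"mean"` (default) or `"peak"`
#' @return named numeric vector of amplitudes (uV) per component
#' @export
component_amplitude <- function(waveform, components = tep_components(),
                                channel = "F4", mode = c("mean", "peak")) {
  mode <- match.arg(mode)
  ch <- match(channel, rownames(waveform$mean))
  if (is.na(ch)) stop("channel not present: ", channel)
  t_ms <- waveform$times * 1000
  excl <- waveform$excluded_samples
  if (is.null(excl)) excl <- rep(FALSE, length(t_ms))
  out <- numeric(nrow(components))
  for (i in seq_len(nrow(components))) {
    sel <- t_ms >= components$lo_ms[i] & t_ms <= components$hi_ms[i] & !excl
    if (!any(sel)) stop("TOI of ", components$name[i],
                        " lies entirely inside the artifact window")
    v <- waveform$mean[ch, sel]
    out[i] <- if (mode == "mean") mean(v) else {
      v[which.max(components$polarity[i] * v)]
    }
  }
  stats::setNames(out, components$name)
}

#' Pre/post x group TEP contrast for one TOI
#'
#' Subject-level change scores (post minus pre TOI amplitude, per channel)
#' are contrasted between two groups with an independent-t cluster
#' permutation test, or screened across all groups with a one-way F variant.
#' Subjects without both sessions are dropped with a warning.
#'
#' @param amp_pre,amp_post subjects x channels matrices of TOI amplitudes,
#'   with subject row names
#' @param groups named vector (or vector aligned to `amp_pre` rows) of group
#'   labels
#' @param montage a `montage` object
#' @param contrast two group labels for the pairwise contrast, or `"anova"`
#'   for the across-group interaction screen
#' @param n_perm,seed,alpha_cf permutation settings
#' @return a `cluster_result` on the change scores
#' @export
tep_contrast <- function(amp_pre, amp_post, groups, montage,
                         contrast = c("Real", "Sham"), n_perm = 1000,
                         seed = 1, alpha_cf = 0.05) {
  common <- intersect(rownames(amp_pre), rownames(amp_post))
  dropped <- setdiff(union(rownames(amp_pre), rownames(amp_post)), common)
  if (length(dropped) > 0)
    warning("dropping unpaired subject(s): ", paste(dropped, collapse = ", "))
  if (is.null(names(groups))) names(groups) <- rownames(amp_pre)
  change <- amp_post[common, , drop = FALSE] - amp_pre[common, , drop = FALSE]
  g <- groups[common]
  ord <- montage$channels$label
  change <- change[, ord, drop = FALSE]
  if (identical(contrast, "anova")) {
    cluster_permutation(change, "anova", montage$adjacency, groups = g,
                        alpha_cf = alpha_cf, n_perm = n_perm, seed = seed)
  } else {
    keep <- g %in% contrast
    cluster_permutation(change[keep, , drop = FALSE], "two-group",
                        montage$adjacency, groups = factor(g[keep], levels = contrast),
                        alpha_cf = alpha_cf, n_perm = n_perm, seed = seed)
  }
}

#' TOI amplitude table for a cohort
#'
#' Builds subjects x channels amplitude matrices for one component from
#' per-subject averaged waveforms.
#'
#' @param waveforms named list of `tep_waveform` objects (one per subject)
#' @param component one row of [tep_components()]
#' @param channels channel labels (default all channels of the first
#'   waveform)
#' @param mode amplitude mode, see [component_amplitude()]
#' @return subjects x channels numeric matrix
#' @export
toi_amplitude_matrix <- function(waveforms, component,
                                 channels = rownames(waveforms[[1]]$mean),
                                 mode = "mean") {
  out <- matrix(NA_real_, length(waveforms), length(channels),
                dimnames = list(names(waveforms), channels))
  for (s in names(waveforms)) {
    for (ch in channels) {
      out[s, ch] <- component_amplitude(waveforms[[s]], component, ch, mode)
    }
  }
  out
}

#' Tidy export of an averaged TEP waveform
#' @param waveform a `tep_waveform`
#' @return data frame (channel, time_ms, mean, se)
#' @export
tep_waveform_table <- function(waveform) {
  data.frame(
    channel = rep(rownames(waveform$mean), times = ncol(waveform$mean)),
    time_ms = rep(waveform$times * 1000, each = nrow(waveform$mean)),
    mean = as.vector(waveform$mean),
    se = as.vector(waveform$se)
  )
}
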