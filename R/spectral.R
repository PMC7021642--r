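# Spectral estimation and the treatment biomarker: Welch band powers, the
# low-gamma/alpha power-ratio marker, whole-scalp correlation maps,
# inter-hemispheric balance models, ITI power dynamics, and rest-vs-treatment
# correlations.

#' Frequency band definitions
#'
#' Default bands: Alpha 8-14.5 Hz (a stable, trait-like activity), LowGamma
#' 30-40 Hz (the transient cortical response to stimulation trains), and Beta
#' 15-29.5 Hz for generic band contrasts. Band edges are inclusive.
#'
#' @param name band name
#' @param lo,hi band edges in Hz (0 < lo < hi)
#' @return data frame with columns name, lo, hi
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  data.frame(name = name, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  rbind(band_definition("Alpha", 8, 14.5),
        band_definition("LowGamma", 30, 40),
        band_definition("Beta", 15, 29.5))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: each epoch is split into Hann-windowed
#' segments of `seg_len` seconds with the given overlap, one-sided
#' periodograms are density-scaled (uV^2/Hz) and averaged across segments and
#' epochs. Frequency resolution is 1/seg_len.
#'
#' @param epochs an `epoch_set`
#' @param seg_len segment length in seconds (default 1; must not exceed the
#'   epoch length)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return object of class `psd_set`: list with `freqs` (Hz) and `power`
#'   (channels x frequencies matrix)
#' @export
welch_psd <- function(epochs, seg_len = 1, overlap = 0.5) {
  fs <- epochs$sfreq
  d <- epochs$data
  nseg <- round(seg_len * fs)
  nt <- dim(d)[2]
  if (nseg > nt) stop("seg_len exceeds the epoch length")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, nt - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / nseg)  # periodic Hann
  scale <- 2 / (fs * sum(w^2))
  nfreq <- nseg %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / nseg
  acc <- matrix(0, dim(d)[1], nfreq)
  count <- 0
  for (e in seq_len(dim(d)[3])) {
    for (s in starts) {
      seg <- matrix(d[, s:(s + nseg - 1), e], nrow = dim(d)[1]) *
        rep(w, each = dim(d)[1])
      ft <- stats::mvfft(t(seg))
      pxx <- t(Mod(ft[seq_len(nfreq), , drop = FALSE])^2) * scale
      pxx[, 1] <- pxx[, 1] / 2                       # DC not doubled
      if (nseg %% 2 == 0) pxx[, nfreq] <- pxx[, nfreq] / 2  # Nyquist
      acc <- acc + pxx
      count <- count + 1
    }
  }
  if (count == 0) stop("no epochs to average")
  power <- acc / count
  rownames(power) <- dimnames(d)[[1]]
  structure(list(freqs = freqs, power = power, sfreq = fs,
                 condition = epochs$condition, reference = epochs$reference,
                 subject = epochs$subject),
            class = "psd_set")
}

#' Absolute band power
#'
#' Integrates the PSD over `[lo, hi]` (edges inclusive) by the trapezoid rule
#' on the frequency grid, linearly interpolating the PSD at band edges that
#' fall between grid points.
#'
#' @param psd a `psd_set`
#' @param band one row of a band definition table (`name`, `lo`, `hi`)
#' @return named numeric vector of band power per channel (uV^2)
#' @export
band_power <- function(psd, band) {
  lo <- band$lo; hi <- band$hi
  f <- psd$freqs
  if (hi > max(f) || lo < min(f)) stop("band extends beyond the frequency grid")
  grid <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  if (length(grid) < 2) stop("band contains no frequency interval")
  vals <- apply(psd$power, 1, function(p) stats::approx(f, p, xout = grid)$y)
  dx <- diff(grid)
  colSums((vals[-1, , drop = FALSE] + vals[-length(grid), , drop = FALSE]) / 2 * dx)
}

#' Band power table over subjects
#' @param psd_list named list of `psd_set` objects (one per subject)
#' @param bands band definition table (default [default_bands()])
#' @return tidy data frame (subject, channel, band, power)
#' @export
band_power_table <- function(psd_list, bands = default_bands()) {
  out <- list()
  for (s in names(psd_list)) {
    for (b in seq_len(nrow(bands))) {
      bp <- band_power(psd_list[[s]], bands[b, ])
      out[[length(out) + 1]] <- data.frame(
        subject = s, channel = names(bp), band = bands$name[b],
        power = unname(bp), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' The low-gamma/alpha treatment biomarker
#'
#' Elementwise ratio of low-gamma to alpha band power, computed from the
#' first post-train ITI segments of the first treatment session. The ratio
#' direction (gamma over alpha) follows the sign structure of the component
#' correlations with clinical improvement (gamma positive, alpha negative);
#' `direction = "alpha_over_gamma"` inverts it.
#'
#' @param power_alpha,power_gamma subjects x channels matrices of absolute
#'   band power, aligned on both axes
#' @param direction `"gamma_over_alpha"` (default) or `"alpha_over_gamma"`
#' @return subjects x channels marker matrix
#' @export
compute_marker <- function(power_alpha, power_gamma,
                           direction = c("gamma_over_alpha", "alpha_over_gamma")) {
  direction <- match.arg(direction)
  if (!identical(dim(power_alpha), dim(power_gamma)))
    stop("power tables are not aligned")
  if (any(power_alpha <= 0)) stop("zero or negative alpha power: degenerate input")
  m <- if (direction == "gamma_over_alpha") power_gamma / power_alpha
       else power_alpha / power_gamma
  dimnames(m) <- dimnames(power_alpha)
  m
}

#' Whole-scalp marker-outcome correlation map
#'
#' Per-channel Pearson correlation between the (log-transformed) marker and
#' per-subject clinical improvement, cluster-corrected by Monte-Carlo
#' permutation with the r statistic.
#'
#' @param marker subjects x channels marker matrix
#' @param improvement per-subject improvement scores, aligned to marker rows
#' @param montage a `montage` object
#' @param n_perm,seed,alpha_cf permutation settings
#' @param log_transform correlate log marker values (default TRUE; ratio
#'   distributions are right-skewed)
#' @return a `cluster_result` (see [cluster_permutation()])
#' @export
marker_outcome_map <- function(marker, improvement, montage, n_perm = 1000,
                               seed = 1, alpha_cf = 0.05, log_transform = TRUE) {
  if (nrow(marker) < 5) stop("need at least 5 subjects")
  if (length(improvement) != nrow(marker))
    stop("improvement is not aligned to marker rows")
  if (stats::sd(improvement) == 0) stop("improvement has zero variance")
  x <- if (log_transform) log(marker) else marker
  x <- x[, montage$channels$label, drop = FALSE]
  cluster_permutation(x, "correlation", montage$adjacency,
                      covariate = improvement, alpha_cf = alpha_cf,
                      n_perm = n_perm, seed = seed)
}

#' Inter-hemispheric balance model
#'
#' For every lateral channel, the partial correlation between the marker (or
#' band power) at that channel and clinical improvement, controlling for the
#' value at the homologous contralateral channel; two-tailed parametric
#' p-values (t transform, df = n - 3) and Benjamini-Hochberg q-values over
#' the 54 lateral channels. Midline channels are reported as not applicable.
#'
#' @param values subjects x channels matrix (marker or band power)
#' @param improvement per-subject improvement scores
#' @param montage a `montage` object
#' @param q FDR level (default 0.05)
#' @param log_transform use log values (default TRUE)
#' @param channels optional subset of lateral channels (FDR is then computed
#'   over that subset)
#' @return data frame (channel, pair, r_partial, t, df, p, q, significant)
#' @export
interhemispheric_balance <- function(values, improvement, montage, q = 0.05,
                                     log_transform = TRUE, channels = NULL) {
  if (nrow(values) < 6) stop("need at least 6 subjects for partial correlations")
  x <- if (log_transform) log(values) else values
  lat <- lateral_channels(montage)
  if (!is.null(channels)) {
    if (!all(channels %in% lat)) stop("channels of interest must be lateral channels")
    lat <- channels
  }
  rows <- lapply(lat, function(ch) {
    pr <- homologous_pair(ch, montage)
    if (!(ch %in% colnames(x)) || !(pr %in% colnames(x))) {
      warning("missing data for channel ", ch, " or its pair; skipped")
      return(NULL)
    }
    pc <- partial_correlation(x[, ch], improvement, x[, pr])
    data.frame(channel = ch, pair = pr, r_partial = pc$r, t = pc$t,
               df = pc$df, p = pc$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  fdr <- bh_fdr(tab$p, q)
  tab$q <- fdr$q_values
  tab$significant <- fdr$rejected
  mid <- montage$channels$label[montage$channels$is_midline]
  if (is.null(channels) && length(mid) > 0) {
    tab <- rbind(tab, data.frame(channel = mid, pair = NA_character_,
                                 r_partial = NA_real_, t = NA_real_,
                                 df = NA_integer_, p = NA_real_, q = NA_real_,
                                 significant = NA))
  }
  rownames(tab) <- NULL
  tab
}

#' Resting-state alpha inter-hemispheric balance
#'
#' The inter-hemispheric balance model applied to resting-state alpha power,
#' restricted to the prefrontal channels most implicated by the treatment
#' marker (FC4, FC2, F4, F2 and their left homologues by default), with FDR
#' over that channel set.
#'
#' @param rest_alpha_power subjects x channels matrix of resting alpha power
#' @param improvement per-subject improvement scores
#' @param montage a `montage` object
#' @param channels_of_interest channel subset (default the 8 prefrontal
#'   channels)
#' @param q FDR level
#' @param log_transform use log power (default TRUE)
#' @return data frame as in [interhemispheric_balance()]
#' @export
resting_alpha_balance <- function(rest_alpha_power, improvement, montage,
                                  channels_of_interest = c("FC4", "FC2", "F4", "F2",
                                                           "FC3", "FC1", "F3", "F1"),
                                  q = 0.05, log_transform = TRUE) {
  interhemispheric_balance(rest_alpha_power, improvement, montage, q = q,
                           log_transform = log_transform,
                           channels = channels_of_interest)
}

#' ITI band-power dynamics
#'
#' Per-subject, per-band power in every ITI segment expressed as a ratio to
#' the first post-train segment, with group means/SE per segment and a
#' within-subject ANOVA (factors: segment 2..k and band) on the normalized
#' power of the later segments.
#'
#' @param power_table data frame (subject, band, segment, power), e.g. built
#'   with [segment_band_power()] at a channel of interest
#' @param anova_segments segments entering the repeated-measures ANOVA
#'   (default 2..7, the later segments of a standard 20 s interval; the
#'   segment-1 ratio is 1 by construction and carries no information)
#' @return list with `ratios` (subject, band, segment, ratio), `summary`
#'   (band, segment, mean, se), and `anova` (data frame with the Segment,
#'   Band and Segment:Band effects)
#' @export
iti_dynamics <- function(power_table, anova_segments = 2:7) {
  stopifnot(all(c("subject", "band", "segment", "power") %in% names(power_table)))
  if (length(unique(power_table$segment)) < 2) stop("need at least 2 segments")
  parts <- split(power_table, list(power_table$subject, power_table$band), drop = TRUE)
  rows <- lapply(parts, function(df) {
    base <- df$power[df$segment == 1]
    if (length(base) != 1) {
      warning("subject ", df$subject[1], " lacks a unique segment-1 power; dropped")
      return(NULL)
    }
    data.frame(subject = df$subject, band = df$band, segment = df$segment,
               ratio = df$power / base, stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(ratios) <- NULL
  agg <- stats::aggregate(ratio ~ band + segment, ratios, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v))))
  summary_tab <- data.frame(band = agg$band, segment = agg$segment,
                            mean = agg$ratio[, "mean"], se = agg$ratio[, "se"])

  later <- ratios[ratios$segment %in% anova_segments, ]
  later$segment <- factor(later$segment)
  later$band <- factor(later$band)
  later$subject <- factor(later$subject)
  fit <- stats::aov(ratio ~ segment * band +
                      Error(subject / (segment * band)), data = later)
  anova_tab <- .extract_rm_anova(fit)
  list(ratios = ratios, summary = summary_tab, anova = anova_tab)
}

.extract_rm_anova <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    res <- eff == "Residuals"
    if (!any(res) || all(res)) next
    df2 <- tab[res, "Df"]; ms2 <- tab[res, "Mean Sq"]
    for (i in which(!res)) {
      fv <- tab[i, "Mean Sq"] / ms2
      rows[[length(rows) + 1]] <- data.frame(
        effect = eff[i], df1 = tab[i, "Df"], df2 = df2,
        f = fv, p = stats::pf(fv, tab[i, "Df"], df2, lower.tail = FALSE),
        eta_p_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + tab[res, "Sum Sq"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment band power at one channel
#'
#' Convenience builder for [iti_dynamics()]: Welch band power per ITI segment
#' for a single subject's ITI epochs at a channel of interest.
#'
#' @param epochs an `epoch_set` with condition `"iti"`
#' @param bands band definition table
#' @param channel channel label (default FC4, under the stimulation target)
#' @param subject subject identifier for the output table
#' @return data frame (subject, band, segment, power)
#' @export
segment_band_power <- function(epochs, bands = default_bands()[1:2, ],
                               channel = "FC4", subject = epochs$subject) {
  segs <- sort(unique(epochs$segment_index))
  out <- list()
  for (s in segs) {
    sub <- select_epochs(epochs, epochs$segment_index == s)
    psd <- welch_psd(sub)
    for (b in seq_len(nrow(bands))) {
      bp <- band_power(psd, bands[b, ])
      out[[length(out) + 1]] <- data.frame(
        subject = subject, band = bands$name[b], segment = s,
        power = unname(bp[channel]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rest vs treatment band-power correlation map
#'
#' Across-subject Pearson correlation, per channel, between resting-state
#' band power and first-ITI-segment band power of the first treatment
#' session.
#'
#' @param rest_power,iti_power subjects x channels matrices, aligned
#' @param log_transform correlate log power (default TRUE)
#' @return named numeric vector of per-channel r
#' @export
rest_treatment_correlation <- function(rest_power, iti_power,
                                       log_transform = TRUE) {
  if (!identical(dim(rest_power), dim(iti_power)))
    stop("power tables are not aligned")
  if (nrow(rest_power) < 4) stop("need at least 4 subjects")
  a <- if (log_transform) log(rest_power) else rest_power
  b <- if (log_transform) log(iti_power) else iti_power
  r <- vapply(seq_len(ncol(a)), function(j) stats::cor(a[, j], b[, j]), numeric(1))
  stats::setNames(r, colnames(rest_power))
}
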