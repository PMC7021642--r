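# Preprocessing: raw recordings -> analysis-ready epochs. Covers ITI
# segmentation, resting/TEP epoching, artifact-window handling, and
# re-referencing (average reference and spherical-spline CSD).

#' Construct an epoch set
#'
#' The package's epoch container: a channels x samples x epochs array with
#' sampling rate, condition tag, per-epoch ITI segment index, and reference
#' bookkeeping (so re-referencing is never silently applied twice).
#'
#' @param data numeric array `[channel, sample, epoch]` in microvolts; the
#'   first dimension must carry channel dimnames
#' @param sfreq sampling rate in Hz
#' @param condition one of `"rest"`, `"iti"`, `"tep"`
#' @param segment_index integer vector (one per epoch) of ITI segment
#'   positions, 1 = first post-train segment; required iff condition = "iti"
#' @param reference `"raw"`, `"AVR"` or `"CSD"`
#' @param times per-sample time axis in seconds (TEP epochs: time relative to
#'   the pulse)
#' @param excluded_samples logical per-sample flags for samples excluded from
#'   amplitude statistics (e.g. the interpolated TMS artifact window)
#' @param subject,session identifiers carried through the pipeline
#' @return object of class `epoch_set`
#' @export
epoch_set <- function(data, sfreq, condition, segment_index = NULL,
                      reference = "raw", times = NULL,
                      excluded_samples = NULL, subject = NA, session = NA) {
  stopifnot(length(dim(data)) == 3, sfreq > 0)
  condition <- match.arg(condition, c("rest", "iti", "tep"))
  if (condition == "iti") {
    if (is.null(segment_index) || length(segment_index) != dim(data)[3])
      stop("iti epochs need one segment_index per epoch")
  } else if (!is.null(segment_index)) {
    stop("segment_index is only meaningful for condition = 'iti'")
  }
  structure(list(data = data, sfreq = sfreq, condition = condition,
                 segment_index = segment_index, reference = reference,
                 times = times, excluded_samples = excluded_samples,
                 subject = subject, session = session),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d ch x %d samples x %d epochs, %g Hz, condition=%s, reference=%s\n",
              d[1], d[2], d[3], x$sfreq, x$condition, x$reference))
  invisible(x)
}

#' Number of epochs
#' @param epochs an `epoch_set`
#' @export
n_epochs <- function(epochs) dim(epochs$data)[3]

#' Select epochs by index
#' @param epochs an `epoch_set`
#' @param idx integer or logical epoch index
#' @return an `epoch_set` with the selected epochs
#' @export
select_epochs <- function(epochs, idx) {
  out <- epochs
  out$data <- epochs$data[, , idx, drop = FALSE]
  if (!is.null(epochs$segment_index)) out$segment_index <- epochs$segment_index[idx]
  out
}

.train_bounds <- function(recording, train_events) {
  if (is.null(train_events)) {
    ev <- recording$events
    on <- ev$onset[ev$type == "train_onset"]
    off <- ev$onset[ev$type == "train_offset"]
  } else {
    on <- train_events$onset
    off <- train_events$offset
  }
  if (length(on) != length(off) || length(on) == 0)
    stop("recording carries no complete train events")
  if (is.unsorted(on, strictly = TRUE) || is.unsorted(off, strictly = TRUE) ||
      any(off <= on) || any(utils::head(off, -1) > utils::tail(on, -1)))
    stop("train events must be sorted and non-overlapping")
  dur <- nrow_samples(recording) / recording$sfreq
  if (any(on < 0) || any(off > dur))
    stop("train events fall outside the recording")
  list(onset = on, offset = off)
}

nrow_samples <- function(recording) ncol(recording$data)

#' Extract inter-train-interval epochs
#'
#' For each inter-train interval (train end to next train onset; the last
#' interval is bounded by the end of the recording), consecutive
#' non-overlapping epochs of `epoch_len` seconds are cut from the window
#' starting `start_gap` s after the train ends (to clear stimulation
#' artifacts) and ending `end_gap` s before the next train starts (to avoid
#' anticipation effects; no end gap applies to the final interval). Epochs
#' overlapping artifact-flagged samples are dropped. With the default 20 s
#' gap this yields 7 two-second segments per interval, indexed 1..7 in
#' temporal order.
#'
#' @param recording an `eeg_recording` (see [synthesize_treatment_eeg()])
#' @param train_events optional data frame with `onset`/`offset` columns
#'   (seconds); defaults to the recording's annotated train events
#' @param epoch_len,start_gap,end_gap segmentation windows in seconds
#' @return an `epoch_set` with condition `"iti"` and per-epoch `segment_index`
#' @export
extract_iti_epochs <- function(recording, train_events = NULL, epoch_len = 2,
                               start_gap = 1, end_gap = 5) {
  tb <- .train_bounds(recording, train_events)
  fs <- recording$sfreq
  n_samp <- ncol(recording$data)
  rec_end <- n_samp / fs
  flags <- recording$flags
  dat <- list(); seg <- integer(0)
  for (i in seq_along(tb$offset)) {
    w0 <- tb$offset[i] + start_gap
    w1 <- if (i < length(tb$onset)) tb$onset[i + 1] - end_gap else rec_end
    k <- max(0, floor((w1 - w0) / epoch_len + 1e-9))
    if (k == 0) next
    for (j in seq_len(k)) {
      a <- round((w0 + (j - 1) * epoch_len) * fs) + 1
      b <- a + round(epoch_len * fs) - 1
      if (b > n_samp) next
      if (!is.null(flags) && any(flags[a:b])) next
      dat[[length(dat) + 1]] <- recording$data[, a:b, drop = FALSE]
      seg <- c(seg, j)
    }
  }
  if (length(dat) == 0) {
    arr <- array(0, dim = c(nrow(recording$data), round(epoch_len * fs), 0),
                 dimnames = list(rownames(recording$data), NULL, NULL))
  } else {
    arr <- array(unlist(dat), dim = c(nrow(recording$data), ncol(dat[[1]]), length(dat)),
                 dimnames = list(rownames(recording$data), NULL, NULL))
  }
  epoch_set(arr, fs, "iti", segment_index = seg,
            subject = recording$subject, session = recording$session)
}

#' Keep only first post-train segments
#'
#' Restricts an ITI epoch set to the epochs covering seconds 1-3 after each
#' train (segment index 1), the window the treatment biomarker is computed
#' from.
#'
#' @param epochs an `epoch_set` with condition `"iti"`
#' @return an `epoch_set` containing only segment-1 epochs
#' @export
first_segment <- function(epochs) {
  if (!inherits(epochs, "epoch_set") || epochs$condition != "iti")
    stop("first_segment() expects iti epochs")
  select_epochs(epochs, epochs$segment_index == 1)
}

#' Cut fixed-length epochs from a resting recording
#' @param recording an `eeg_recording`
#' @param epoch_len epoch length in seconds
#' @return an `epoch_set` with condition `"rest"`
#' @export
extract_rest_epochs <- function(recording, epoch_len = 2) {
  fs <- recording$sfreq
  n_samp <- ncol(recording$data)
  step <- round(epoch_len * fs)
  k <- floor(n_samp / step)
  if (k == 0) stop("recording shorter than one epoch")
  keep <- list()
  for (j in seq_len(k)) {
    a <- (j - 1) * step + 1; b <- j * step
    if (!is.null(recording$flags) && any(recording$flags[a:b])) next
    keep[[length(keep) + 1]] <- recording$data[, a:b, drop = FALSE]
  }
  arr <- array(unlist(keep), dim = c(nrow(recording$data), step, length(keep)),
               dimnames = list(rownames(recording$data), NULL, NULL))
  epoch_set(arr, fs, "rest", subject = recording$subject,
            session = recording$session)
}

#' Reject epochs exceeding an amplitude threshold
#' @param epochs an `epoch_set`
#' @param threshold peak amplitude in microvolts (default 100)
#' @return an `epoch_set` without the offending epochs
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  peak <- apply(abs(epochs$data), 3, max)
  select_epochs(epochs, peak <= threshold)
}

#' Average reference
#'
#' Subtracts the instantaneous cross-channel mean from every sample, so each
#' sample's channel mean is zero.
#'
#' @param epochs an `epoch_set` with reference `"raw"`
#' @return the re-referenced `epoch_set` (reference `"AVR"`)
#' @export
apply_average_reference <- function(epochs) {
  if (epochs$reference == "CSD")
    stop("cannot average-reference CSD-transformed data")
  d <- epochs$data
  mu <- colMeans(d, dims = 1)            # sample x epoch means over channels
  out <- d - rep(mu, each = dim(d)[1])
  epochs$data <- array(out, dim = dim(d), dimnames = dimnames(d))
  epochs$reference <- "AVR"
  epochs
}

# ---- spherical-spline surface Laplacian (CSD) ----------------------------

.legendre_table <- function(x, n_terms) {
  # P_n(x) for n = 1..n_terms via the Bonnet recurrence, vectorized over x
  out <- matrix(0, length(x), n_terms)
  p0 <- rep(1, length(x)); p1 <- x
  out[, 1] <- p1
  for (n in 2:n_terms) {
    p2 <- ((2 * n - 1) * x * p1 - (n - 1) * p0) / n
    out[, n] <- p2
    p0 <- p1; p1 <- p2
  }
  out
}

#' Precompute the spherical-spline CSD transform for a montage
#'
#' Builds the G (interpolation) and H (Laplacian) matrices of the
#' spherical-spline surface Laplacian from the inter-electrode cosine
#' distances, with spline stiffness `m`, ridge regularization `lambda`, and a
#' truncated Legendre series.
#'
#' @param montage a `montage` object
#' @param m spline stiffness (default 4)
#' @param lambda regularization added to the diagonal of G (default 1e-5)
#' @param n_legendre number of Legendre terms (default 50)
#' @return list with the inverted spline system, used by [apply_csd()]
#' @export
csd_transform <- function(montage, m = 4, lambda = 1e-5, n_legendre = 50) {
  p <- montage_positions(montage)
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-12))
    stop("duplicate electrode positions make the spline system singular")
  n <- 1:n_legendre
  gw <- (2 * n + 1) / ((n * (n + 1))^m * 4 * pi)
  hw <- (2 * n + 1) / ((n * (n + 1))^(m - 1) * 4 * pi)
  P <- .legendre_table(as.vector(cosang), n_legendre)
  nc <- nrow(cosang)
  G <- matrix(P %*% gw, nc, nc)
  H <- matrix(P %*% hw, nc, nc)
  Gi <- solve(G + diag(lambda, nc))
  tc <- rowSums(Gi)
  list(Gi = Gi, H = H, tc = tc, sgi = sum(tc), m = m, lambda = lambda,
       channels = rownames(p))
}

#' Current source density (spherical-spline surface Laplacian)
#'
#' Transforms scalp potentials to an estimate of the current source density
#' at each electrode, de-emphasizing volume-conducted distant sources. The
#' output is reference-free: it is identical for raw and average-referenced
#' input, and a spatially constant potential maps to zero.
#'
#' @param epochs an `epoch_set` with reference `"raw"` or `"AVR"`
#' @param montage a `montage` object (channel order must match the data)
#' @param m,lambda,n_legendre spline parameters, see [csd_transform()]
#' @param transform optional precomputed result of [csd_transform()]
#' @return the transformed `epoch_set` (reference `"CSD"`)
#' @export
apply_csd <- function(epochs, montage, m = 4, lambda = 1e-5, n_legendre = 50,
                      transform = NULL) {
  if (epochs$reference == "CSD") stop("data is already CSD-transformed")
  if (is.null(transform)) transform <- csd_transform(montage, m, lambda, n_legendre)
  d <- epochs$data
  dm <- dim(d)
  if (dm[1] != length(transform$channels))
    stop("channel count does not match the montage")
  flat <- matrix(d, nrow = dm[1])
  cp <- transform$Gi %*% flat
  c0 <- colSums(cp) / transform$sgi
  coef <- cp - outer(transform$tc, c0)
  out <- transform$H %*% coef
  epochs$data <- array(out, dim = dm, dimnames = dimnames(d))
  epochs$reference <- "CSD"
  epochs
}

#' Extract TMS-evoked potential epochs
#'
#' Cuts one epoch per TMS pulse, linearly interpolates the samples inside the
#' pulse-artifact window (and marks them excluded from amplitude statistics),
#' and subtracts the per-channel baseline mean.
#'
#' @param recording an `eeg_recording` with `tms_pulse` events
#' @param pulse_events optional numeric vector of pulse times in seconds
#' @param window epoch window around the pulse, seconds
#' @param artifact_window window replaced by interpolation, seconds
#' @param baseline baseline window, seconds (must not overlap the artifact
#'   window)
#' @return an `epoch_set` with condition `"tep"`, a `times` axis, and
#'   `excluded_samples` flags over the artifact window
#' @export
extract_tep_epochs <- function(recording, pulse_events = NULL,
                               window = c(-0.5, 0.5),
                               artifact_window = c(-0.002, 0.010),
                               baseline = c(-0.2, -0.01)) {
  if (baseline[2] > artifact_window[1] && baseline[1] < artifact_window[2])
    stop("baseline window overlaps the artifact window")
  if (is.null(pulse_events)) {
    ev <- recording$events
    pulse_events <- ev$onset[ev$type == "tms_pulse"]
  }
  if (length(pulse_events) < 1) stop("no pulse events")
  fs <- recording$sfreq
  n_samp <- ncol(recording$data)
  times <- seq(window[1], window[2], by = 1 / fs)
  nt <- length(times)
  art <- times >= artifact_window[1] & times <= artifact_window[2]
  bas <- times >= baseline[1] & times <= baseline[2]
  a_lo <- min(which(art)) - 1; a_hi <- max(which(art)) + 1
  if (a_lo < 1 || a_hi > nt) stop("artifact window touches the epoch edge")

  eps <- list()
  for (t0 in pulse_events) {
    a <- round((t0 + window[1]) * fs) + 1
    b <- a + nt - 1
    if (a < 1 || b > n_samp) next
    e <- recording$data[, a:b, drop = FALSE]
    # excise the pulse artifact: linear interpolation between window edges
    w <- (which(art) - a_lo) / (a_hi - a_lo)
    e[, art] <- e[, a_lo] %o% (1 - w) + e[, a_hi] %o% w
    e <- e - rowMeans(e[, bas, drop = FALSE])
    eps[[length(eps) + 1]] <- e
  }
  arr <- array(unlist(eps), dim = c(nrow(recording$data), nt, length(eps)),
               dimnames = list(rownames(recording$data), NULL, NULL))
  epoch_set(arr, fs, "tep", times = times, excluded_samples = art,
            subject = recording$subject, session = recording$session)
}

#' Band-pass (and optional notch) filtering of a recording
#'
#' Zero-phase Butterworth band-pass, with an optional 50 Hz notch. Synthetic
#' recordings are generated in-band and do not need this; it exists for real
#' recordings entering the pipeline.
#'
#' @param recording an `eeg_recording`
#' @param l_freq,h_freq band edges in Hz
#' @param notch if TRUE, apply a 48-52 Hz band-stop
#' @return the filtered recording
#' @export
filter_recording <- function(recording, l_freq = 0.5, h_freq = 100,
                             notch = FALSE) {
  fs <- recording$sfreq
  bp <- signal::butter(4, c(l_freq, h_freq) / (fs / 2), type = "pass")
  d <- t(apply(recording$data, 1, function(x) signal::filtfilt(bp, x)))
  if (notch) {
    bs <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
    d <- t(apply(d, 1, function(x) signal::filtfilt(bs, x)))
  }
  dimnames(d) <- dimnames(recording$data)
  recording$data <- d
  recording
}
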