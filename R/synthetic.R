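# Synthetic rTMS-EEG cohorts with ground-truthed planted effects.
#
# The generator emulates the statistical structure the analysis assumes:
# stable subject-level alpha (8-14.5 Hz) power, post-train low-gamma
# (30-40 Hz) power decaying exponentially across the inter-train interval,
# a right-prefrontal gamma topography peaked near FC4, and a planted linear
# coupling between the log gamma/alpha first-segment marker (plus an
# inter-hemispheric asymmetry term) and clinical improvement. Every cohort
# is returned together with its ground truth so recovery tests are
# self-validating.

#' Cohort and protocol configuration
#'
#' Defaults reproduce the trial protocol: three groups (Real, AC, Sham) of
#' 15/14/14 subjects; treatment sessions of 40 trains, 2 s long and 18 Hz,
#' separated by 20 s inter-train intervals (1440 pulses per session); TEP
#' sessions of 50 single pulses 5 s apart; 120 s of rest; 500 Hz sampling.
#'
#' The clinical model plants, in the Real group only,
#' `improvement = beta0 + beta1 (m - mu_m) + beta2 asym + noise`, where `m`
#' is the subject's noise-free first-segment log gamma/alpha marker at FC4
#' and `asym` the alpha asymmetry coefficient; control groups receive their
#' own `beta0` with matched noise (`beta1 = beta2 = 0`). When `beta1` is not
#' given it is calibrated from the trait-distribution moments so that the
#' population correlation between `m` and improvement equals `planted_r`.
#'
#' @param n_per_group named vector of group sizes (Real, AC, Sham)
#' @param seed integer seed controlling the whole cohort
#' @param planted_r target population correlation between the FC4 log marker
#'   and improvement in the Real group
#' @param beta1 marker coefficient (t-score units per log unit); NULL =
#'   calibrate from `planted_r`
#' @param beta2 asymmetry coefficient (t-score units per asymmetry unit)
#' @param noise_sd residual SD of improvement (t-score units)
#' @param beta0 named vector of mean improvement per group (t-score units)
#' @param sfreq sampling rate, Hz (>= 200 to resolve the gamma band)
#' @param n_trains,train_dur,iti_dur,train_freq treatment protocol: number of
#'   trains, train duration (s), inter-train interval from train end to next
#'   onset (s), pulse frequency within a train (Hz)
#' @param n_tep_pulses,tep_ipi TEP protocol: pulse count and inter-pulse
#'   interval (s)
#' @param rest_duration resting recording length (s)
#' @param alpha_amp_meanlog,alpha_amp_sdlog log-normal law of the subject
#'   alpha source amplitude (uV)
#' @param gamma_resp_meanlog,gamma_resp_sdlog log-normal law of the evoked
#'   post-train gamma amplitude (uV)
#' @param gamma_rest_meanlog,gamma_rest_sdlog log-normal law of the ongoing
#'   (resting) gamma amplitude (uV)
#' @param gamma_decay_tau exponential decay constant of post-train gamma (s)
#' @param tau_sdlog between-subject log-SD of the decay constant (default 0:
#'   fixed tau, which keeps the planted marker-improvement correlation in
#'   closed form)
#' @param asym_sd SD of the left-right alpha asymmetry coefficient
#' @param noise_rms broadband 1/f background noise RMS (uV)
#' @param group_gamma_scale scaling of the evoked gamma response per group
#'   (Sham receives no effective stimulation)
#' @param topography_width angular width (radians) of the right-prefrontal
#'   evoked-gamma topography around FC4
#' @param pre_t_mean,pre_t_sd law of the baseline CAARS-style total-symptom
#'   t-score
#' @param tep_gain_sdlog between-subject log-SD of TEP amplitude
#' @param n75_reduction named vector: fractional reduction of the N75
#'   component from pre to post treatment per group
#' @param pad recording padding before the first event (s)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_per_group = c(Real = 15, AC = 14, Sham = 14),
                          seed = 1,
                          planted_r = 0.85, beta1 = NULL, beta2 = 0,
                          noise_sd = 7,
                          beta0 = c(Real = 8.3, AC = 2.8, Sham = 1.9),
                          sfreq = 500,
                          n_trains = 40, train_dur = 2, iti_dur = 20,
                          train_freq = 18,
                          n_tep_pulses = 50, tep_ipi = 5,
                          rest_duration = 120,
                          alpha_amp_meanlog = log(15), alpha_amp_sdlog = 0.4,
                          gamma_resp_meanlog = log(10), gamma_resp_sdlog = 0.4,
                          gamma_rest_meanlog = log(1.4), gamma_rest_sdlog = 0.4,
                          gamma_decay_tau = 3, tau_sdlog = 0,
                          asym_sd = 0.15,
                          noise_rms = 3,
                          group_gamma_scale = c(Real = 1, AC = 0.5, Sham = 0),
                          topography_width = 0.6,
                          pre_t_mean = 76, pre_t_sd = 10,
                          tep_gain_sdlog = 0.2,
                          n75_reduction = c(Real = 0.4, AC = 0, Sham = 0),
                          pad = 2) {
  if (any(n_per_group < 2)) stop("n_per_group must be at least 2 per group")
  if (sfreq < 200) stop("sfreq must be >= 200 Hz to resolve the 30-40 Hz band")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Pulses per treatment session
#' @param config a `cohort_config`
#' @return total pulse count (trains x duration x frequency)
#' @export
protocol_pulse_count <- function(config) {
  config$n_trains * config$train_dur * config$train_freq
}

# mean of exp(-2 t / tau) over the first-segment window [1, 3] s post train:
# the decay-envelope power factor entering the noise-free marker
.decay_power_factor <- function(tau, lo = 1, hi = 3) {
  tau / (2 * (hi - lo)) * (exp(-2 * lo / tau) - exp(-2 * hi / tau))
}

# noise-free first-segment log marker at FC4 for given traits
.true_marker <- function(alpha_amp, gamma_resp, tau, asym) {
  p_gamma <- gamma_resp^2 * .decay_power_factor(tau)
  p_alpha <- (alpha_amp * (1 + asym / 2))^2
  log(p_gamma / p_alpha)
}

.draw_traits <- function(n, config) {
  asym <- pmax(-1.5, pmin(1.5, stats::rnorm(n, 0, config$asym_sd)))
  tau <- if (config$tau_sdlog > 0) {
    stats::rlnorm(n, log(config$gamma_decay_tau), config$tau_sdlog)
  } else rep(config$gamma_decay_tau, n)
  data.frame(
    alpha_amp = stats::rlnorm(n, config$alpha_amp_meanlog, config$alpha_amp_sdlog),
    gamma_resp = stats::rlnorm(n, config$gamma_resp_meanlog, config$gamma_resp_sdlog),
    gamma_rest = stats::rlnorm(n, config$gamma_rest_meanlog, config$gamma_rest_sdlog),
    gamma_decay_tau = tau,
    asym = asym,
    tep_gain = stats::rlnorm(n, 0, config$tep_gain_sdlog)
  )
}

# Trait-distribution moments of (marker, asym), from a large fixed-seed draw.
.marker_moments <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(20260131)
  tr <- .draw_traits(50000, config)
  m <- .true_marker(tr$alpha_amp, tr$gamma_resp, tr$gamma_decay_tau, tr$asym)
  list(mu_m = mean(m), var_m = stats::var(m),
       cov_ma = stats::cov(m, tr$asym), var_a = stats::var(tr$asym))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Marker coefficient implied by a target planted correlation
#'
#' Solves for `beta1` such that the population correlation between the
#' noise-free FC4 log marker and improvement equals `planted_r`, given
#' `beta2` and `noise_sd`, using the trait-distribution moments.
#'
#' @param config a `cohort_config`
#' @return list with `beta1`, the moments used, and the implied correlation
#' @export
calibrate_beta1 <- function(config) {
  mm <- .marker_moments(config)
  r <- config$planted_r; b2 <- config$beta2; s2 <- config$noise_sd^2
  r_of_b1 <- function(b1) {
    covv <- b1 * mm$var_m + b2 * mm$cov_ma
    vimp <- b1^2 * mm$var_m + b2^2 * mm$var_a + 2 * b1 * b2 * mm$cov_ma + s2
    covv / sqrt(mm$var_m * vimp)
  }
  if (b2 == 0) {
    b1 <- r * config$noise_sd / (sqrt(mm$var_m) * sqrt(1 - r^2))
  } else {
    b1 <- stats::uniroot(function(b) r_of_b1(b) - r, c(0, 1e4))$root
  }
  list(beta1 = b1, moments = mm, implied_r = r_of_b1(b1))
}

# ---- signal synthesis ----------------------------------------------------

# direct-form IIR filtering (compiled)
.iir <- function(b, a, x) {
  iir_filter_cpp(b / a[1], a / a[1], as.numeric(x))
}

# filter one long draw and split it into channel rows, normalizing each row
# to unit RMS; filter state bleeding across row boundaries is negligible for
# noise sources (transients decay within ~0.1 s) and avoids per-channel
# filter-call overhead
.filtered_rows <- function(b, a, n_chan, n_samp) {
  x <- .iir(b, a, stats::rnorm(n_chan * n_samp))
  m <- matrix(x, n_chan, n_samp, byrow = TRUE)
  m / sqrt(rowMeans(m^2))
}

# broadband 1/f ("pink") noise via a 3-pole IIR shaping filter, scaled to a
# target RMS per channel
.pink_noise <- function(n_chan, n_samp, rms) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  rms * .filtered_rows(b, a, n_chan, n_samp)
}

# unit-RMS band-limited noise source
.band_source <- function(n_samp, fs, lo, hi) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- .iir(bf$b, bf$a, stats::rnorm(n_samp))
  x / stats::sd(x)
}

# Band-limited scalp activity as a fixed low-rank source mixture: k latent
# unit-RMS band sources projected through a fixed random mixing matrix with
# unit-norm rows, then scaled by the per-channel RMS gains. The mixture makes
# channels only partially coherent (as scalp oscillations are), so the
# average reference does not cancel the activity, while per-channel RMS
# equals `gains` exactly. The mixing matrix is deterministic (per band) and
# constant across subjects and sessions, playing the role of fixed source
# geometry.
.mixing_matrix <- function(n_chan, k, band_tag) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(777000L + round(band_tag * 10))
  w <- matrix(stats::rnorm(n_chan * k), n_chan, k)
  w / sqrt(rowSums(w^2))
}

.band_noise_matrix <- function(gains, n_samp, fs, lo, hi, k = 8) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  s <- .filtered_rows(bf$b, bf$a, k, n_samp)
  (gains * .mixing_matrix(length(gains), k, lo)) %*% s
}

# spatial weight map: Gaussian in great-circle distance around a seed channel
.topography <- function(montage, center, width) {
  p <- montage_positions(montage)
  cosang <- pmin(1, pmax(-1, as.vector(p %*% p[center, ])))
  stats::setNames(exp(-acos(cosang)^2 / (2 * width^2)), rownames(p))
}

# hemisphere weighting of the alpha source: right x (1 + asym/2),
# left x (1 - asym/2), midline unweighted
.alpha_weights <- function(montage, asym) {
  x <- montage$channels$x
  w <- rep(1, length(x))
  w[x > 1e-9] <- 1 + asym / 2
  w[x < -1e-9] <- 1 - asym / 2
  stats::setNames(w, montage$channels$label)
}

.new_recording <- function(data, sfreq, events, flags, subject, session, condition) {
  structure(list(data = data, sfreq = sfreq, events = events, flags = flags,
                 subject = subject, session = session, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (%s), %d events\n",
              x$subject, x$session, nrow(x$data), ncol(x$data), x$sfreq,
              x$condition, nrow(x$events)))
  invisible(x)
}

#' Synthesize a resting-state recording
#'
#' 1/f background noise plus the subject's stable alpha source (hemisphere
#' weighting by the asymmetry trait) and ongoing low-gamma activity.
#'
#' @param traits one row of a trait table (see [generate_cohort()])
#' @param config a `cohort_config`
#' @param montage a `montage` object
#' @param duration recording length in seconds
#' @param seed optional seed (NULL: use the current RNG state)
#' @return an `eeg_recording`
#' @export
synthesize_rest_eeg <- function(traits, config, montage = standard_montage(),
                                duration = config$rest_duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sfreq
  n <- round(duration * fs)
  labs <- montage$channels$label
  dat <- .pink_noise(length(labs), n, config$noise_rms)
  w_a <- .alpha_weights(montage, traits$asym)
  dat <- dat + .band_noise_matrix(traits$alpha_amp * w_a, n, fs, 8.5, 13.5)
  dat <- dat + .band_noise_matrix(rep(traits$gamma_rest, length(labs)), n, fs, 31, 39)
  rownames(dat) <- labs
  .new_recording(dat, fs, data.frame(onset = numeric(0), type = character(0),
                                     duration = numeric(0)),
                 rep(FALSE, n), traits$subject, "rest", "rest")
}

#' Synthesize a treatment session with stimulation trains
#'
#' The session carries `n_trains` trains of `train_dur` seconds separated by
#' `iti_dur` seconds of inter-train interval (train end to next onset).
#' Samples during trains are saturated and flagged (a stand-in for the TMS
#' artifact, which the analysis windows are designed to avoid). Between
#' trains the signal is 1/f noise plus the stable alpha source, ongoing
#' gamma, and a 30-40 Hz evoked component whose envelope after each train is
#' `gamma_resp * exp(-t/tau)`, spatially peaked at the right-prefrontal
#' channels around FC4 and scaled per group (`group_gamma_scale`).
#'
#' @param traits one row of a trait table; must carry `group`
#' @param config a `cohort_config`
#' @param montage a `montage` object
#' @param seed optional seed
#' @return an `eeg_recording` with `train_onset`/`train_offset` events
#' @export
synthesize_treatment_eeg <- function(traits, config, montage = standard_montage(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sfreq
  period <- config$train_dur + config$iti_dur
  total <- config$pad + config$n_trains * period
  n <- round(total * fs)
  labs <- montage$channels$label
  onsets <- config$pad + (seq_len(config$n_trains) - 1) * period
  offsets <- onsets + config$train_dur

  dat <- .pink_noise(length(labs), n, config$noise_rms)
  w_a <- .alpha_weights(montage, traits$asym)
  dat <- dat + .band_noise_matrix(traits$alpha_amp * w_a, n, fs, 8.5, 13.5)
  dat <- dat + .band_noise_matrix(rep(traits$gamma_rest, length(labs)), n, fs, 31, 39)

  scale <- config$group_gamma_scale[[as.character(traits$group)]]
  if (is.null(scale) || is.na(scale)) scale <- 1
  g_eff <- traits$gamma_resp * scale
  if (g_eff > 0) {
    tt <- (seq_len(n) - 1) / fs
    env <- numeric(n)
    for (i in seq_along(offsets)) {
      lo <- offsets[i]
      hi <- if (i < length(onsets)) onsets[i + 1] else total
      idx <- which(tt >= lo & tt < hi)
      env[idx] <- exp(-(tt[idx] - lo) / traits$gamma_decay_tau)
    }
    w_g <- .topography(montage, "FC4", config$topography_width)
    dat <- dat + (g_eff * w_g) %o% (.band_source(n, fs, 31, 39) * env)
  }

  flags <- rep(FALSE, n)
  for (i in seq_along(onsets)) {
    a <- round(onsets[i] * fs) + 1
    b <- min(n, round(offsets[i] * fs))
    dat[, a:b] <- 400                  # saturated amplifier during the train
    flags[a:b] <- TRUE
  }
  rownames(dat) <- labs
  ev <- rbind(data.frame(onset = onsets, type = "train_onset", duration = config$train_dur),
              data.frame(onset = offsets, type = "train_offset", duration = 0))
  ev <- ev[order(ev$onset), ]
  .new_recording(dat, fs, ev, flags, traits$subject, "treatment", "treatment")
}

#' Noise-free TEP template
#'
#' Sum of Gaussian-windowed deflections at the canonical component latencies
#' (N45, P60, N75, N100, P180), N components negative and P components
#' positive, evaluated on a time axis in seconds relative to the pulse.
#'
#' @param times time axis (s)
#' @param component_scales named amplitude multipliers per component
#' @return numeric waveform (uV at the peak channel)
#' @export
tep_template <- function(times,
                         component_scales = c(N45 = 1, P60 = 1, N75 = 1,
                                              N100 = 1, P180 = 1)) {
  comp <- data.frame(
    name = c("N45", "P60", "N75", "N100", "P180"),
    lat = c(0.045, 0.060, 0.075, 0.100, 0.180),
    amp = c(-3, 2.5, -4, -5, 4),
    width = c(0.006, 0.006, 0.008, 0.015, 0.030)
  )
  w <- numeric(length(times))
  for (i in seq_len(nrow(comp))) {
    s <- component_scales[[comp$name[i]]]
    if (is.null(s) || is.na(s)) s <- 1
    w <- w + s * comp$amp[i] * exp(-(times - comp$lat[i])^2 / (2 * comp$width[i]^2))
  }
  w
}

#' Synthesize a TEP session
#'
#' Single TMS pulses at a fixed inter-pulse interval; each pulse evokes the
#' stereotyped component waveform (see [tep_template()]) scaled by the
#' subject's TEP gain and spatially peaked near F4, on top of 1/f noise and
#' the alpha source. A high-amplitude artifact burst spans -2..10 ms around
#' each pulse (flagged).
#'
#' @param traits one row of a trait table
#' @param config a `cohort_config`
#' @param montage a `montage` object
#' @param component_scales per-component amplitude multipliers
#' @param session session label (e.g. "tep_pre", "tep_post")
#' @param seed optional seed
#' @return an `eeg_recording` with `tms_pulse` events
#' @export
synthesize_tep <- function(traits, config, montage = standard_montage(),
                           component_scales = c(N45 = 1, P60 = 1, N75 = 1,
                                                N100 = 1, P180 = 1),
                           session = "tep", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sfreq
  total <- 2 * config$pad + config$n_tep_pulses * config$tep_ipi
  n <- round(total * fs)
  labs <- montage$channels$label
  pulses <- config$pad + (seq_len(config$n_tep_pulses) - 1) * config$tep_ipi

  dat <- .pink_noise(length(labs), n, config$noise_rms)

  tmpl_t <- seq(0, 0.35, by = 1 / fs)
  tmpl <- tep_template(tmpl_t, component_scales) * traits$tep_gain
  w_tep <- .topography(montage, "F4", 0.7)
  flags <- rep(FALSE, n)
  for (t0 in pulses) {
    a <- round(t0 * fs) + 1
    idx <- a:(a + length(tmpl) - 1)
    dat[, idx] <- dat[, idx] + w_tep %o% tmpl
    # pulse artifact burst, -2..10 ms
    art <- (round((t0 - 0.002) * fs) + 1):(round((t0 + 0.010) * fs))
    dat[, art] <- dat[, art] + matrix(stats::rnorm(length(labs) * length(art), 0, 200),
                                      length(labs))
    flags[art] <- TRUE
  }
  rownames(dat) <- labs
  ev <- data.frame(onset = pulses, type = "tms_pulse", duration = 0)
  .new_recording(dat, fs, ev, flags, traits$subject, session, "tep")
}

# ---- cohort assembly -----------------------------------------------------

.derive_seed <- function(seed, i, k) {
  ((seed %% 100000) * 10000 + i * 10 + k) %% 2147483647L
}

#' Regenerate one subject's session on demand
#'
#' Cohorts can be large; rather than holding every recording in memory, any
#' session can be re-synthesized deterministically from the cohort's ground
#' truth and seed. The recording returned here is identical to the one
#' [generate_cohort()] or [run_simulate()] produces for the same subject and
#' session.
#'
#' @param cohort result of [generate_cohort()] (the EEG part may have been
#'   generated with `eeg = FALSE`)
#' @param subject subject index or identifier
#' @param session one of `"rest"`, `"tep_pre"`, `"tep_post"`, `"treatment"`
#' @param config the `cohort_config` the cohort was generated with
#' @param montage a `montage` object
#' @return an `eeg_recording`
#' @export
cohort_session <- function(cohort, subject, session, config,
                           montage = standard_montage()) {
  traits <- cohort$ground_truth$traits
  i <- if (is.character(subject)) match(subject, traits$subject) else subject
  if (is.na(i) || i < 1 || i > nrow(traits)) stop("unknown subject: ", subject)
  tr <- traits[i, ]
  seed <- config$seed
  switch(match.arg(session, c("rest", "tep_pre", "tep_post", "treatment")),
    rest = synthesize_rest_eeg(tr, config, montage,
                               seed = .derive_seed(seed, i, 1)),
    tep_pre = synthesize_tep(tr, config, montage, session = "tep_pre",
                             seed = .derive_seed(seed, i, 2)),
    tep_post = {
      red <- config$n75_reduction[[tr$group]]
      if (is.null(red) || is.na(red)) red <- 0
      synthesize_tep(tr, config, montage,
                     component_scales = c(N45 = 1, P60 = 1, N75 = 1 - red,
                                          N100 = 1, P180 = 1),
                     session = "tep_post", seed = .derive_seed(seed, i, 3))
    },
    treatment = synthesize_treatment_eeg(tr, config, montage,
                                         seed = .derive_seed(seed, i, 4))
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws per-subject traits and clinical scores (and, optionally, the EEG
#' recordings) for a three-arm cohort with the planted marker-improvement
#' coupling in the Real group. The ground truth (traits, noise-free markers,
#' planted coefficients) is returned alongside, so recovery analyses can be
#' validated against it.
#'
#' @param config a `cohort_config`
#' @param montage a `montage` object
#' @param eeg generate EEG recordings (set FALSE for clinical-only cohorts,
#'   e.g. large calibration runs)
#' @param sessions which sessions to synthesize when `eeg = TRUE`; subset of
#'   `c("rest", "tep", "treatment")`
#' @return list with `clinical` (data frame: subject, group, pre/post/FU
#'   t-scores and raw scores, improvement, responder), `ground_truth` (traits
#'   + planted model), and `recordings` (per-subject named list, or NULL)
#' @export
generate_cohort <- function(config, montage = standard_montage(), eeg = TRUE,
                            sessions = c("rest", "tep", "treatment")) {
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%02d", seq_len(n))

  traits <- .draw_traits(n, config)
  traits$subject <- ids
  traits$group <- groups

  cal <- calibrate_beta1(config)
  b1 <- if (is.null(config$beta1)) cal$beta1 else config$beta1
  m_true <- .true_marker(traits$alpha_amp, traits$gamma_resp,
                         traits$gamma_decay_tau, traits$asym)
  # homologous-channel marker: the evoked gamma topography is attenuated at
  # FC3 and the alpha asymmetry weight mirrors
  w_fc3 <- .topography(montage, "FC4", config$topography_width)[["FC3"]]
  m_fc3 <- log((traits$gamma_resp * w_fc3)^2 *
                 .decay_power_factor(traits$gamma_decay_tau) /
                 (traits$alpha_amp * (1 - traits$asym / 2))^2)
  eps <- stats::rnorm(n, 0, config$noise_sd)
  improvement <- config$beta0[groups] + eps
  real <- groups == "Real"
  improvement[real] <- improvement[real] +
    b1 * (m_true[real] - cal$moments$mu_m) + config$beta2 * traits$asym[real]

  pre_t <- stats::rnorm(n, config$pre_t_mean, config$pre_t_sd)
  post_t <- pre_t - improvement
  fu_t <- pre_t - (0.8 * improvement + stats::rnorm(n, 0, config$noise_sd / 2))
  to_raw <- function(t) pmax(1, round(1.1 * (t - 35)))
  pre_raw <- to_raw(pre_t); post_raw <- to_raw(post_t)
  resp <- classify_responders(pre_raw, post_raw)

  clinical <- data.frame(subject = ids, group = groups,
                         pre_t = pre_t, post_t = post_t, fu_t = fu_t,
                         pre_raw = pre_raw, post_raw = post_raw,
                         improvement = improvement,
                         responder = resp$responder,
                         stringsAsFactors = FALSE)
  ground_truth <- list(
    traits = traits, true_marker = stats::setNames(m_true, ids),
    true_marker_fc3 = stats::setNames(m_fc3, ids),
    true_improvement = stats::setNames(improvement, ids),
    planted_r = config$planted_r, beta0 = config$beta0, beta1 = b1,
    beta2 = config$beta2, noise_sd = config$noise_sd,
    mu_m = cal$moments$mu_m, sd_m = sqrt(cal$moments$var_m)
  )

  out <- list(clinical = clinical, ground_truth = ground_truth,
              recordings = NULL)
  if (eeg) {
    recordings <- stats::setNames(vector("list", n), ids)
    for (i in seq_len(n)) {
      rec <- list()
      if ("rest" %in% sessions)
        rec$rest <- cohort_session(out, i, "rest", config, montage)
      if ("tep" %in% sessions) {
        rec$tep_pre <- cohort_session(out, i, "tep_pre", config, montage)
        rec$tep_post <- cohort_session(out, i, "tep_post", config, montage)
      }
      if ("treatment" %in% sessions)
        rec$treatment <- cohort_session(out, i, "treatment", config, montage)
      recordings[[i]] <- rec
    }
    out$recordings <- recordings
  }
  out
}
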