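# Shared fixtures. The montage and CSD spline system are deterministic and
# montage construction is cheap, but build them once per test run.

test_montage <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- standard_montage()
    m
  }
})

# minimal recording constructor for hand-built fixtures
make_recording <- function(data, sfreq, events = NULL, flags = NULL,
                           subject = "T1", session = "treatment") {
  if (is.null(events))
    events <- data.frame(onset = numeric(0), type = character(0),
                         duration = numeric(0))
  if (is.null(flags)) flags <- rep(FALSE, ncol(data))
  structure(list(data = data, sfreq = sfreq, events = events, flags = flags,
                 subject = subject, session = session, condition = session),
            class = "eeg_recording")
}

# recording with zeros on the full montage and a given train timeline
make_train_recording <- function(onsets, offsets, total, sfreq = 100,
                                 montage = test_montage(), flags = NULL) {
  n <- round(total * sfreq)
  data <- matrix(0, 64, n, dimnames = list(montage$channels$label, NULL))
  ev <- rbind(data.frame(onset = onsets, type = "train_onset", duration = offsets - onsets),
              data.frame(onset = offsets, type = "train_offset", duration = 0))
  make_recording(data, sfreq, ev[order(ev$onset), ], flags = flags)
}

# small epoch_set of white noise on the full montage
make_noise_epochs <- function(n_epochs = 5, sfreq = 200, epoch_len = 2,
                              seed = 1, condition = "rest") {
  set.seed(seed)
  mont <- test_montage()
  d <- array(rnorm(64 * sfreq * epoch_len * n_epochs),
             dim = c(64, sfreq * epoch_len, n_epochs),
             dimnames = list(mont$channels$label, NULL, NULL))
  epoch_set(d, sfreq, condition)
}

# two trains of 2 s separated by a gap L, with the recording ending at the
# second train's offset so only the first (bounded) interval yields epochs
gap_recording <- function(L, sfreq = 100) {
  make_train_recording(onsets = c(1, 3 + L), offsets = c(3, 5 + L),
                       total = 5 + L, sfreq = sfreq)
}

# elementwise linear combination of two aligned epoch sets
within_epochs_lincomb <- function(ep1, ep2, a, b) {
  out <- ep1
  out$data <- a * ep1$data + b * ep2$data
  out
}

# fast cohort settings used by unit tests (full protocol is exercised in the
# acceptance suite at larger sizes)
tiny_cohort_config <- function(...) {
  cohort_config(n_per_group = c(Real = 3, AC = 2, Sham = 2), seed = 42,
                sfreq = 200, n_trains = 4, rest_duration = 12,
                n_tep_pulses = 12, ...)
}
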