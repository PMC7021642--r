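test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- tiny_cohort_config()
  mont <- test_montage()
  a <- generate_cohort(cfg, mont, eeg = TRUE, sessions = "treatment")
  b <- generate_cohort(cfg, mont, eeg = TRUE, sessions = "treatment")
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$ground_truth$traits, b$ground_truth$traits)
  expect_identical(a$recordings[[1]]$treatment$data, b$recordings[[1]]$treatment$data)
  c2 <- generate_cohort(cohort_config(n_per_group = c(Real = 3, AC = 2, Sham = 2),
                                      seed = 43, sfreq = 200, n_trains = 4,
                                      rest_duration = 12, n_tep_pulses = 12),
                        mont, eeg = FALSE)
  expect_false(identical(a$clinical$pre_t, c2$clinical$pre_t))
})

test_that("config validation rejects degenerate cohorts", {
  expect_error(cohort_config(n_per_group = c(Real = 1, AC = 2, Sham = 2)),
               "at least 2")
  expect_error(cohort_config(sfreq = 100), "sfreq")
})

test_that("generated band sources have their power inside the nominal bands", {
  set.seed(3)
  fs <- 200
  src_a <- itimarker:::.band_source(fs * 120, fs, 8.5, 13.5)
  src_g <- itimarker:::.band_source(fs * 120, fs, 31, 39)
  in_band <- function(x, lo, hi) {
    ep <- epoch_set(array(x, c(1, length(x), 1),
                          dimnames = list("FC4", NULL, NULL)), fs, "rest")
    psd <- welch_psd(ep)
    band_power(psd, band_definition("b", lo, hi)) /
      band_power(psd, band_definition("all", 0.5, 99))
  }
  expect_gt(in_band(src_a, 8, 14.5), 0.8)
  expect_gt(in_band(src_g, 30, 40), 0.8)
})

test_that("without a planted coupling the marker and improvement are unrelated", {
  cfg <- cohort_config(n_per_group = c(Real = 200), seed = 9, beta1 = 0,
                       beta2 = 0, noise_sd = 7)
  co <- generate_cohort(cfg, test_montage(), eeg = FALSE)
  r <- cor(co$ground_truth$true_marker, co$clinical$improvement)
  expect_lt(abs(r), 3 / sqrt(200))
})

test_that("the planted correlation is recovered in the ground truth at n = 200", {
  cfg <- cohort_config(n_per_group = c(Real = 200), seed = 10, planted_r = 0.9,
                       beta2 = 0)
  co <- generate_cohort(cfg, test_montage(), eeg = FALSE)
  r <- cor(co$ground_truth$true_marker, co$clinical$improvement)
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("control groups improve by their own baseline mean", {
  cfg <- cohort_config(n_per_group = c(Real = 40, AC = 40, Sham = 40), seed = 12)
  co <- generate_cohort(cfg, test_montage(), eeg = FALSE)
  cl <- co$clinical
  for (g in c("AC", "Sham")) {
    imp <- cl$improvement[cl$group == g]
    se <- sd(imp) / sqrt(length(imp))
    expect_lt(abs(mean(imp) - cfg$beta0[[g]]), 2 * se + 1e-9)
  }
})

test_that("a zero gamma response leaves ITI gamma power at its resting level", {
  cfg <- tiny_cohort_config()
  mont <- test_montage()
  tr <- data.frame(alpha_amp = 15, gamma_resp = 0, gamma_rest = 1.4,
                   gamma_decay_tau = 3, asym = 0, tep_gain = 1,
                   subject = "S1", group = "Real")
  treat <- synthesize_treatment_eeg(tr, cfg, mont, seed = 31)
  rest <- synthesize_rest_eeg(tr, cfg, mont, duration = 30, seed = 32)
  bands <- default_bands()
  g_iti <- band_power(welch_psd(first_segment(extract_iti_epochs(treat))),
                      bands[2, ])["FC4"]
  g_rest <- band_power(welch_psd(extract_rest_epochs(rest)), bands[2, ])["FC4"]
  expect_lt(abs(log(g_iti / g_rest)), log(1.5))
})

test_that("the planted gamma decay constant is recoverable from segment powers", {
  cfg <- cohort_config(n_per_group = c(Real = 2), seed = 14, sfreq = 200,
                       n_trains = 40, gamma_decay_tau = 2,
                       gamma_resp_meanlog = log(12), gamma_resp_sdlog = 0)
  mont <- test_montage()
  tr <- generate_cohort(cfg, mont, eeg = FALSE)$ground_truth$traits[1, ]
  rec <- synthesize_treatment_eeg(tr, cfg, mont, seed = 15)
  ep <- extract_iti_epochs(rec)
  pt <- segment_band_power(ep, default_bands()[2, , drop = FALSE], channel = "FC4",
                           subject = "S1")
  pt <- pt[pt$segment <= 7, ]
  # segment k spans [2k - 1, 2k + 1] s post train; evoked power decays as
  # exp(-2 t / tau) on top of a stationary floor (resting gamma + broadband
  # noise), estimated from the late segments where the decay has died out
  floor_est <- mean(pt$power[pt$segment >= 6])
  early <- pt[pt$segment <= 3, ]
  fit <- lm(log(pmax(early$power - floor_est, 1e-6)) ~ I(2 * early$segment))
  tau_hat <- -2 / coef(fit)[[2]]
  expect_lt(abs(tau_hat - 2) / 2, 0.3)
})

test_that("alpha power is a stable trait between rest and treatment", {
  cfg <- cohort_config(n_per_group = c(Real = 25), seed = 16, sfreq = 200,
                       n_trains = 3, rest_duration = 16)
  mont <- test_montage()
  co <- generate_cohort(cfg, mont, eeg = TRUE, sessions = c("rest", "treatment"))
  bands <- default_bands()
  pow <- t(vapply(co$recordings, function(rec) {
    a_iti <- band_power(welch_psd(first_segment(extract_iti_epochs(rec$treatment))),
                        bands[1, ])["FC4"]
    a_rest <- band_power(welch_psd(extract_rest_epochs(rec$rest)), bands[1, ])["FC4"]
    c(a_iti, a_rest)
  }, numeric(2)))
  expect_gt(cor(log(pow[, 1]), log(pow[, 2])), 0.9)
})

test_that("TEP sessions carry the planted component structure", {
  cfg <- cohort_config(n_per_group = c(Real = 2), seed = 17, sfreq = 500,
                       n_tep_pulses = 50, tep_gain_sdlog = 0)
  mont <- test_montage()
  tr <- data.frame(alpha_amp = 15, gamma_resp = 8, gamma_rest = 1,
                   gamma_decay_tau = 3, asym = 0, tep_gain = 1,
                   subject = "S1", group = "Real")
  # all components off -> TOI amplitudes are pure noise around zero
  rec0 <- synthesize_tep(tr, cfg, mont,
                         component_scales = c(N45 = 0, P60 = 0, N75 = 0,
                                              N100 = 0, P180 = 0), seed = 18)
  amp0 <- component_amplitude(average_tep(extract_tep_epochs(rec0)))
  expect_lt(max(abs(amp0)), 1.5)

  # halving N75 shifts its TOI amplitude by exactly the template difference
  # (paired comparison on the same noise seed)
  rec1 <- synthesize_tep(tr, cfg, mont, seed = 19)
  rec2 <- synthesize_tep(tr, cfg, mont,
                         component_scales = c(N45 = 1, P60 = 1, N75 = 0.5,
                                              N100 = 1, P180 = 1), seed = 19)
  a1 <- component_amplitude(average_tep(extract_tep_epochs(rec1)))
  a2 <- component_amplitude(average_tep(extract_tep_epochs(rec2)))
  tmpl_t <- seq(0, 0.35, by = 1 / 500)
  toi <- tmpl_t >= 0.070 & tmpl_t <= 0.090
  d75 <- mean(tep_template(tmpl_t)[toi]) -
    mean(tep_template(tmpl_t, c(N45 = 1, P60 = 1, N75 = 0.5,
                                N100 = 1, P180 = 1))[toi])
  expect_equal(a1[["N75"]] - a2[["N75"]], d75, tolerance = 0.05)
  expect_lt(a1[["N75"]], a2[["N75"]])
})

test_that("template peak latencies sit at the canonical component times", {
  t <- seq(0, 0.3, by = 1e-4)
  w <- tep_template(t)
  comp <- tep_components()
  for (i in seq_len(nrow(comp))) {
    sel <- t >= comp$lo_ms[i] / 1000 & t <= comp$hi_ms[i] / 1000
    t_peak <- t[sel][which.max(comp$polarity[i] * w[sel])]
    lat <- c(N45 = 45, P60 = 60, N75 = 75, N100 = 100, P180 = 180)[[comp$name[i]]]
    expect_lt(abs(t_peak * 1000 - lat), 5)
  }
})

test_that("treatment sessions flag saturated train samples", {
  cfg <- tiny_cohort_config()
  tr <- data.frame(alpha_amp = 15, gamma_resp = 8, gamma_rest = 1,
                   gamma_decay_tau = 3, asym = 0, tep_gain = 1,
                   subject = "S1", group = "Real")
  rec <- synthesize_treatment_eeg(tr, cfg, test_montage(), seed = 20)
  on <- rec$events$onset[rec$events$type == "train_onset"][1]
  idx <- round((on + 1) * rec$sfreq)
  expect_true(rec$flags[idx])
  expect_equal(unname(rec$data[1, idx]), 400)
  expect_equal(sum(rec$events$type == "train_onset"), cfg$n_trains)
})
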