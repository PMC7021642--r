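make_tone_epochs <- function(freqs, amps, sfreq = 200, epoch_len = 2,
                             n_epochs = 4) {
  mont <- test_montage()
  t <- seq(0, epoch_len - 1 / sfreq, by = 1 / sfreq)
  sig <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  d <- array(rep(sig, each = 64), dim = c(64, length(t), 1))[, , rep(1, n_epochs), drop = FALSE]
  dimnames(d) <- list(mont$channels$label, NULL, NULL)
  epoch_set(d, sfreq, "rest")
}

test_that("welch PSD concentrates a pure tone in its band", {
  ep <- make_tone_epochs(10, 2)
  psd <- welch_psd(ep)
  bands <- default_bands()
  total <- band_power(psd, band_definition("all", 0.5, 99))
  alpha <- band_power(psd, bands[bands$name == "Alpha", ])
  expect_true(all(alpha / total >= 0.95))
  expect_error(welch_psd(ep, seg_len = 5), "seg_len")
})

test_that("welch PSD satisfies Parseval on white noise and vanishes on silence", {
  ep <- make_noise_epochs(n_epochs = 10, seed = 3)
  psd <- welch_psd(ep)
  df <- diff(psd$freqs)[1]
  for (ch in c(1, 30, 64)) {
    expect_equal(sum(psd$power[ch, ]) * df,
                 var(as.vector(ep$data[ch, , ])), tolerance = 0.05)
  }
  zep <- ep; zep$data[] <- 0
  expect_true(all(welch_psd(zep)$power == 0))
})

test_that("band power integrates tones correctly and scales quadratically", {
  ep35 <- make_tone_epochs(35, 2)
  psd <- welch_psd(ep35)
  bands <- default_bands()
  g <- band_power(psd, bands[bands$name == "LowGamma", ])
  a <- band_power(psd, bands[bands$name == "Alpha", ])
  tot <- band_power(psd, band_definition("all", 0.5, 99))
  expect_true(all(g / tot > 0.95))
  expect_true(all(a / tot < 0.01))

  # equal-amplitude 10 + 35 Hz tones: alpha and gamma power within 10%
  ep2 <- make_tone_epochs(c(10, 35), c(1.5, 1.5))
  psd2 <- welch_psd(ep2)
  a2 <- band_power(psd2, bands[bands$name == "Alpha", ])
  g2 <- band_power(psd2, bands[bands$name == "LowGamma", ])
  expect_true(all(abs(a2 / g2 - 1) < 0.1))

  # doubling the signal quadruples the power
  ep4 <- ep2; ep4$data <- 2 * ep2$data
  psd4 <- welch_psd(ep4)
  expect_equal(band_power(psd4, bands[1, ]), 4 * a2, tolerance = 1e-6)
})

test_that("band power is additive over a disjoint band partition", {
  ep <- make_noise_epochs(n_epochs = 6, seed = 13)
  psd <- welch_psd(ep)
  cuts <- c(0.5, 8, 14.5, 29.5, 40, 99)
  parts <- sapply(seq_len(length(cuts) - 1), function(i)
    band_power(psd, band_definition("p", cuts[i], cuts[i + 1])))
  whole <- band_power(psd, band_definition("all", 0.5, 99))
  expect_equal(unname(rowSums(parts)), unname(whole), tolerance = 1e-9)
})

test_that("the marker is the elementwise gamma/alpha ratio", {
  a <- matrix(2, 4, 3, dimnames = list(paste0("S", 1:4), c("FC4", "FC3", "Cz")))
  g <- a
  expect_true(all(compute_marker(a, g) == 1))
  expect_true(all(compute_marker(a, 2 * g) == 2))
  expect_true(all(compute_marker(a, g, direction = "alpha_over_gamma") == 1))
  a0 <- a; a0[1, 1] <- 0
  expect_error(compute_marker(a0, g), "alpha")
  expect_error(compute_marker(a[1:3, ], g), "aligned")
})

test_that("marker rank-orders subjects by their planted gamma/alpha ratio", {
  cfg <- cohort_config(n_per_group = c(Real = 20), seed = 5, sfreq = 200,
                       n_trains = 8)
  mont <- test_montage()
  co <- generate_cohort(cfg, mont, eeg = TRUE, sessions = "treatment")
  bands <- default_bands()
  mk <- vapply(co$recordings, function(rec) {
    ep <- first_segment(extract_iti_epochs(rec$treatment))
    psd <- welch_psd(apply_average_reference(ep))
    pa <- band_power(psd, bands[1, ]); pg <- band_power(psd, bands[2, ])
    unname(pg["FC4"] / pa["FC4"])
  }, numeric(1))
  tr <- co$ground_truth$traits
  planted <- (tr$gamma_resp / tr$alpha_amp)^2
  expect_gt(cor(mk, planted, method = "spearman"), 0.9)
})

test_that("marker-outcome map validates inputs and flags degenerate channels", {
  mont <- test_montage()
  set.seed(2)
  mk <- matrix(rlnorm(10 * 64), 10, 64, dimnames = list(NULL, mont$channels$label))
  expect_error(marker_outcome_map(mk, rep(1, 10), mont), "zero variance")
  expect_error(marker_outcome_map(mk[1:4, ], rnorm(4), mont), "5 subjects")
  mk[, "POz"] <- 2
  expect_warning(marker_outcome_map(mk, rnorm(10), mont, n_perm = 50), "POz")
})

test_that("interhemispheric balance equals the residual-regression oracle", {
  mont <- test_montage()
  set.seed(21)
  n <- 15
  vals <- matrix(rlnorm(n * 64), n, 64, dimnames = list(NULL, mont$channels$label))
  imp <- rnorm(n)
  tab <- interhemispheric_balance(vals, imp, mont)
  expect_equal(sum(!is.na(tab$r_partial)), 54)
  expect_equal(sum(is.na(tab$r_partial)), 10)
  for (ch in c("FC4", "F3", "TP10")) {
    pr <- homologous_pair(ch, mont)
    oracle <- cor(residuals(lm(log(vals[, ch]) ~ log(vals[, pr]))),
                  residuals(lm(imp ~ log(vals[, pr]))))
    expect_equal(tab$r_partial[tab$channel == ch], oracle, tolerance = 1e-10)
  }
})

test_that("interhemispheric balance is antisymmetric under left-right swap", {
  mont <- test_montage()
  set.seed(22)
  vals <- matrix(rlnorm(12 * 64), 12, 64, dimnames = list(NULL, mont$channels$label))
  imp <- rnorm(12)
  tab <- interhemispheric_balance(vals, imp, mont)
  swapped <- vals
  for (ch in lateral_channels(mont)) {
    swapped[, ch] <- vals[, homologous_pair(ch, mont)]
  }
  tab2 <- interhemispheric_balance(swapped, imp, mont)
  for (ch in lateral_channels(mont)) {
    pr <- homologous_pair(ch, mont)
    expect_equal(tab2$r_partial[tab2$channel == ch],
                 tab$r_partial[tab$channel == pr], tolerance = 1e-12)
  }
})

test_that("resting alpha balance restricts consistently and BH is monotone in m", {
  mont <- test_montage()
  set.seed(23)
  vals <- matrix(rlnorm(15 * 64), 15, 64, dimnames = list(NULL, mont$channels$label))
  imp <- rnorm(15)
  full <- interhemispheric_balance(vals, imp, mont)
  sub <- resting_alpha_balance(vals, imp, mont)
  expect_equal(nrow(sub), 8)
  for (ch in sub$channel) {
    expect_equal(sub$r_partial[sub$channel == ch],
                 full$r_partial[full$channel == ch], tolerance = 1e-12)
  }
  # FDR over the 8-channel subset rejects a superset of the 54-channel FDR
  p54 <- full$p[!is.na(full$p)]
  idx8 <- match(sub$channel, full$channel[!is.na(full$p)])
  rej54 <- bh_fdr(p54, 0.05)$rejected[idx8]
  rej8 <- bh_fdr(full$p[match(sub$channel, full$channel)], 0.05)$rejected
  expect_true(all(rej54 <= rej8))
  expect_error(resting_alpha_balance(vals, imp, mont,
                                     channels_of_interest = c("FC4", "Cz")),
               "lateral")
})

test_that("ITI dynamics normalizes to segment 1 and flags incomplete subjects", {
  pt <- expand.grid(subject = paste0("S", 1:6), band = c("Alpha", "LowGamma"),
                    segment = 1:7, stringsAsFactors = FALSE)
  pt$power <- 10
  dyn <- iti_dynamics(pt)
  expect_true(all(dyn$ratios$ratio == 1))
  expect_true(all(dyn$summary$mean == 1))
  expect_true(all(dyn$ratios$ratio[dyn$ratios$segment == 1] == 1))
  # a subject without segment 1 is dropped with a warning (one per band)
  pt2 <- pt[!(pt$subject == "S1" & pt$segment == 1), ]
  expect_warning(expect_warning(dyn2 <- iti_dynamics(pt2), "S1"), "S1")
  expect_false("S1" %in% dyn2$ratios$subject)
  expect_error(iti_dynamics(pt[pt$segment == 1, ]), "2 segments")
})

test_that("rest-treatment correlation is exact on identical tables and null on noise", {
  mont <- test_montage()
  set.seed(24)
  n <- 40
  rest <- matrix(rlnorm(n * 64), n, 64, dimnames = list(NULL, mont$channels$label))
  expect_true(all(abs(rest_treatment_correlation(rest, rest) - 1) < 1e-12))
  other <- matrix(rlnorm(n * 64), n, 64, dimnames = list(NULL, mont$channels$label))
  r <- rest_treatment_correlation(rest, other)
  expect_gte(mean(abs(r) < 3 / sqrt(n)), 0.95)
  expect_error(rest_treatment_correlation(rest[1:3, ], other[1:3, ]), "4 subjects")
})
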