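test_that("partial correlation reduces to simple correlation for orthogonal controls", {
  set.seed(1)
  n <- 40
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  # construct z orthogonal to both x and y
  z0 <- rnorm(n)
  z <- residuals(lm(z0 ~ x + y))
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
  expect_equal(partial_correlation(x, x, z)$r, 1, tolerance = 1e-10)
})

test_that("partial correlation equals the correlation of OLS residuals", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(30); z <- rnorm(30); y <- 0.4 * x - 0.3 * z + rnorm(30)
    pc <- partial_correlation(x, y, z)
    oracle <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-10)
    # parametric p from the t transform, df = n - 3
    tt <- oracle * sqrt(27 / (1 - oracle^2))
    expect_equal(pc$p, 2 * pt(-abs(tt), 27), tolerance = 1e-10)
  }
})

test_that("partial correlation is symmetric in x, y and affine-invariant", {
  set.seed(11)
  x <- rnorm(25); y <- rnorm(25); z <- rnorm(25)
  expect_equal(partial_correlation(x, y, z)$r, partial_correlation(y, x, z)$r,
               tolerance = 1e-12)
  expect_equal(partial_correlation(2 * x + 3, -1 + 0.5 * y, 10 * z - 2)$r,
               partial_correlation(x, y, z)$r, tolerance = 1e-10)
  expect_error(partial_correlation(x, y, 2 * x), "collinear")
})

test_that("BH-FDR matches the brute-force step-up definition", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(54)^sample(c(1, 3), 1)  # mix of uniform and signal-heavy vectors
    res <- bh_fdr(p, q = 0.05)
    expect_identical(res$rejected, bh_oracle(p, 0.05))
  }
  expect_identical(bh_fdr(0.04, 0.05)$rejected, TRUE)
  expect_identical(bh_fdr(0.06, 0.05)$rejected, FALSE)
  expect_true(all(bh_fdr(rep(0.001, 54))$rejected))
  expect_length(bh_fdr(numeric(0))$rejected, 0)
})

test_that("BH-FDR controls the empirical false discovery rate", {
  set.seed(31)
  m <- 54; m1 <- 10
  fdp <- replicate(500, {
    p <- c(runif(m - m1), rbeta(m1, 0.05, 1))
    truth <- c(rep(FALSE, m - m1), rep(TRUE, m1))
    rej <- bh_fdr(p, 0.05)$rejected
    if (sum(rej) == 0) 0 else sum(rej & !truth) / sum(rej)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(500))
})

test_that("effect size arithmetic is correct", {
  expect_equal(partial_eta_squared(0, 1, 39), 0)
  f <- 7.3
  expect_equal(partial_eta_squared(f, 2, 30), f * 2 / (f * 2 + 30))
  expect_equal(cohens_d(1, 1, 10, 0, 1, 10), 1)
  expect_equal(cohens_d(5, 2, 8, 5, 3, 12), 0)
  # recompute from raw draws
  set.seed(2)
  g1 <- rnorm(14, 8, 7); g2 <- rnorm(14, 2, 7)
  d <- cohens_d(mean(g1), sd(g1), 14, mean(g2), sd(g2), 14)
  sp <- sqrt((13 * var(g1) + 13 * var(g2)) / 26)
  expect_equal(d, (mean(g1) - mean(g2)) / sp, tolerance = 1e-12)
})

test_that("responder rule is a 25% raw reduction, boundary inclusive", {
  expect_true(classify_responders(80, 60)$responder)
  expect_false(classify_responders(80, 61)$responder)
  r <- classify_responders(rep(80, 15), c(rep(55, 6), rep(75, 9)))
  expect_equal(r$rate_pct, 40.0)
  expect_error(classify_responders(0, 1), "positive")
})

test_that("fisher exact reproduces hand-enumerated two-sided p-values", {
  expect_equal(fisher_exact(1, 0, 0, 1)$p, 1.0)
  expect_equal(fisher_exact(5, 0, 0, 5)$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
  expect_equal(fisher_exact(6, 9, 1, 13)$odds_ratio, 6 * 13 / 9)
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
})

test_that("mixed ANOVA matches aov error strata on a fixed toy table", {
  # 2 groups x 3 subjects, hand-fixed values
  pre <- c(10, 12, 11, 20, 22, 21)
  post <- c(8, 9, 10, 20, 23, 19)
  g <- rep(c("A", "B"), each = 3)
  ma <- mixed_anova(pre, post, g)
  long <- data.frame(y = c(pre, post),
                     time = factor(rep(c("pre", "post"), each = 6)),
                     group = factor(rep(g, 2)),
                     subj = factor(rep(1:6, 2)))
  sm <- summary(aov(y ~ group * time + Error(subj), data = long))
  btw <- sm$`Error: subj`[[1]]
  wth <- sm$`Error: Within`[[1]]
  expect_equal(ma$anova$f[ma$anova$effect == "Group"], btw["group", "F value"],
               tolerance = 1e-10)
  expect_equal(ma$anova$f[ma$anova$effect == "Time"], wth["time", "F value"],
               tolerance = 1e-10)
  expect_equal(ma$anova$f[ma$anova$effect == "Time:Group"],
               wth["group:time", "F value"], tolerance = 1e-10)
  expect_equal(ma$anova$p[2], wth["time", "Pr(>F)"], tolerance = 1e-10)
})

test_that("mixed ANOVA degenerates gracefully and validates groups", {
  ma <- mixed_anova(rep(5, 6), rep(5, 6), rep(c("A", "B"), 3))
  expect_equal(ma$anova$f, c(0, 0, 0))
  expect_error(mixed_anova(1:3, 2:4, c("A", "A", "B")), "at least 2")
})

test_that("cluster permutation matches exhaustive enumeration on small designs", {
  # 6 subjects, two groups of 3, 3 channels in a chain
  set.seed(9)
  data <- matrix(rnorm(18), 6, 3) + cbind(rep(c(1.8, 0), each = 3), 0, 0)
  colnames(data) <- c("c1", "c2", "c3")
  adj <- matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 3, 3)
  dimnames(adj) <- list(colnames(data), colnames(data))
  g <- rep(c("A", "B"), each = 3)

  # independent brute-force oracle over all 20 relabelings
  tstat <- function(lab) {
    apply(data, 2, function(v) {
      i1 <- lab == "A"
      sp2 <- (2 * var(v[i1]) + 2 * var(v[!i1])) / 4
      (mean(v[i1]) - mean(v[!i1])) / sqrt(sp2 * (2 / 3))
    })
  }
  thr <- qt(0.975, 4)
  mass_of <- function(st) {
    best <- 0
    for (s in c(1, -1)) {
      above <- which(s * st >= thr)
      if (length(above) == 0) next
      # chain adjacency: consecutive indices cluster together
      groups <- split(above, cumsum(c(1, diff(above) != 1)))
      for (gr in groups) best <- max(best, abs(sum(st[gr])))
    }
    best
  }
  labs <- combn(6, 3, function(i) { l <- rep("B", 6); l[i] <- "A"; l },
                simplify = FALSE)
  null_max <- vapply(labs, function(l) mass_of(tstat(l)), numeric(1))
  obs <- mass_of(tstat(g))
  p_oracle <- mean(null_max >= obs - 1e-12)

  res_ex <- cluster_permutation(data, "two-group", adj, groups = g,
                                alpha_cf = 0.05, exact = TRUE)
  expect_gt(length(res_ex$clusters), 0)
  expect_equal(res_ex$clusters[[1]]$p_mc, p_oracle, tolerance = 1e-12)

  res_mc <- cluster_permutation(data, "two-group", adj, groups = g,
                                alpha_cf = 0.05, n_perm = 2000, seed = 3)
  expect_lt(abs(res_mc$clusters[[1]]$p_mc - p_oracle), 0.05)
})

test_that("cluster permutation handles degenerate inputs", {
  m <- test_montage()
  data <- matrix(0, 8, 64, dimnames = list(NULL, m$channels$label))
  res <- suppressWarnings(cluster_permutation(data, "paired", m$adjacency,
                                              n_perm = 50, seed = 1))
  expect_length(res$clusters, 0)
  # a planted constant channel is excluded with a warning
  set.seed(4)
  data <- matrix(rnorm(8 * 64), 8, 64, dimnames = list(NULL, m$channels$label))
  data[, "Cz"] <- 3
  expect_warning(
    cluster_permutation(data, "correlation", m$adjacency,
                        covariate = rnorm(8), n_perm = 50, seed = 1),
    "Cz")
  expect_error(suppressWarnings(cluster_permutation(data, "bogus", m$adjacency,
                                                    covariate = rnorm(8))),
               "design")
})

test_that("paired-design cluster statistics flip sign with the data", {
  m <- test_montage()
  set.seed(12)
  data <- matrix(rnorm(10 * 64, mean = 0.8), 10, 64,
                 dimnames = list(NULL, m$channels$label))
  r1 <- cluster_permutation(data, "paired", m$adjacency, n_perm = 200, seed = 5)
  r2 <- cluster_permutation(-data, "paired", m$adjacency, n_perm = 200, seed = 5)
  expect_equal(unname(r1$stat), unname(-r2$stat), tolerance = 1e-12)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "mass"),
               -vapply(r2$clusters, `[[`, numeric(1), "mass"), tolerance = 1e-12)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p_mc"),
               vapply(r2$clusters, `[[`, numeric(1), "p_mc"))
})
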