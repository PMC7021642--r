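# Statistical machinery: cluster-based Monte-Carlo permutation tests on scalp
# maps, partial correlation, BH-FDR, effect sizes, responder classification,
# Fisher exact test, and the two-way mixed ANOVA for clinical outcomes.

#' First-order partial correlation
#'
#' Correlation between `x` and `y` controlling for a single covariate `z`,
#' by the standard first-order formula
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' with a two-tailed parametric p-value from the t transform on n - 3 degrees
#' of freedom.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4), finite values
#' @return list with `r`, `t`, `df`, `p`
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (!all(is.finite(c(x, y, z)))) stop("non-finite values in input")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control variable is collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, t = tval, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: adjusted q-values and the rejection set at level `q`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @param q FDR level (default 0.05)
#' @return list with `q_values` (BH-adjusted), `rejected` (logical), `q`
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(list(q_values = numeric(0), rejected = logical(0), q = q))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(pvals, method = "BH")
  list(q_values = qv, rejected = !is.na(qv) & qv <= q, q = q)
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta^2_p = F \cdot df_1 / (F \cdot df_1 + df_2)}.
#'
#' @param f F statistic (>= 0)
#' @param df1,df2 numerator and denominator degrees of freedom
#' @return partial eta squared in \[0, 1\]
#' @export
partial_eta_squared <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Cohen's d with pooled standard deviation
#'
#' @param mean1,sd1,n1 summary statistics of group 1
#' @param mean2,sd2,n2 summary statistics of group 2
#' @return standardized mean difference (group 1 minus group 2)
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean1 - mean2) / sp
}

#' Responder classification from raw symptom scores
#'
#' A responder shows a reduction of at least 25% of the baseline raw total
#' symptom score (boundary inclusive).
#'
#' @param pre_raw,post_raw raw total scores before/after treatment (`pre_raw > 0`)
#' @return list with `responder` (logical vector) and `rate_pct` (percentage)
#' @export
classify_responders <- function(pre_raw, post_raw) {
  if (any(pre_raw <= 0)) stop("pre-treatment raw scores must be positive")
  resp <- (pre_raw - post_raw) / pre_raw >= 0.25
  list(responder = resp, rate_pct = 100 * mean(resp))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule (sum of hypergeometric
#' probabilities of tables no more likely than the observed one, conditional
#' on the margins) and the sample odds ratio `ad/bc`.
#'
#' @param a,b,c,d cell counts of the 2x2 table, rows = groups,
#'   columns = responder yes/no
#' @return list with `p` and `odds_ratio`
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero table")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  list(p = p, odds_ratio = or)
}

#' Two-way mixed ANOVA for a pre/post design
#'
#' Classical sums-of-squares decomposition for designs with one within-subject
#' factor (time: pre, post) and one between-subject factor (group), plus
#' Bonferroni-corrected per-group pre-vs-post contrasts tested against the
#' within-subject error term. Unequal group sizes are handled by the standard
#' (sequential) between-group sums of squares; results match
#' `aov(y ~ group*time + Error(subject))` on the same data.
#'
#' @param pre,post numeric vectors of per-subject scores at the two time points
#' @param group factor or character vector of group labels
#' @return list with `anova` (data frame: effect, ss, df1, df2, f, p,
#'   eta_p_sq) and `posthoc` (per-group time contrasts, Bonferroni-corrected)
#' @export
mixed_anova <- function(pre, post, group) {
  n <- length(pre)
  stopifnot(length(post) == n, length(group) == n)
  group <- factor(group)
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects")
  k <- nlevels(group)

  s_mean <- (pre + post) / 2          # subject means (between-subject part)
  d <- post - pre                     # within-subject change
  gm <- mean(s_mean)
  g_mean <- tapply(s_mean, group, mean)
  ng <- tabulate(group)

  ss_group <- 2 * sum(ng * (g_mean - gm)^2)
  ss_subj <- 2 * sum((s_mean - g_mean[group])^2)
  df_group <- k - 1; df_subj <- n - k

  d_gmean <- tapply(d, group, mean)
  d_grand <- mean(d)                  # weighted grand mean (sequential SS)
  ss_time <- n * d_grand^2 / 2
  ss_int <- sum(ng * (d_gmean - d_grand)^2) / 2
  ss_err_w <- sum((d - d_gmean[group])^2) / 2
  df_err_w <- n - k

  fstat <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err == 0) {
      f <- if (ss_eff == 0) 0 else Inf
    } else f <- (ss_eff / df_eff) / (ss_err / df_err)
    p <- if (is.finite(f)) stats::pf(f, df_eff, df_err, lower.tail = FALSE) else 0
    eta <- if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
    c(f = f, p = p, eta = eta)
  }
  rows <- rbind(
    Group        = fstat(ss_group, df_group, ss_subj, df_subj),
    Time         = fstat(ss_time, 1, ss_err_w, df_err_w),
    `Time:Group` = fstat(ss_int, df_group, ss_err_w, df_err_w)
  )
  anova_tab <- data.frame(
    effect = rownames(rows),
    ss = c(ss_group, ss_time, ss_int),
    df1 = c(df_group, 1, df_group),
    df2 = c(df_subj, df_err_w, df_err_w),
    f = rows[, "f"], p = rows[, "p"], eta_p_sq = rows[, "eta"],
    row.names = NULL
  )

  ph <- lapply(levels(group), function(g) {
    nj <- sum(group == g)
    ss_c <- nj * d_gmean[[g]]^2 / 2
    st <- fstat(ss_c, 1, ss_err_w, df_err_w)
    data.frame(group = g, mean_change = d_gmean[[g]], f = st[["f"]],
               df1 = 1, df2 = df_err_w, p = st[["p"]],
               p_bonferroni = min(1, k * st[["p"]]),
               eta_p_sq = st[["eta"]])
  })
  list(anova = anova_tab, posthoc = do.call(rbind, ph))
}

# ---- cluster-based permutation -------------------------------------------

.channel_stats <- function(data, design, covariate, groups, alpha_cf) {
  n <- nrow(data)
  if (design == "correlation") {
    if (stats::sd(covariate) == 0) stop("covariate has zero variance")
    stat <- as.vector(stats::cor(covariate, data))
    tcrit <- stats::qt(1 - alpha_cf / 2, n - 2)
    thresh <- tcrit / sqrt(n - 2 + tcrit^2)
  } else if (design == "two-group") {
    g <- factor(groups)
    stopifnot(nlevels(g) == 2)
    i1 <- g == levels(g)[1]; i2 <- !i1
    n1 <- sum(i1); n2 <- sum(i2)
    m1 <- colMeans(data[i1, , drop = FALSE]); m2 <- colMeans(data[i2, , drop = FALSE])
    v1 <- apply(data[i1, , drop = FALSE], 2, stats::var)
    v2 <- apply(data[i2, , drop = FALSE], 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    thresh <- stats::qt(1 - alpha_cf / 2, n1 + n2 - 2)
  } else if (design == "paired") {
    m <- colMeans(data)
    s <- apply(data, 2, stats::sd)
    stat <- m / (s / sqrt(n))
    thresh <- stats::qt(1 - alpha_cf / 2, n - 1)
  } else if (design == "anova") {
    g <- factor(groups)
    k <- nlevels(g)
    gm <- colMeans(data)
    ssb <- ssw <- 0
    for (lev in levels(g)) {
      idx <- g == lev
      mg <- colMeans(data[idx, , drop = FALSE])
      ssb <- ssb + sum(idx) * (mg - gm)^2
      ssw <- ssw + colSums(sweep(data[idx, , drop = FALSE], 2, mg)^2)
    }
    stat <- (ssb / (k - 1)) / (ssw / (n - k))
    thresh <- stats::qf(1 - alpha_cf, k - 1, n - k)
  } else stop("unknown design: ", design)
  list(stat = stat, threshold = thresh)
}

# connected components of the suprathreshold subgraph; the subgraphs are
# small (a handful of channels), so a direct flood fill beats building a
# graph object for every permutation
.components <- function(sub) {
  n <- nrow(sub)
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cid <- cid + 1
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(sub[v, ] & comp == 0)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

.cluster_masses <- function(stat, thresh, adjacency, signed) {
  clusters <- list()
  signs <- if (signed) c(1, -1) else 1
  for (s in signs) {
    above <- which(is.finite(stat) & s * stat >= thresh)
    if (length(above) == 0) next
    comp <- .components(adjacency[above, above, drop = FALSE])
    for (cid in unique(comp)) {
      idx <- above[comp == cid]
      clusters[[length(clusters) + 1]] <-
        list(channels = idx, mass = sum(stat[idx]))
    }
  }
  clusters
}

#' Cluster-based Monte-Carlo permutation test on scalp maps
#'
#' Per-channel statistics (Pearson r against a covariate, independent-samples
#' t, paired/one-sample t, or one-way F across groups) are thresholded at the
#' two-tailed `alpha_cf` critical value, suprathreshold channels are clustered
#' by spatial adjacency separately per sign, cluster mass is the sum of member
#' statistics, and the Monte-Carlo null distribution is the maximum absolute
#' cluster mass over random relabelings (covariate shuffles, group-label
#' shuffles, or sign flips, according to the design).
#'
#' The Monte-Carlo p-value uses the (1 + count) / (1 + n_perm) estimator. With
#' `exact = TRUE` all distinct relabelings are enumerated instead (feasible for
#' small samples only) and the p-value is the exact proportion including the
#' identity relabeling.
#'
#' @param data numeric matrix, subjects x channels (for `design = "paired"`,
#'   per-subject difference scores)
#' @param design one of `"correlation"`, `"two-group"`, `"paired"`, `"anova"`
#' @param adjacency symmetric logical channel adjacency matrix
#' @param covariate per-subject covariate (correlation design)
#' @param groups per-subject group labels (two-group / anova designs)
#' @param alpha_cf cluster-forming significance level (two-tailed)
#' @param n_perm number of random relabelings
#' @param seed integer seed for the relabeling generator
#' @param exact enumerate all relabelings instead of sampling
#' @return object of class `cluster_result`: per-channel `stat`, `threshold`,
#'   `clusters` (list of channel index set, labels, mass, `p_mc`), `excluded`
#'   channels, `n_perm`, `seed`, `design`
#' @export
cluster_permutation <- function(data, design, adjacency, covariate = NULL,
                                groups = NULL, alpha_cf = 0.05, n_perm = 1000,
                                seed = 1, exact = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data); nc <- ncol(data)
  if (n < 5 && !exact) stop("need at least 5 subjects")
  if (nrow(adjacency) != nc) stop("adjacency does not cover all channels")
  labels <- colnames(data)
  if (is.null(labels)) labels <- as.character(seq_len(nc))

  # exclude zero-variance channels from the statistic map entirely
  sds <- apply(data, 2, stats::sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  if (length(excluded) > 0) {
    warning("excluding zero-variance channel(s): ",
            paste(labels[excluded], collapse = ", "))
  }
  keep <- setdiff(seq_len(nc), excluded)
  data <- data[, keep, drop = FALSE]
  adjacency <- adjacency[keep, keep, drop = FALSE]

  full_stat <- function(st) {
    out <- rep(NA_real_, nc)
    out[keep] <- st
    stats::setNames(out, labels)
  }

  cs <- .channel_stats(data, design, covariate, groups, alpha_cf)
  signed <- design != "anova"
  obs <- .cluster_masses(cs$stat, cs$threshold, adjacency, signed)
  if (length(obs) == 0) {
    res <- list(stat = full_stat(cs$stat), threshold = cs$threshold,
                clusters = list(), excluded = labels[excluded],
                n_perm = n_perm, seed = seed, design = design)
    return(structure(res, class = "cluster_result"))
  }

  relabelings <- NULL
  if (exact) {
    if (design == "two-group") {
      g <- factor(groups)
      n1 <- sum(g == levels(g)[1])
      combs <- utils::combn(n, n1)
      relabelings <- lapply(seq_len(ncol(combs)), function(j) {
        gg <- rep(levels(g)[2], n); gg[combs[, j]] <- levels(g)[1]; gg
      })
    } else if (design == "paired") {
      relabelings <- lapply(0:(2^n - 1), function(b) {
        ifelse(bitwAnd(b, bitwShiftL(1, 0:(n - 1))) > 0, -1, 1)
      })
    } else if (design == "correlation") {
      if (n > 8) stop("exact enumeration of covariate permutations limited to n <= 8")
      perms <- .all_permutations(n)
      relabelings <- lapply(seq_len(nrow(perms)), function(i) perms[i, ])
    } else stop("exact enumeration not supported for design ", design)
    n_perm <- length(relabelings)
  }

  max_mass <- function(st) {
    cl <- .cluster_masses(st, cs$threshold, adjacency, signed)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }

  perm_stat <- function(i) {
    if (design == "correlation") {
      cov_p <- if (exact) covariate[relabelings[[i]]] else sample(covariate)
      .channel_stats(data, design, cov_p, NULL, alpha_cf)$stat
    } else if (design %in% c("two-group", "anova")) {
      g_p <- if (exact) relabelings[[i]] else sample(groups)
      .channel_stats(data, design, NULL, g_p, alpha_cf)$stat
    } else {
      flips <- if (exact) relabelings[[i]] else sample(c(-1, 1), n, replace = TRUE)
      .channel_stats(data * flips, design, NULL, NULL, alpha_cf)$stat
    }
  }

  if (!exact) set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) max_mass(perm_stat(i)), numeric(1))

  clusters <- lapply(obs, function(cl) {
    if (exact) {
      p <- mean(null_max >= abs(cl$mass) - 1e-12)
    } else {
      p <- (1 + sum(null_max >= abs(cl$mass) - 1e-12)) / (1 + n_perm)
    }
    list(channels = labels[keep[cl$channels]], channel_index = keep[cl$channels],
         mass = cl$mass, p_mc = p)
  })
  ord <- order(-abs(vapply(clusters, `[[`, numeric(1), "mass")))
  res <- list(stat = full_stat(cs$stat), threshold = cs$threshold,
              clusters = clusters[ord], excluded = labels[excluded],
              n_perm = n_perm, seed = seed, design = design)
  structure(res, class = "cluster_result")
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1
      out[r, ] <- append(sub[i, ], n, after = pos - 1)
    }
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> design=%s, threshold=%.3f, %d cluster(s), n_perm=%d\n",
              x$design, x$threshold, length(x$clusters), x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  %2d channels, mass=%8.2f, p_mc=%.4g  [%s%s]\n",
                length(cl$channels), cl$mass, cl$p_mc,
                paste(utils::head(cl$channels, 6), collapse = ","),
                if (length(cl$channels) > 6) ",..." else ""))
  }
  invisible(x)
}

#' Significant cluster channels
#' @param result a `cluster_result`
#' @param alpha significance level for the Monte-Carlo p-values
#' @return character vector of channels belonging to significant clusters
#' @export
significant_channels <- function(result, alpha = 0.05) {
  sig <- Filter(function(cl) cl$p_mc <= alpha, result$clusters)
  unique(unlist(lapply(sig, `[[`, "channels")))
}

#' Tidy export of a cluster result
#' @param result a `cluster_result`
#' @return data frame (channel, statistic, cluster_id, cluster_p)
#' @export
cluster_table <- function(result) {
  df <- data.frame(channel = names(result$stat), statistic = unname(result$stat),
                   cluster_id = NA_integer_, cluster_p = NA_real_)
  for (i in seq_along(result$clusters)) {
    idx <- match(result$clusters[[i]]$channels, df$channel)
    df$cluster_id[idx] <- i
    df$cluster_p[idx] <- result$clusters[[i]]$p_mc
  }
  df
}
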