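# End-to-end orchestration: simulate -> preprocess -> analyze -> report,
# with a single serializable configuration, deterministic seeding, and
# tidy CSV/JSON outputs.

#' Pipeline configuration
#'
#' Bundles the cohort configuration with the analysis settings: band
#' definitions, segmentation windows, reference schemes, permutation
#' settings, and the TEP component table. Serializable to JSON; every run
#' copies its configuration into the output directory.
#'
#' @param cohort a `cohort_config`
#' @param bands band definition table
#' @param reference_schemes subset of `c("AVR", "CSD")` to analyze
#' @param n_perm,alpha_cf,fdr_q statistical settings
#' @param marker_channel channel for ITI dynamics (default FC4)
#' @param tep_channel channel for TEP component summaries (default F4)
#' @param epoch_len,start_gap,end_gap ITI segmentation windows (s)
#' @param components TEP component table
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            bands = default_bands(),
                            reference_schemes = c("AVR", "CSD"),
                            n_perm = 1000, alpha_cf = 0.05, fdr_q = 0.05,
                            marker_channel = "FC4", tep_channel = "F4",
                            epoch_len = 2, start_gap = 1, end_gap = 5,
                            components = tep_components()) {
  stopifnot(all(reference_schemes %in% c("AVR", "CSD")))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.named_cohort_fields <- c("n_per_group", "beta0", "group_gamma_scale",
                          "n75_reduction")

#' Serialize / restore a pipeline configuration
#' @param config a `pipeline_config`
#' @param path JSON file path
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  raw$cohort <- unclass(raw$cohort)
  # keep names of named vectors through JSON (objects, not arrays)
  for (f in .named_cohort_fields) raw$cohort[[f]] <- as.list(raw$cohort[[f]])
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in .named_cohort_fields) raw$cohort[[f]] <- unlist(raw$cohort[[f]])
  if (length(raw$cohort$beta1) == 0) raw$cohort["beta1"] <- list(NULL)
  cohort <- do.call(cohort_config, raw$cohort[setdiff(names(raw$cohort), character(0))])
  cfg <- pipeline_config(
    cohort = cohort,
    bands = as.data.frame(raw$bands),
    reference_schemes = raw$reference_schemes,
    n_perm = raw$n_perm, alpha_cf = raw$alpha_cf, fdr_q = raw$fdr_q,
    marker_channel = raw$marker_channel, tep_channel = raw$tep_channel,
    epoch_len = raw$epoch_len, start_gap = raw$start_gap,
    end_gap = raw$end_gap, components = as.data.frame(raw$components))
  cfg
}

#' Simulate a cohort to disk
#'
#' Generates the full synthetic cohort and writes it under `out_dir`:
#' per-subject session recordings (RDS), the clinical table (CSV), the
#' ground truth (JSON), the configuration, and a manifest with file
#' checksums and the seed.
#'
#' @param config a `pipeline_config`
#' @param out_dir output directory (created if missing)
#' @param sessions sessions to synthesize
#' @return the manifest, invisibly
#' @export
run_simulate <- function(config, out_dir,
                         sessions = c("rest", "tep", "treatment")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  montage <- standard_montage()
  co <- generate_cohort(config$cohort, montage, eeg = FALSE)
  utils::write.csv(co$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  gt <- co$ground_truth
  gt$traits <- as.list(gt$traits)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, file.path(out_dir, "config.json"))

  traits <- co$ground_truth$traits
  seed <- config$cohort$seed
  files <- c("clinical.csv", "ground_truth.json", "config.json")
  wanted <- c(if ("rest" %in% sessions) "rest",
              if ("tep" %in% sessions) c("tep_pre", "tep_post"),
              if ("treatment" %in% sessions) "treatment")
  for (i in seq_len(nrow(traits))) {
    sdir <- file.path(out_dir, traits$subject[i])
    dir.create(sdir, showWarnings = FALSE)
    for (sess in wanted) {
      rec <- cohort_session(co, i, sess, config$cohort, montage)
      saveRDS(rec, file.path(sdir, paste0(sess, ".rds")))
      files <- c(files, file.path(traits$subject[i], paste0(sess, ".rds")))
    }
  }
  manifest <- list(seed = seed, n_subjects = nrow(traits),
                   sessions = sessions, files = files,
                   md5 = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.subject_band_powers <- function(rec, config, montage, scheme, csd_tr,
                                 what = c("first_iti", "rest")) {
  ref <- function(ep) {
    if (scheme == "AVR") apply_average_reference(ep)
    else apply_csd(ep, montage, transform = csd_tr)
  }
  out <- list()
  if ("first_iti" %in% what) {
    ep <- first_segment(extract_iti_epochs(rec$treatment,
                                           epoch_len = config$epoch_len,
                                           start_gap = config$start_gap,
                                           end_gap = config$end_gap))
    out$first_iti <- welch_psd(ref(ep))
    out$iti_epochs <- ep
  }
  if ("rest" %in% what && !is.null(rec$rest)) {
    ep <- extract_rest_epochs(rec$rest, epoch_len = config$epoch_len)
    out$rest <- welch_psd(ref(ep))
  }
  out
}

#' Analyze a simulated cohort
#'
#' Runs the complete analysis battery on a cohort directory produced by
#' [run_simulate()]: per reference scheme, the marker map and its
#' whole-scalp outcome correlation clusters, the inter-hemispheric balance
#' table, ITI dynamics, rest-vs-treatment correlations, the resting alpha
#' balance model, the TEP N75 contrast, and the clinical layer (mixed
#' ANOVA, effect sizes, responder rates, Fisher tests). Missing sessions
#' skip the analyses that need them (logged in the summary). Results are
#' written as tidy CSVs plus a machine-readable `summary.json`.
#'
#' @param config a `pipeline_config`
#' @param cohort_dir directory produced by [run_simulate()]
#' @param out_dir results directory (default `cohort_dir`/results)
#' @return the summary list, invisibly
#' @export
run_analyze <- function(config, cohort_dir,
                        out_dir = file.path(cohort_dir, "results")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  montage <- standard_montage()
  csd_tr <- if ("CSD" %in% config$reference_schemes) csd_transform(montage) else NULL
  clinical <- utils::read.csv(file.path(cohort_dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  subjects <- clinical$subject
  summary <- list(seed = config$cohort$seed, skipped = list())

  has <- function(session) {
    all(file.exists(file.path(cohort_dir, subjects, paste0(session, ".rds"))))
  }
  have_treat <- has("treatment"); have_rest <- has("rest"); have_tep <- has("tep_pre")
  bands <- config$bands
  alpha_band <- bands[bands$name == "Alpha", ]
  gamma_band <- bands[bands$name == "LowGamma", ]

  # ---- clinical layer (no EEG needed) ----
  real <- clinical[clinical$group == "Real", ]
  ma <- mixed_anova(clinical$pre_t, clinical$post_t, clinical$group)
  utils::write.csv(ma$anova, file.path(out_dir, "clinical_anova.csv"), row.names = FALSE)
  utils::write.csv(ma$posthoc, file.path(out_dir, "clinical_posthoc.csv"), row.names = FALSE)
  grp_stats <- lapply(split(clinical, clinical$group), function(df)
    list(n = nrow(df), mean_improvement = mean(df$improvement),
         sd_improvement = stats::sd(df$improvement),
         responders = sum(df$responder),
         response_rate_pct = 100 * mean(df$responder)))
  d_sham <- cohens_d(grp_stats$Real$mean_improvement, grp_stats$Real$sd_improvement,
                     grp_stats$Real$n, grp_stats$Sham$mean_improvement,
                     grp_stats$Sham$sd_improvement, grp_stats$Sham$n)
  fe <- fisher_exact(grp_stats$Real$responders,
                     grp_stats$Real$n - grp_stats$Real$responders,
                     grp_stats$Sham$responders,
                     grp_stats$Sham$n - grp_stats$Sham$responders)
  summary$clinical <- list(
    anova = ma$anova, posthoc = ma$posthoc, groups = grp_stats,
    cohens_d_real_vs_sham = d_sham,
    fisher_real_vs_sham = fe)

  improvement <- stats::setNames(clinical$improvement, subjects)
  real_ids <- real$subject

  if (have_treat) {
    for (scheme in config$reference_schemes) {
      psd_iti <- list(); psd_rest <- list(); dyn_rows <- list()
      for (i in seq_along(subjects)) {
        s <- subjects[i]
        rec <- list(
          treatment = readRDS(file.path(cohort_dir, s, "treatment.rds")),
          rest = if (have_rest) readRDS(file.path(cohort_dir, s, "rest.rds")))
        bp <- .subject_band_powers(rec, config, montage, scheme, csd_tr,
                                   what = c("first_iti", if (have_rest) "rest"))
        psd_iti[[s]] <- bp$first_iti
        if (have_rest) psd_rest[[s]] <- bp$rest
        if (s %in% real_ids) {
          iti_all <- extract_iti_epochs(rec$treatment, epoch_len = config$epoch_len,
                                        start_gap = config$start_gap,
                                        end_gap = config$end_gap)
          iti_all <- if (scheme == "AVR") apply_average_reference(iti_all)
                     else apply_csd(iti_all, montage, transform = csd_tr)
          dyn_rows[[s]] <- segment_band_power(iti_all, bands[bands$name %in%
                                                c("Alpha", "LowGamma"), ],
                                              channel = config$marker_channel,
                                              subject = s)
        }
      }
      p_alpha <- t(vapply(psd_iti, band_power, numeric(64), band = alpha_band))
      p_gamma <- t(vapply(psd_iti, band_power, numeric(64), band = gamma_band))
      marker <- compute_marker(p_alpha, p_gamma)
      utils::write.csv(
        data.frame(subject = rep(rownames(marker), ncol(marker)),
                   channel = rep(colnames(marker), each = nrow(marker)),
                   marker = as.vector(marker)),
        file.path(out_dir, paste0("marker_", scheme, ".csv")), row.names = FALSE)

      mom <- marker_outcome_map(marker[real_ids, , drop = FALSE],
                                improvement[real_ids], montage,
                                n_perm = config$n_perm,
                                seed = config$cohort$seed,
                                alpha_cf = config$alpha_cf)
      utils::write.csv(cluster_table(mom),
                       file.path(out_dir, paste0("marker_outcome_map_", scheme, ".csv")),
                       row.names = FALSE)
      ihb <- interhemispheric_balance(marker[real_ids, , drop = FALSE],
                                      improvement[real_ids], montage,
                                      q = config$fdr_q)
      utils::write.csv(ihb, file.path(out_dir, paste0("interhemispheric_", scheme, ".csv")),
                       row.names = FALSE)
      dyn <- iti_dynamics(do.call(rbind, dyn_rows))
      utils::write.csv(dyn$summary, file.path(out_dir, paste0("iti_dynamics_", scheme, ".csv")),
                       row.names = FALSE)

      sch <- list(
        marker_fc4_mean = mean(marker[, config$marker_channel]),
        marker_outcome = list(
          r_fc4 = unname(mom$stat[config$marker_channel]),
          clusters = lapply(mom$clusters, function(cl)
            list(n_channels = length(cl$channels), mass = cl$mass, p_mc = cl$p_mc))),
        interhemispheric = list(
          r_fc4 = ihb$r_partial[ihb$channel == "FC4"],
          r_fc3 = ihb$r_partial[ihb$channel == "FC3"],
          n_significant = sum(ihb$significant, na.rm = TRUE)),
        dynamics_anova = dyn$anova)

      if (have_rest) {
        r_alpha <- t(vapply(psd_rest, band_power, numeric(64), band = alpha_band))
        r_gamma <- t(vapply(psd_rest, band_power, numeric(64), band = gamma_band))
        rt_alpha <- rest_treatment_correlation(r_alpha, p_alpha)
        rt_gamma <- rest_treatment_correlation(r_gamma, p_gamma)
        utils::write.csv(
          data.frame(channel = names(rt_alpha), r_alpha = unname(rt_alpha),
                     r_gamma = unname(rt_gamma)),
          file.path(out_dir, paste0("rest_treatment_", scheme, ".csv")),
          row.names = FALSE)
        rab <- resting_alpha_balance(r_alpha[real_ids, , drop = FALSE],
                                     improvement[real_ids], montage,
                                     q = config$fdr_q)
        utils::write.csv(rab, file.path(out_dir, paste0("resting_alpha_balance_", scheme, ".csv")),
                         row.names = FALSE)
        sch$rest_treatment <- list(mean_r_alpha = mean(rt_alpha),
                                   mean_r_gamma = mean(rt_gamma))
        sch$resting_alpha_balance <- list(
          r_fc4 = rab$r_partial[rab$channel == "FC4"],
          r_fc3 = rab$r_partial[rab$channel == "FC3"])
      } else {
        summary$skipped <- c(summary$skipped, "rest_treatment (no rest sessions)")
      }
      summary[[paste0("scheme_", scheme)]] <- sch
    }
  } else {
    summary$skipped <- c(summary$skipped, "eeg analyses (no treatment sessions)")
  }

  if (have_tep) {
    n75 <- config$components[config$components$name == "N75", ]
    waves_pre <- list(); waves_post <- list()
    for (s in subjects) {
      waves_pre[[s]] <- average_tep(extract_tep_epochs(
        readRDS(file.path(cohort_dir, s, "tep_pre.rds"))))
      waves_post[[s]] <- average_tep(extract_tep_epochs(
        readRDS(file.path(cohort_dir, s, "tep_post.rds"))))
    }
    amp_pre <- toi_amplitude_matrix(waves_pre, n75)
    amp_post <- toi_amplitude_matrix(waves_post, n75)
    groups <- stats::setNames(clinical$group, subjects)
    tc <- tep_contrast(amp_pre, amp_post, groups, montage,
                       contrast = c("Real", "Sham"), n_perm = config$n_perm,
                       seed = config$cohort$seed, alpha_cf = config$alpha_cf)
    utils::write.csv(cluster_table(tc),
                     file.path(out_dir, "tep_n75_real_vs_sham.csv"), row.names = FALSE)
    summary$tep <- list(n75_real_vs_sham = lapply(tc$clusters, function(cl)
      list(n_channels = length(cl$channels), mass = cl$mass, p_mc = cl$p_mc)))
  } else {
    summary$skipped <- c(summary$skipped, "tep contrasts (no tep sessions)")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

#' Render a human-readable report from a results bundle
#'
#' Deterministic text report with sections for every analysis present in the
#' results directory; per-channel value listings are already available as
#' the tidy CSVs written by [run_analyze()]. Missing sections are flagged.
#'
#' @param results_dir directory written by [run_analyze()]
#' @param out_file report path (default `results_dir`/report.txt)
#' @return path to the report, invisibly
#' @export
run_report <- function(results_dir, out_file = file.path(results_dir, "report.txt")) {
  sf <- file.path(results_dir, "summary.json")
  if (!file.exists(sf)) stop("missing results file: ", sf)
  s <- jsonlite::read_json(sf, simplifyVector = TRUE)
  lines <- c("ITI biomarker pipeline report",
             "=============================", "")
  if (!is.null(s$clinical)) {
    lines <- c(lines, "Clinical outcome (mixed ANOVA):",
               utils::capture.output(print(s$clinical$anova)),
               "", "Post-hoc time contrasts:",
               utils::capture.output(print(s$clinical$posthoc)),
               sprintf("Cohen's d (Real vs Sham): %.2f", s$clinical$cohens_d_real_vs_sham),
               sprintf("Fisher exact p (response rates, Real vs Sham): %.4g",
                       s$clinical$fisher_real_vs_sham$p), "")
  } else lines <- c(lines, "[missing] clinical section", "")
  for (scheme in c("AVR", "CSD")) {
    sch <- s[[paste0("scheme_", scheme)]]
    if (is.null(sch)) next
    lines <- c(lines, sprintf("Reference scheme %s:", scheme),
               sprintf("  marker-outcome r at FC4: %.3f", sch$marker_outcome$r_fc4),
               sprintf("  inter-hemispheric partial r FC4 / FC3: %.3f / %.3f",
                       sch$interhemispheric$r_fc4, sch$interhemispheric$r_fc3), "")
  }
  if (!is.null(s$tep)) {
    lines <- c(lines, "TEP N75 Real-vs-Sham contrast clusters:",
               utils::capture.output(print(as.data.frame(
                 do.call(rbind, lapply(s$tep$n75_real_vs_sham, as.data.frame))))), "")
  }
  if (length(s$skipped) > 0)
    lines <- c(lines, "Skipped analyses:", paste(" -", unlist(s$skipped)))
  writeLines(lines, out_file)
  invisible(out_file)
}
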