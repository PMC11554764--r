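#' Write the simulation summary to CSV reports
#'
#' Emits four CSV tables plus a plain-text run manifest:
#' \describe{
#'   \item{auc_summary.csv}{Mean and 2.5/97.5 percentiles of the AUC for
#'     raw scores, corrected scores, and their difference, for both
#'     contrasts (MCI-or-dementia vs healthy; MCI vs healthy).}
#'   \item{marginal_sens_spec.csv}{Marginal sensitivity and specificity
#'     per cutoff and score type.}
#'   \item{stratum_sens_spec.csv}{Sensitivity and specificity per
#'     age-group x education-years stratum, cutoff, and score type.}
#'   \item{cutoffs.csv}{The three thresholds per score type.}
#'   \item{manifest.txt}{Configuration echo, master seed, replication
#'     count, and the mean fitted correction coefficients.}
#' }
#' Re-running with the same configuration and seed reproduces identical
#' files.
#'
#' @param summary A [run_simulation()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
write_reports <- function(summary, outdir) {
  stopifnot(inherits(summary, "moca_summary"))
  ok <- dir.exists(outdir) ||
    suppressWarnings(dir.create(outdir, recursive = TRUE))
  if (!ok) stop("cannot create output directory: ", outdir)
  m <- summary$metrics

  pick <- function(metric) {
    i <- match(metric, m$metric)
    if (anyNA(i)) stop("metric missing from summary: ",
                       metric[which(is.na(i))[1]])
    m[i, c("mean", "p2.5", "p97.5", "n_defined")]
  }

  contrasts <- c(all = "mci_or_dementia_vs_healthy", mci = "mci_vs_healthy")
  scores <- c(raw = "raw", corrected = "corrected", diff = "difference")
  auc_grid <- expand.grid(scores = names(scores),
                          contrast = names(contrasts),
                          stringsAsFactors = FALSE)
  auc_tab <- cbind(
    data.frame(contrast = contrasts[auc_grid$contrast],
               scores = scores[auc_grid$scores]),
    pick(paste("auc", auc_grid$scores, auc_grid$contrast, sep = "_"))[
      , c("mean", "p2.5", "p97.5")]
  )

  op_grid <- expand.grid(metric = c("sensitivity", "specificity"),
                         score_type = c("raw", "corrected"),
                         cutoff_type = names(.cutoff_targets),
                         stringsAsFactors = FALSE)
  op_tab <- cbind(
    op_grid[, c("cutoff_type", "score_type", "metric")],
    pick(paste(ifelse(op_grid$metric == "sensitivity", "se", "sp"),
               op_grid$score_type, op_grid$cutoff_type, sep = "_"))[
      , c("mean", "p2.5", "p97.5")]
  )

  cut_grid <- expand.grid(score_type = c("raw", "corrected"),
                          cutoff_type = names(.cutoff_targets),
                          stringsAsFactors = FALSE)
  cut_tab <- cbind(
    cut_grid[, c("cutoff_type", "score_type")],
    pick(paste("cutoff", cut_grid$score_type, cut_grid$cutoff_type,
               sep = "_"))[, c("mean", "p2.5", "p97.5")]
  )

  st_grid <- expand.grid(metric = c("sensitivity", "specificity"),
                         edu_years = c(5, 8, 11, 13, 17),
                         age_group = age_group_levels(),
                         score_type = c("raw", "corrected"),
                         cutoff_type = names(.cutoff_targets),
                         stringsAsFactors = FALSE)
  st_tab <- cbind(
    st_grid[, c("cutoff_type", "score_type", "age_group", "edu_years",
                "metric")],
    pick(paste(ifelse(st_grid$metric == "sensitivity", "se", "sp"),
               st_grid$score_type, st_grid$cutoff_type, st_grid$age_group,
               st_grid$edu_years, sep = "_"))
  )

  cfg <- summary$config
  manifest <- c(
    "mocasim run manifest",
    sprintf("package version: %s",
            as.character(utils::packageVersion("mocasim"))),
    sprintf("equation: %s", cfg$equation$id),
    sprintf("residual_sd: %g", cfg$params$residual_sd),
    sprintf("offset_mci: %g", cfg$params$offset_mci),
    sprintf("offset_dementia: %g", cfg$params$offset_dementia),
    sprintf("round_and_clip: %s", cfg$round_and_clip),
    sprintf("n_dev: %d", cfg$n_dev),
    sprintf("n_val: %d", cfg$n_val),
    sprintf("n_reps: %d", cfg$n_reps),
    sprintf("master_seed: %d", cfg$master_seed),
    sprintf("mean fitted beta0: %.6f", summary_metric(summary, "fit_beta0")),
    sprintf("mean fitted beta_age: %.8g",
            summary_metric(summary, "fit_beta_age")),
    sprintf("mean fitted beta_edu: %.8g",
            summary_metric(summary, "fit_beta_edu")),
    sprintf("mean fitted residual SD: %.6f",
            summary_metric(summary, "fit_residual_sd"))
  )

  paths <- c(
    auc_summary = file.path(outdir, "auc_summary.csv"),
    marginal_sens_spec = file.path(outdir, "marginal_sens_spec.csv"),
    stratum_sens_spec = file.path(outdir, "stratum_sens_spec.csv"),
    cutoffs = file.path(outdir, "cutoffs.csv"),
    manifest = file.path(outdir, "manifest.txt")
  )
  utils::write.csv(auc_tab, paths["auc_summary"], row.names = FALSE)
  utils::write.csv(op_tab, paths["marginal_sens_spec"], row.names = FALSE)
  utils::write.csv(st_tab, paths["stratum_sens_spec"], row.names = FALSE)
  utils::write.csv(cut_tab, paths["cutoffs"], row.names = FALSE)
  writeLines(manifest, paths["manifest"])
  invisible(paths)
}
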