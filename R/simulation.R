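#' Configuration of a develop-then-validate simulation run
#'
#' Bundles everything one replication needs: the generating equation, the
#' residual and offset model, sample sizes, replication count, and the
#' master seed.  Defaults are the main-analysis settings: cubic-age /
#' log-education generating equation, residual SD 2.9, offsets 5.1 (MCI)
#' and 10.7 (dementia), development n = 5,000, validation n = 50,000,
#' 10,000 replications, no rounding or clipping.
#'
#' @param equation Equation id (see [normative_equation()]) or a
#'   `normative_equation` object.
#' @param residual_sd Residual standard deviation in points.
#' @param offset_mci,offset_dementia Status offsets in points.
#' @param round_and_clip If `TRUE`, raw scores are rounded to the nearest
#'   integer and truncated to `[0, 30]` (the robustness-check variant);
#'   corrected scores are always left continuous.
#' @param n_dev,n_val Development and validation sample sizes.
#' @param n_reps Number of replications.
#' @param master_seed Integer seed from which per-replication seeds are
#'   derived.
#' @param table A [load_joint_table()] result; defaults to the packaged
#'   population table.
#' @return An object of class `run_config`.
#' @export
run_config <- function(equation = "aiello",
                       residual_sd = 2.9,
                       offset_mci = 5.1,
                       offset_dementia = 10.7,
                       round_and_clip = FALSE,
                       n_dev = 5000,
                       n_val = 50000,
                       n_reps = 10000,
                       master_seed = 1,
                       table = NULL) {
  eq <- if (inherits(equation, "normative_equation")) equation
        else normative_equation(equation)
  if (n_dev < 1 || n_val < 1 || n_reps < 1) {
    stop("`n_dev`, `n_val` and `n_reps` must all be at least 1")
  }
  if (is.null(table)) table <- load_joint_table()
  params <- score_gen_params(residual_sd = residual_sd,
                             offset_mci = offset_mci,
                             offset_dementia = offset_dementia,
                             round_scores = round_and_clip,
                             clip_scores = round_and_clip)
  structure(
    list(equation = eq, params = params,
         round_and_clip = isTRUE(round_and_clip),
         n_dev = as.integer(n_dev), n_val = as.integer(n_val),
         n_reps = as.integer(n_reps),
         master_seed = as.integer(master_seed),
         table = table),
    class = "run_config"
  )
}

#' Preset simulation configurations
#'
#' Named variants of the main analysis: `"main"` (the defaults), `"eq2"`,
#' `"eq3"`, `"eq4"` (alternative generating equations), `"rounded"`
#' (integer scores truncated to `[0, 30]`), and `"sd34"` (residual SD
#' 3.4).
#'
#' @param preset Preset name.
#' @param ... Further arguments passed to [run_config()] (e.g. `n_reps`,
#'   `master_seed`), overriding the preset.
#' @return A [run_config()] object.
#' @export
preset_config <- function(preset = c("main", "eq2", "eq3", "eq4",
                                     "rounded", "sd34"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    main    = list(),
    eq2     = list(equation = "conti"),
    eq3     = list(equation = "santangelo"),
    eq4     = list(equation = "montemurro"),
    rounded = list(round_and_clip = TRUE),
    sd34    = list(residual_sd = 3.4)
  )
  do.call(run_config, utils::modifyList(base, list(...)))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: equation '%s', residual SD %.2f, offsets %.1f/%.1f\n",
    x$equation$id, x$params$residual_sd, x$params$offset_mci,
    x$params$offset_dementia))
  cat(sprintf("  n_dev = %d, n_val = %d, n_reps = %d, master seed = %d\n",
              x$n_dev, x$n_val, x$n_reps, x$master_seed))
  cat(sprintf("  rounding/clipping of raw scores: %s\n",
              if (x$round_and_clip) "on" else "off"))
  invisible(x)
}

# Target operating points: specificity 97.7% and 84.1% match the healthy
# mean minus 2 and 1 residual SDs under normality; sensitivity 84.1% is
# the screening-oriented third cutoff.
.cutoff_targets <- list(
  spec977 = list(kind = "specificity", target = 0.977),
  spec841 = list(kind = "specificity", target = 0.841),
  sens841 = list(kind = "sensitivity", target = 0.841)
)

# Counter-based per-replication seeds: reproducible independently of
# execution order, and each below 2^31.
replication_seeds <- function(master_seed, n_reps) {
  (as.numeric(master_seed) + seq_len(n_reps)) %% 2147483647
}

#' Run one develop-then-validate replication
#'
#' One end-to-end pass: sample a development cohort (n_dev) and an
#' independent validation cohort (n_val) from the population table,
#' generate raw scores, fit the normative correction on the healthy
#' development individuals, correct both cohorts, determine the three
#' marginal cutoffs per score type on the development sample, then
#' evaluate on the validation sample: both AUC contrasts (MCI-or-dementia
#' vs healthy; MCI vs healthy) for raw and corrected scores, and
#' sensitivity/specificity (marginal and per age-education stratum) at
#' every cutoff.
#'
#' @param config A [run_config()].
#' @param rep_seed Integer seed for this replication; the result is a
#'   pure function of `(config, rep_seed)`.
#' @return A list of class `moca_metrics`: `auc` (named vector of the six
#'   AUC metrics), `cutoffs` (named vector of the six thresholds),
#'   `operating` (marginal Se/Sp per score type and cutoff), `strata`
#'   (stratum Se/Sp table), and `fit` (the fitted correction model).
#' @export
run_replication <- function(config, rep_seed) {
  stopifnot(inherits(config, "run_config"))
  set.seed(as.integer(rep_seed %% 2147483647))

  dev <- sample_cohort(config$table, config$n_dev)
  dev <- generate_raw_scores(dev, config$equation, config$params)
  val <- sample_cohort(config$table, config$n_val)
  val <- generate_raw_scores(val, config$equation, config$params)

  if (!any(dev$status == "healthy") || !any(dev$status == "MCI")) {
    stop("development sample lacks healthy or MCI individuals; increase n_dev")
  }

  fit <- fit_normative(dev, config$equation)
  dev <- apply_correction(dev, fit)
  val <- apply_correction(val, fit)

  impaired <- val$status %in% c("MCI", "dementia")
  mci <- val$status == "MCI"
  healthy <- val$status == "healthy"
  auc_vals <- c(
    auc_raw_all = auc(val$raw_score[impaired], val$raw_score[healthy]),
    auc_corrected_all = auc(val$corrected_score[impaired],
                            val$corrected_score[healthy]),
    auc_raw_mci = auc(val$raw_score[mci], val$raw_score[healthy]),
    auc_corrected_mci = auc(val$corrected_score[mci],
                            val$corrected_score[healthy])
  )
  auc_vals <- c(auc_vals,
    auc_diff_all = unname(auc_vals["auc_raw_all"] - auc_vals["auc_corrected_all"]),
    auc_diff_mci = unname(auc_vals["auc_raw_mci"] - auc_vals["auc_corrected_mci"]))

  cutoffs <- numeric(0)
  operating <- list()
  strata <- list()
  for (score_type in c("raw", "corrected")) {
    col <- paste0(score_type, "_score")
    dev_healthy <- dev[[col]][dev$status == "healthy"]
    dev_mci <- dev[[col]][dev$status == "MCI"]
    for (cut_name in names(.cutoff_targets)) {
      tgt <- .cutoff_targets[[cut_name]]
      cut <- if (tgt$kind == "specificity") {
        find_cutoff_specificity(dev_healthy, tgt$target)
      } else {
        find_cutoff_sensitivity(dev_mci, tgt$target)
      }
      cutoffs[paste("cutoff", score_type, cut_name, sep = "_")] <- cut
      ss <- sens_spec(val, score_type, cut, stratified = TRUE)
      operating[[length(operating) + 1L]] <- data.frame(
        score_type = score_type, cutoff_type = cut_name, cutoff = cut,
        sensitivity = ss$sensitivity, specificity = ss$specificity)
      st <- ss$strata
      st$score_type <- score_type
      st$cutoff_type <- cut_name
      strata[[length(strata) + 1L]] <- st
    }
  }

  structure(
    list(auc = auc_vals,
         cutoffs = cutoffs,
         operating = do.call(rbind, operating),
         strata = do.call(rbind, strata),
         fit = fit),
    class = "moca_metrics"
  )
}

# Flatten one replication's metrics into a named numeric vector so
# replications can be stacked into a matrix and aggregated columnwise.
metrics_to_row <- function(m) {
  op <- m$operating
  op_names <- paste(rep(c("se", "sp"), each = nrow(op)),
                    op$score_type, op$cutoff_type, sep = "_")
  st <- m$strata
  st_key <- paste(st$score_type, st$cutoff_type, st$age_group, st$edu_years,
                  sep = "_")
  c(m$auc,
    m$cutoffs,
    stats::setNames(c(op$sensitivity, op$specificity), op_names),
    stats::setNames(st$sensitivity, paste0("se_", st_key)),
    stats::setNames(st$specificity, paste0("sp_", st_key)),
    fit_beta0 = m$fit$beta0,
    fit_beta_age = m$fit$beta_age,
    fit_beta_edu = m$fit$beta_edu,
    fit_residual_sd = m$fit$residual_sd_hat)
}

#' Run the full replicated simulation
#'
#' Executes `config$n_reps` independent replications with per-replication
#' seeds derived from the master seed by a counter scheme
#' (`(master_seed + i) mod (2^31 - 1)` for replication `i`), and
#' aggregates every metric across replications into its mean and
#' empirical 2.5th / 97.5th percentiles.  Stratum metrics undefined in a
#' replication (no members of the class in that stratum) are dropped from
#' that metric's aggregation.
#'
#' @param config A [run_config()].
#' @param progress_every Emit a progress message every this many
#'   replications (0 = silent).
#' @return An object of class `moca_summary`: the `config`, a `metrics`
#'   data frame (`metric`, `mean`, `p2.5`, `p97.5`, `n_defined`), and the
#'   full replication-by-metric matrix `replications`.
#' @examples
#' \donttest{
#' cfg <- run_config(n_dev = 500, n_val = 2000, n_reps = 5, master_seed = 42)
#' summ <- run_simulation(cfg)
#' subset(summ$metrics, metric == "auc_raw_all")
#' }
#' @export
run_simulation <- function(config, progress_every = 0) {
  stopifnot(inherits(config, "run_config"))
  seeds <- replication_seeds(config$master_seed, config$n_reps)
  rows <- vector("list", config$n_reps)
  for (i in seq_len(config$n_reps)) {
    rows[[i]] <- metrics_to_row(run_replication(config, seeds[i]))
    if (progress_every > 0 && i %% progress_every == 0) {
      message("replication ", i, " of ", config$n_reps)
    }
  }
  mat <- do.call(rbind, rows)
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  metrics <- data.frame(
    metric = colnames(mat),
    mean = colMeans(mat, na.rm = TRUE),
    p2.5 = qs[1, ],
    p97.5 = qs[2, ],
    n_defined = colSums(!is.na(mat)),
    row.names = NULL
  )
  structure(
    list(config = config, n_reps = config$n_reps,
         metrics = metrics, replications = mat),
    class = "moca_summary"
  )
}

#' @export
print.moca_summary <- function(x, ...) {
  cat(sprintf("Simulation summary over %d replications\n", x$n_reps))
  main <- x$metrics[x$metrics$metric %in%
                      c("auc_raw_all", "auc_corrected_all", "auc_diff_all",
                        "auc_raw_mci", "auc_corrected_mci", "auc_diff_mci"), ]
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-18s %.4f [%.3f, %.3f]\n", main$metric[i],
                main$mean[i], main$p2.5[i], main$p97.5[i]))
  }
  invisible(x)
}

#' Fetch one aggregated metric from a summary
#'
#' @param summary A [run_simulation()] result.
#' @param metric Metric name as in `summary$metrics$metric`, e.g.
#'   `"auc_raw_all"` or `"se_raw_spec841_85-89_5"`.
#' @param what `"mean"`, `"p2.5"`, or `"p97.5"`.
#' @return The requested number.
#' @export
summary_metric <- function(summary, metric, what = "mean") {
  stopifnot(inherits(summary, "moca_summary"))
  i <- match(metric, summary$metrics$metric)
  if (is.na(i)) stop("unknown metric: ", metric)
  summary$metrics[[what]][i]
}
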