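#' Mann-Whitney AUC for a low-score-positive test
#'
#' Area under the empirical ROC curve, oriented so that LOWER scores
#' indicate impairment: the probability that a randomly chosen positive
#' (impaired) individual scores below a randomly chosen negative
#' (healthy) one, with ties counted one half.  Computed from midranks,
#' which equals the trapezoidal area under the empirical ROC curve and
#' the brute-force all-pairs statistic.
#'
#' @param positive_scores Scores of the impaired class.
#' @param negative_scores Scores of the healthy class.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 3), c(2, 4))  # 3 of 4 pairs ordered correctly -> 0.75
#' @export
auc <- function(positive_scores, negative_scores) {
  n_pos <- length(positive_scores)
  n_neg <- length(negative_scores)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both score groups must be non-empty")
  }
  r <- rank(c(positive_scores, negative_scores))
  rank_sum_neg <- sum(r[(n_pos + 1L):(n_pos + n_neg)])
  (rank_sum_neg - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

#' Cutoff achieving a preselected specificity
#'
#' Returns the threshold `c` such that the proportion of healthy
#' development scores classified negative (score `>= c`) equals the
#' target specificity: the linearly interpolated empirical quantile
#' (type 7) of the healthy scores at probability `1 - target`.
#'
#' @param healthy_scores Healthy development-sample scores.
#' @param target_specificity Desired specificity in `(0, 1)`.
#' @return The cutoff in score points.
#' @export
find_cutoff_specificity <- function(healthy_scores, target_specificity) {
  if (length(healthy_scores) == 0L) stop("no healthy scores provided")
  if (length(target_specificity) != 1L || !is.finite(target_specificity) ||
      target_specificity <= 0 || target_specificity >= 1) {
    stop("`target_specificity` must lie strictly between 0 and 1")
  }
  stats::quantile(healthy_scores, probs = 1 - target_specificity,
                  type = 7, names = FALSE)
}

#' Cutoff achieving a preselected sensitivity
#'
#' Returns the threshold `c` such that the proportion of MCI development
#' scores classified positive (score `< c`) equals the target
#' sensitivity: the interpolated empirical quantile (type 7) of the MCI
#' scores at probability `target`.
#'
#' @param mci_scores MCI development-sample scores.
#' @param target_sensitivity Desired sensitivity in `(0, 1)`.
#' @return The cutoff in score points.
#' @export
find_cutoff_sensitivity <- function(mci_scores, target_sensitivity) {
  if (length(mci_scores) == 0L) stop("no MCI scores provided")
  if (length(target_sensitivity) != 1L || !is.finite(target_sensitivity) ||
      target_sensitivity <= 0 || target_sensitivity >= 1) {
    stop("`target_sensitivity` must lie strictly between 0 and 1")
  }
  stats::quantile(mci_scores, probs = target_sensitivity,
                  type = 7, names = FALSE)
}

#' Sensitivity and specificity at a cutoff, marginal and by stratum
#'
#' Evaluates the screen "positive if score < cutoff" (scores equal to the
#' cutoff are negative) for the MCI-versus-healthy contrast: individuals
#' with dementia are excluded, sensitivity is the fraction of MCI
#' individuals screening positive, specificity the fraction of healthy
#' individuals screening negative.  With `stratified = TRUE` the same
#' fractions are also computed within each age-group x education-years
#' stratum; strata with no members of a class carry `NA` for the
#' corresponding metric.
#'
#' The marginal sensitivity is exactly the stratum-size-weighted average
#' of the stratum sensitivities (weights: share of MCI individuals per
#' stratum), and analogously for specificity with healthy-count weights.
#'
#' @param cohort A cohort with the requested scores present.
#' @param score_type `"raw"` or `"corrected"`.
#' @param cutoff Threshold in score points.
#' @param stratified Also compute the 7 x 5 stratum table?
#' @return A list of class `sens_spec` with elements `sensitivity`,
#'   `specificity`, `n_mci`, `n_healthy`, `cutoff`, `score_type`, and
#'   (if requested) `strata`, a data frame with one row per age-education
#'   stratum.
#' @export
sens_spec <- function(cohort, score_type = c("raw", "corrected"), cutoff,
                      stratified = TRUE) {
  stopifnot(inherits(cohort, "moca_cohort"))
  score_type <- match.arg(score_type)
  col <- paste0(score_type, "_score")
  if (is.null(cohort[[col]])) {
    stop("cohort has no ", col, " column")
  }
  keep <- cohort$status %in% c("healthy", "MCI")
  cohort <- cohort[keep, , drop = FALSE]
  is_mci <- cohort$status == "MCI"
  if (!any(is_mci) || all(is_mci)) {
    stop("cohort must contain both MCI and healthy individuals")
  }
  positive <- cohort[[col]] < cutoff
  out <- list(
    sensitivity = mean(positive[is_mci]),
    specificity = mean(!positive[!is_mci]),
    n_mci = sum(is_mci),
    n_healthy = sum(!is_mci),
    cutoff = cutoff,
    score_type = score_type
  )
  if (stratified) {
    stratum <- interaction(cohort$age_group,
                           factor(cohort$edu_years, levels = c(5, 8, 11, 13, 17)),
                           sep = "/", drop = FALSE)
    n_mci_s  <- tapply(is_mci, stratum, sum, default = 0L)
    n_hea_s  <- tapply(!is_mci, stratum, sum, default = 0L)
    tp_s     <- tapply(positive & is_mci, stratum, sum, default = 0L)
    tn_s     <- tapply(!positive & !is_mci, stratum, sum, default = 0L)
    key <- strsplit(names(n_mci_s), "/", fixed = TRUE)
    out$strata <- data.frame(
      age_group = factor(vapply(key, `[`, "", 1L), levels = age_group_levels()),
      edu_years = as.numeric(vapply(key, `[`, "", 2L)),
      n_mci = as.integer(n_mci_s),
      n_healthy = as.integer(n_hea_s),
      sensitivity = ifelse(n_mci_s > 0, tp_s / n_mci_s, NA_real_),
      specificity = ifelse(n_hea_s > 0, tn_s / n_hea_s, NA_real_),
      row.names = NULL
    )
  }
  class(out) <- "sens_spec"
  out
}

#' @export
print.sens_spec <- function(x, ...) {
  cat(sprintf("%s scores, cutoff %.3f: sensitivity %.1f%%, specificity %.1f%% (%d MCI, %d healthy)\n",
              x$score_type, x$cutoff, 100 * x$sensitivity,
              100 * x$specificity, x$n_mci, x$n_healthy))
  if (!is.null(x$strata)) {
    cat("  stratum table: ", nrow(x$strata), " age x education cells\n", sep = "")
  }
  invisible(x)
}
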