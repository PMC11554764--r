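#' Load the joint population distribution
#'
#' Reads the packaged transcription of the joint distribution of sex,
#' five-year age group, completed education, and cognitive status for
#' Italian residents aged 55 to 89 (as of January 1st, 2023), and returns
#' it as a validated, normalized probability table.
#'
#' The fixture stores one row per cell with the probability in percent as
#' printed (three decimals), so the file stays diff-able against the
#' published table.  Because of printed rounding the raw percentages sum
#' to 100 only within a small slack; the loader rescales them so the
#' normalized probabilities sum to exactly 1.
#'
#' @param source Path to a CSV file with columns `sex`, `age_low`,
#'   `age_high`, `edu_years`, `edu_levels`, `status`, `percent`.  Defaults
#'   to the table shipped with the package.
#' @return A data frame of class `joint_table` with 210 rows (2 sexes x
#'   7 age groups x 5 education columns x 3 statuses) and an added `prob`
#'   column holding the normalized sampling probability of each cell.
#'   The pre-normalization percentage total is kept in the
#'   `percent_total` attribute.
#' @examples
#' tab <- load_joint_table()
#' sum(tab$prob)                       # exactly 1
#' # marginal prevalence of dementia, directly from the table
#' sum(tab$prob[tab$status == "dementia"])
#' @export
load_joint_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "table1_joint_distribution.csv",
                          package = "mocasim", mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop("joint distribution fixture not found: ", source)
  }
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  validate_joint_table(tab)
  total <- sum(tab$percent)
  tab$prob <- tab$percent / total
  tab$age_group <- age_group_label(tab$age_low, tab$age_high)
  attr(tab, "percent_total") <- total
  class(tab) <- c("joint_table", "data.frame")
  tab
}

# Grid the table must span: 2 x 7 x 5 x 3 = 210 cells.
.joint_table_spec <- list(
  sexes      = c("female", "male"),
  age_lows   = seq(55, 85, by = 5),
  edu_years  = c(5, 8, 11, 13, 17),
  edu_levels = c(1, 2, 3, 3, 4),
  statuses   = c("healthy", "MCI", "dementia"),
  # printed 3-decimal rounding slack on the percentage total
  percent_slack = 0.15
)

validate_joint_table <- function(tab) {
  needed <- c("sex", "age_low", "age_high", "edu_years", "edu_levels",
              "status", "percent")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("joint table is missing columns: ", paste(missing, collapse = ", "))
  }
  spec <- .joint_table_spec
  if (nrow(tab) != 210L) {
    stop("joint table must have 210 cells, found ", nrow(tab))
  }
  bad <- which(!(tab$sex %in% spec$sexes) |
                 !(tab$age_low %in% spec$age_lows) |
                 tab$age_high != tab$age_low + 4 |
                 !(tab$edu_years %in% spec$edu_years) |
                 !(tab$status %in% spec$statuses))
  if (length(bad)) {
    stop("joint table row ", bad[1], " has an unrecognized cell: ",
         paste(unlist(tab[bad[1], needed]), collapse = "/"))
  }
  key <- with(tab, paste(sex, age_low, edu_years, status))
  if (anyDuplicated(key)) {
    stop("joint table has duplicated cell: ", key[anyDuplicated(key)[1]])
  }
  lvl <- spec$edu_levels[match(tab$edu_years, spec$edu_years)]
  if (any(tab$edu_levels != lvl)) {
    i <- which(tab$edu_levels != lvl)[1]
    stop("joint table row ", i, ": education level ", tab$edu_levels[i],
         " does not match ", tab$edu_years[i], " years of education")
  }
  neg <- which(!is.finite(tab$percent) | tab$percent < 0)
  if (length(neg)) {
    stop("joint table row ", neg[1], " (", key[neg[1]],
         ") has an invalid probability: ", tab$percent[neg[1]])
  }
  total <- sum(tab$percent)
  if (abs(total - 100) > spec$percent_slack) {
    stop("joint table percentages sum to ", format(total),
         ", expected 100 within ", spec$percent_slack)
  }
  invisible(tab)
}

#' Age-group labels used throughout the package
#'
#' Seven five-year groups spanning ages 55 to 89.  Group `"a-b"` covers the
#' half-open real age interval `[a, b + 1)`: a person aged 89 years and 11
#' months still belongs to "85-89".
#'
#' @return Character vector of the 7 labels, ordered by age.
#' @export
age_group_levels <- function() {
  lows <- .joint_table_spec$age_lows
  age_group_label(lows, lows + 4)
}

age_group_label <- function(low, high) {
  sprintf("%d-%d", low, high)
}

#' Map continuous ages to age-group labels
#'
#' @param age Numeric vector of ages in `[55, 90)`.
#' @return Factor with the levels of [age_group_levels()].
#' @export
age_to_group <- function(age) {
  if (any(age < 55 | age >= 90)) {
    stop("ages must lie in [55, 90)")
  }
  low <- pmin(55 + 5 * floor((age - 55) / 5), 85)
  factor(age_group_label(low, low + 4), levels = age_group_levels())
}

#' @export
print.joint_table <- function(x, ...) {
  cat("Joint sex x age x education x cognitive-status distribution\n")
  cat(sprintf("  %d cells; transcribed percentages total %.3f%%\n",
              nrow(x), attr(x, "percent_total")))
  prev <- vapply(split(x$prob, x$status), sum, numeric(1))
  cat(sprintf("  marginal prevalence: healthy %.1f%%, MCI %.1f%%, dementia %.1f%%\n",
              100 * prev[["healthy"]], 100 * prev[["MCI"]],
              100 * prev[["dementia"]]))
  invisible(x)
}

#' Sample a cohort of individuals from the joint distribution
#'
#' Each individual is drawn independently: a single flattened categorical
#' draw over the 210 cells picks sex, age group, education, and cognitive
#' status, then a continuous age is drawn uniformly on the group's
#' half-open interval `[low, high + 1)`.  Scores are left unset; see
#' [generate_raw_scores()].
#'
#' @param table A normalized [load_joint_table()] result.
#' @param n Number of individuals (positive integer).
#' @return A data frame of class `moca_cohort` with columns `sex`, `age`
#'   (continuous years), `age_group` (factor), `edu_years`, `edu_levels`,
#'   and `status` (factor healthy/MCI/dementia).
#' @examples
#' tab <- load_joint_table()
#' set.seed(1)
#' cohort <- sample_cohort(tab, 1000)
#' table(cohort$status)
#' @export
sample_cohort <- function(table, n) {
  if (!inherits(table, "joint_table")) {
    stop("`table` must be a joint_table from load_joint_table()")
  }
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer")
  }
  idx <- sample.int(nrow(table), size = n, replace = TRUE, prob = table$prob)
  age <- stats::runif(n, min = table$age_low[idx], max = table$age_high[idx] + 1)
  cohort <- data.frame(
    sex        = table$sex[idx],
    age        = age,
    age_group  = factor(table$age_group[idx], levels = age_group_levels()),
    edu_years  = table$edu_years[idx],
    edu_levels = table$edu_levels[idx],
    status     = factor(as.character(table$status[idx]),
                        levels = c("healthy", "MCI", "dementia"))
  )
  class(cohort) <- c("moca_cohort", "data.frame")
  cohort
}
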