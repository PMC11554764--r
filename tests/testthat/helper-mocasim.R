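# Shared fixtures for the test suite.  Everything is generated in code;
# moderately expensive simulations are cached per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# A 50-replication run of the main configuration, shared by the
# simulation-level pattern tests.
main_sim_small <- function() {
  cached("main_small", function() {
    run_simulation(run_config(n_reps = 50, master_seed = 101))
  })
}

# Build a cohort data frame directly (bypassing sampling) for toy cases.
make_cohort <- function(age, edu_years, status, raw_score = NULL) {
  n <- max(length(age), length(edu_years), length(status))
  cohort <- data.frame(
    sex = rep("female", n),
    age = rep_len(age, n),
    age_group = age_to_group(rep_len(age, n)),
    edu_years = rep_len(edu_years, n),
    edu_levels = rep_len(1, n),
    status = factor(rep_len(as.character(status), n),
                    levels = c("healthy", "MCI", "dementia"))
  )
  if (!is.null(raw_score)) cohort$raw_score <- raw_score
  class(cohort) <- c("moca_cohort", "data.frame")
  cohort
}

# Write a modified copy of the packaged joint table to a temp CSV and
# load it through the public loader (so validation still runs).
# `mutate` receives the raw fixture data frame and returns a new one.
make_table <- function(mutate = identity) {
  src <- system.file("extdata", "table1_joint_distribution.csv",
                     package = "mocasim", mustWork = TRUE)
  tab <- utils::read.csv(src, stringsAsFactors = FALSE)
  tab <- mutate(tab)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  load_joint_table(path)
}

# Point-mass table: all probability on one cell.
point_mass_table <- function(sex = "male", age_low = 85, edu = 11,
                             status = "dementia") {
  make_table(function(tab) {
    tab$percent <- 0
    i <- tab$sex == sex & tab$age_low == age_low &
      tab$edu_years == edu & tab$status == status
    stopifnot(sum(i) == 1L)
    tab$percent[i] <- 100
    tab
  })
}

# Internal flattener, aliased for tests of the aggregation contract.
metrics_to_row_public <- function(m) mocasim:::metrics_to_row(m)

# Brute-force all-pairs AUC oracle (low score = positive).
auc_bruteforce <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}
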