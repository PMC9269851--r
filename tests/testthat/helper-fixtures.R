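# Shared fixture builders for the test suite.

# Deterministic symmetric-limit parameters: a 1 Hz stride is an integer
# number of samples at 100 Hz, so left and right cycles hit identical
# intra-cycle sample phases and interpolation error cancels between sides.
sym_params <- function(...) {
  gait_sim_params(stride_frequency = 1.0, noise_sd = 0, stride_jitter_cv = 0, ...)
}

# Small balanced split-plot fixture: G groups x n subjects x k conditions
make_rm_data <- function(G = 2, n = 4, k = 3, seed = 1, constant = NULL) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(G * n), condition = paste0("C", seq_len(k)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- paste0("G", ((d$subject - 1) %/% n) + 1)
  d$y <- if (is.null(constant)) round(rnorm(nrow(d), 10, 3), 1) else constant
  d$participant_id <- d$subject
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)
  d$group <- factor(d$group)
  d$si <- d$y
  d
}

# Synthetic participant-by-condition cohort table (no signal pipeline):
# used by the statistics tests that only need a CohortTable
make_cohort_table <- function(G = 7, n = 6, seed = 1, si_shift = NULL) {
  set.seed(seed)
  groups <- paste0("G", seq_len(G))
  conds <- c("Slow", "Comfortable", "Fast")
  d <- expand.grid(participant_id = seq_len(G * n), condition = conds,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- groups[((d$participant_id - 1) %/% n) + 1]
  subj_eff <- rnorm(G * n, 0, 1)
  d$si <- 95 + subj_eff[d$participant_id] + rnorm(nrow(d), 0, 0.8)
  if (!is.null(si_shift))
    d$si <- d$si + si_shift[cbind(match(d$group, groups), match(d$condition, conds))]
  d$normalized_speed <- 1 + 0.2 * rnorm(G * n)[d$participant_id] + rnorm(nrow(d), 0, 0.05)
  d
}

# Reduced null cohort used for type-I calibration runs
null_calibration_design <- function(n_per_group = 8) {
  groups <- gait_groups(c("Children", "Young Adults", "Middle-Aged", "Elderly"),
                        n = n_per_group)
  cohort_design(groups = groups, trials_per_condition = 1L, path_m = 6,
                profile = null_asymmetry_profile(groups = groups$group))
}

# Reduced study-pattern cohort (all 7 groups, elevated alpha in Fast for
# the affected groups)
pattern_design <- function(n_per_group = 4) {
  groups <- gait_groups(n = n_per_group)
  cohort_design(groups = groups, trials_per_condition = 1L, path_m = 6)
}

run_cohort_anova <- function(design, seed, dv = "si") {
  coh <- simulate_cohort(design, seed = seed, keep_truth = FALSE)
  res <- suppressMessages(process_cohort(coh))
  list(anova = mixed_anova(res$table, dv), table = res$table)
}
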