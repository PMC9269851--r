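#' Run the full processing chain over a simulated or loaded cohort
#'
#' Computes one [compute_trial_si()] result per trial, aggregates SI to the
#' participant-by-condition level, derives observed walking speeds from
#' path length and trial duration, fits the per-condition anthropometric
#' speed model and normalizes individual speed. The returned long-format
#' table (one row per participant x condition) is what the cohort
#' statistics operate on.
#'
#' @param cohort a [simulate_cohort()] object (traces kept), or any list
#'   with `participants`, `trials` and `traces` of the same shape.
#' @param config a [gait_config()]; its `aggregation` entry selects the
#'   trial combiner.
#' @param keep_si keep the per-trial `gait_si` objects in the result.
#' @return Object of class `gait_results`: list with `trials` (per-trial
#'   data frame: ids, `r`, `si`, cycle counts, `observed_speed`, QC),
#'   `table` (participant x condition: `si`, `observed_speed`,
#'   `predicted_speed`, `normalized_speed`, anthropometrics),
#'   `speed_model`, and optionally `si_objects`.
#' @export
process_cohort <- function(cohort, config = gait_config(), keep_si = FALSE) {
  if (length(cohort$traces) == 0L)
    stop("cohort carries no traces (simulate with keep_traces = TRUE)")
  tr_tab <- cohort$trials
  n <- nrow(tr_tab)
  si_list <- vector("list", n)
  rv <- siv <- numeric(n)
  nl <- nr <- integer(n)
  qcv <- character(n)
  for (i in seq_len(n)) {
    res <- compute_trial_si(cohort$traces[[tr_tab$trial_id[i]]], config,
                            participant_id = tr_tab$participant_id[i],
                            condition = tr_tab$condition[i],
                            trial = tr_tab$trial[i])
    si_list[[i]] <- res
    rv[i] <- res$r; siv[i] <- res$si
    nl[i] <- res$n_left; nr[i] <- res$n_right
    qcv[i] <- paste(res$qc$flags, collapse = "; ")
  }
  trials <- data.frame(
    trial_id = tr_tab$trial_id, participant_id = tr_tab$participant_id,
    group = tr_tab$group, condition = tr_tab$condition, trial = tr_tab$trial,
    r = rv, si = siv, n_left = nl, n_right = nr,
    observed_speed = mean_speed(tr_tab$path_m, tr_tab$duration_s),
    qc = qcv, stringsAsFactors = FALSE)

  agg_si <- aggregate_si(si_list, strategy = config$aggregation,
                         conditions = unique(trials$condition))
  agg_si$participant_id <- as.integer(agg_si$participant_id)
  spd <- stats::aggregate(observed_speed ~ participant_id + condition,
                          data = trials, FUN = mean)
  tab <- merge(agg_si[, c("participant_id", "condition", "si", "qc")],
               spd, by = c("participant_id", "condition"))
  tab <- merge(tab, cohort$participants[, c("participant_id", "group", "age",
                                            "sex", "weight_kg", "height_cm")],
               by = "participant_id")
  model <- fit_speed_model(tab, scope = "condition")
  tab <- normalize_speed(tab, model)
  tab <- tab[order(tab$participant_id, match(tab$condition, unique(trials$condition))), ]
  rownames(tab) <- NULL
  out <- list(trials = trials, table = tab, speed_model = model)
  if (keep_si) out$si_objects <- si_list
  structure(out, class = "gait_results")
}

#' @export
print.gait_results <- function(x, ...) {
  cat(sprintf("<gait_results> %d trials, %d participant x condition rows\n",
              nrow(x$trials), nrow(x$table)))
  agg <- stats::aggregate(si ~ group + condition, data = x$table, FUN = mean)
  wide <- stats::reshape(agg, idvar = "group", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^si\\.", "", names(wide))
  cat("mean SI by group and condition:\n")
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.gait_results <- function(x, ...) {
  agg <- stats::aggregate(si ~ group + condition, data = x$table, FUN = mean)
  conds <- unique(x$table$condition)
  groups <- unique(x$table$group)
  graphics::plot(NULL, xlim = c(1, length(groups)), ylim = range(agg$si),
                 xaxt = "n", xlab = "", ylab = "Symmetry Index", ...)
  graphics::axis(1, at = seq_along(groups), labels = groups, las = 2, cex.axis = 0.8)
  for (ci in seq_along(conds)) {
    y <- agg$si[match(paste(groups, conds[ci]), paste(agg$group, agg$condition))]
    graphics::lines(seq_along(groups), y, col = ci, type = "b", pch = 16)
  }
  graphics::legend("bottomleft", legend = conds, col = seq_along(conds),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
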