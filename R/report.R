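#' Cohort-level statistical report
#'
#' Runs the full statistical battery on a processed cohort table, for the
#' symmetry index and the normalized speed: normality (Shapiro-Wilk per
#' group x condition cell) and variance homogeneity (Levene) checks, the
#' split-plot two-way ANOVA with Greenhouse-Geisser correction, Bonferroni
#' pairwise group comparisons associated with the omnibus test, one-way
#' repeated-measures ANOVAs per group with condition post hocs, one-way
#' independent ANOVAs per condition with group pairwise matrices, and the
#' per-condition canonical LDA. Optionally writes the CSV/text report
#' files.
#'
#' @param table the `table` element of a [process_cohort()] result (or any
#'   long table with `participant_id`, `group`, `condition`, `si`,
#'   `normalized_speed`).
#' @param dvs dependent variables to analyse.
#' @param alpha significance level used when printing.
#' @param out_dir optional directory; when given, `anova_omnibus.csv`,
#'   `pairwise_groups_<condition>.csv`, `pairwise_conditions_<group>.csv`,
#'   `lda_<condition>.csv` and `report.txt` are written there.
#' @return Object of class `gait_report` (invisibly if `out_dir` given).
#' @export
analysis_report <- function(table, dvs = c("si", "normalized_speed"),
                            alpha = 0.05, out_dir = NULL) {
  conds <- unique(table$condition)
  groups <- unique(table$group)
  rep_out <- list(alpha = alpha, dvs = dvs, conditions = conds, groups = groups)

  rep_out$assumptions <- do.call(rbind, lapply(dvs, function(dv) {
    sw <- do.call(rbind, lapply(conds, function(cond) {
      d <- table[table$condition == cond, ]
      p <- tryCatch(shapiro_wilk(d[[dv]])$p, error = function(e) NA_real_)
      lv <- tryCatch(levene_test(d[[dv]], d$group)$p, error = function(e) NA_real_)
      data.frame(dv = dv, condition = cond, shapiro_p = p, levene_p = lv,
                 stringsAsFactors = FALSE)
    }))
    sw
  }))

  rep_out$omnibus <- lapply(stats::setNames(dvs, dvs), function(dv)
    mixed_anova(table, dv = dv))

  rep_out$pairwise_groups_omnibus <- lapply(stats::setNames(dvs, dvs), function(dv) {
    pm <- stats::aggregate(table[[dv]],
                           by = list(participant_id = table$participant_id,
                                     group = table$group), FUN = mean)
    bonferroni_pairwise(pm$x, pm$group)
  })

  rep_out$per_group <- lapply(stats::setNames(dvs, dvs), function(dv) {
    lapply(stats::setNames(groups, groups), function(g) {
      d <- table[table$group == g, ]
      list(anova = rm_anova_oneway(d, dv = dv),
           pairwise = bonferroni_pairwise(d[[dv]], d$condition, paired = TRUE,
                                          subject = d$participant_id))
    })
  })

  rep_out$per_condition <- lapply(stats::setNames(dvs, dvs), function(dv) {
    lapply(stats::setNames(conds, conds), function(cond) {
      d <- table[table$condition == cond, ]
      list(anova = oneway_anova(d, dv = dv),
           pairwise = bonferroni_pairwise(d[[dv]], d$group))
    })
  })

  rep_out$lda <- lapply(stats::setNames(conds, conds), function(cond)
    lda_groups(table[table$condition == cond, ]))

  out <- structure(rep_out, class = "gait_report")
  if (!is.null(out_dir)) {
    write_report(out, out_dir)
    return(invisible(out))
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  omni <- do.call(rbind, lapply(names(report$omnibus), function(dv) {
    ef <- report$omnibus[[dv]]$effects
    ef$dv <- dv
    ef$epsilon <- report$omnibus[[dv]]$epsilon
    ef
  }))
  utils::write.csv(omni, file.path(out_dir, "anova_omnibus.csv"), row.names = FALSE)
  for (cond in report$conditions) {
    pg <- do.call(rbind, lapply(names(report$per_condition), function(dv) {
      cbind(dv = dv, report$per_condition[[dv]][[cond]]$pairwise)
    }))
    utils::write.csv(pg, file.path(out_dir, sprintf("pairwise_groups_%s.csv", cond)),
                     row.names = FALSE)
    ld <- report$lda[[cond]]
    utils::write.csv(data.frame(fn = seq_along(ld$eigenvalues),
                                eigenvalue = ld$eigenvalues,
                                proportion = ld$proportion, wilks = ld$wilks,
                                chisq = ld$chisq, df = ld$df, p = ld$p),
                     file.path(out_dir, sprintf("lda_%s.csv", cond)),
                     row.names = FALSE)
  }
  for (g in report$groups) {
    pc <- do.call(rbind, lapply(names(report$per_group), function(dv) {
      cbind(dv = dv, report$per_group[[dv]][[g]]$pairwise)
    }))
    utils::write.csv(pc, file.path(out_dir,
                                   sprintf("pairwise_conditions_%s.csv", gsub("[^A-Za-z0-9-]", "_", g))),
                     row.names = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("=== Cohort statistical report ===\n\n")
  for (dv in x$dvs) {
    cat(sprintf("--- %s ---\n", dv))
    print(x$omnibus[[dv]])
    cat("\nPer-group condition effects (GG-corrected):\n")
    for (g in x$groups) {
      a <- x$per_group[[dv]][[g]]$anova
      cat(sprintf("  %-14s F(%.1f, %.1f) = %6.3f, p_GG = %.4g\n",
                  g, a$df1_gg, a$df2_gg, a$F, a$p_gg))
    }
    cat("\nPer-condition group effects:\n")
    for (cond in x$conditions) {
      a <- x$per_condition[[dv]][[cond]]$anova
      cat(sprintf("  %-12s F(%d, %d) = %6.3f, p = %.4g\n",
                  cond, a$df1, a$df2, a$F, a$p))
    }
    cat("\n")
  }
  cat("--- discriminant analysis per condition ---\n")
  for (cond in x$conditions) {
    cat(sprintf("[%s]\n", cond))
    print(x$lda[[cond]])
  }
  invisible(x)
}
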