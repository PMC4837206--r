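#' Mean, SEM and n of one group of measurements
#'
#' SEM uses the n-1 sample standard deviation divided by sqrt(n); it is
#' reported as `NA` for a single measurement.
#'
#' @param values Numeric vector (one value per measurement).
#' @return A list with `mean`, `sem` and `n`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("cannot summarize an empty group")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Two-sided two-sample t test
#'
#' Wraps the standard two-sample t test (Welch by default; Student's
#' pooled-variance variant by flag), adding explicit conventions for
#' degenerate zero-variance groups, which the standard routine refuses:
#' zero variance in both groups with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means gives `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param variant `"welch"` or `"student"`.
#' @return A list with `t`, `p`, `df` and `degenerate`.
#' @export
t_test <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stopf("t test needs at least 2 measurements per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2L, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

# Long table of per-measurement compartment values from ratio_profile list.
profiles_to_long <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    d <- p$compartments[, c("compartment", "I_lipid", "I_protein", "R")]
    cbind(data.frame(sample_id = p$sample_id, dialect = p$dialect), d)
  }))
}

#' Compare control and metastasis depth profiles
#'
#' For every compartment (`upper`, `lower`, `all`) and measure (`I_lipid`,
#' `I_protein`, `R`): group means with SEM, a two-sample t test, and the
#' percent change `100 * (mean_metastasis - mean_control) / mean_control`.
#' The unit of replication is one measurement (one Z-stack).
#'
#' @param control,metastasis Lists of [profile_stack()] results, one per
#'   measurement; at least 2 per condition.  Dialects must match.
#' @param alpha Significance level; a comparison is flagged significant
#'   when `p < alpha`.
#' @param variant t-test variant, `"welch"` (default) or `"student"`.
#' @param bonferroni Apply a Bonferroni correction across the 9
#'   comparisons before flagging significance (off by default, matching
#'   single-threshold reporting).
#' @return An object of class `raman_comparison`: a data.frame with one
#'   row per compartment x measure (9 rows) and columns `compartment`,
#'   `measure`, `mean_control`, `sem_control`, `n_control`,
#'   `mean_metastasis`, `sem_metastasis`, `n_metastasis`, `t_statistic`,
#'   `p_value`, `percent_change`, `significant`.
#' @export
compare_conditions <- function(control, metastasis, alpha = 0.05,
                               variant = c("welch", "student"),
                               bonferroni = FALSE) {
  variant <- match.arg(variant)
  if (inherits(control, "ratio_profile")) control <- list(control)
  if (inherits(metastasis, "ratio_profile")) metastasis <- list(metastasis)
  if (length(control) < 2L || length(metastasis) < 2L)
    stopf("at least 2 measurements per condition are required")
  dialects <- unique(c(vapply(control, `[[`, character(1L), "dialect"),
                       vapply(metastasis, `[[`, character(1L), "dialect")))
  if (length(dialects) != 1L)
    stopf("mismatched dialects between conditions: %s",
          paste(dialects, collapse = " vs "))
  lc <- profiles_to_long(control)
  lm <- profiles_to_long(metastasis)
  rows <- list()
  for (comp in c("upper", "lower", "all")) {
    for (meas in c("I_lipid", "I_protein", "R")) {
      va <- lc[lc$compartment == comp, meas]
      vb <- lm[lm$compartment == comp, meas]
      sa <- summarize_group(va)
      sb <- summarize_group(vb)
      tt <- t_test(vb, va, variant) # metastasis minus control orientation
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = comp, measure = meas,
        mean_control = sa$mean, sem_control = sa$sem, n_control = sa$n,
        mean_metastasis = sb$mean, sem_metastasis = sb$sem,
        n_metastasis = sb$n,
        t_statistic = tt$t, p_value = tt$p,
        percent_change = 100 * (sb$mean - sa$mean) / sa$mean,
        degenerate = tt$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  p_eff <- if (bonferroni) pmin(1, out$p_value * nrow(out)) else out$p_value
  out$significant <- p_eff < alpha
  structure(out, class = c("raman_comparison", "data.frame"),
            alpha = alpha, variant = variant, bonferroni = bonferroni,
            dialect = dialects)
}

#' @export
print.raman_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("<raman_comparison> %s dialect, %s t test, alpha = %g%s\n",
              attr(x, "dialect"), attr(x, "variant"), attr(x, "alpha"),
              if (isTRUE(attr(x, "bonferroni"))) " (Bonferroni)" else ""))
  df <- as.data.frame(x)
  df$mark <- ifelse(df$significant, "*", "")
  print(format(df[, c("compartment", "measure", "mean_control",
                      "mean_metastasis", "percent_change", "p_value",
                      "mark")], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a comparison table and human-readable report
#'
#' `comparison.tsv` holds the full 9-row table; `report.md` summarises each
#' compartment as mean +/- SEM per condition with significance marks.
#'
#' @param comparison A `raman_comparison`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "comparison.tsv")
  utils::write.table(as.data.frame(comparison), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- file.path(dir, "report.md")
  x <- as.data.frame(comparison)
  lines <- c("# Control vs metastasis comparison", "",
             sprintf("t test: %s; alpha = %g%s", attr(comparison, "variant"),
                     attr(comparison, "alpha"),
                     if (isTRUE(attr(comparison, "bonferroni")))
                       " (Bonferroni-corrected)" else ""), "")
  for (comp in unique(x$compartment)) {
    lines <- c(lines, sprintf("## %s compartment", comp), "")
    sub <- x[x$compartment == comp, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines, sprintf(
        "- %s: control %.4g +/- %.2g (n=%d), metastasis %.4g +/- %.2g (n=%d), change %+.1f%%, p = %.3g%s",
        r$measure, r$mean_control, r$sem_control, r$n_control,
        r$mean_metastasis, r$sem_metastasis, r$n_metastasis,
        r$percent_change, r$p_value, if (r$significant) " *" else ""))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, md)
  invisible(c(tsv, md))
}
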