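#' Chi-square test of predation frequency between predator groups
#'
#' Pearson chi-square test on a groups-by-(success, failure) contingency
#' table, e.g. the number of predators that consumed at least one prey item
#' out of the number tested in each group. Following the conventional
#' default, Yates' continuity correction is applied to 2x2 tables and no
#' correction to larger tables; `correct` overrides this (the correction is
#' only ever applied to 2x2 tables).
#'
#' @param successes integer vector, one success count per group.
#' @param totals integer vector of group totals (same length).
#' @param groups optional group labels.
#' @param correct logical; Yates continuity correction. Default: `TRUE` for
#'   two groups, `FALSE` otherwise.
#' @return `htest` object from [stats::chisq.test()] (statistic, df,
#'   p-value).
#' @examples
#' # incidence of embryo predation in three amphipod groups
#' chi_square_test(c(5, 44, 44), c(45, 45, 45))
#' @export
chi_square_test <- function(successes, totals, groups = NULL,
                            correct = NULL) {
  if (length(successes) != length(totals) || length(successes) < 2L) {
    stop("`successes` and `totals` must be equal-length vectors, >= 2 groups")
  }
  if (any(successes < 0) || any(totals <= 0) || any(successes > totals)) {
    stop("need 0 <= successes <= totals with positive totals")
  }
  if (is.null(groups)) groups <- paste0("group", seq_along(successes))
  tab <- cbind(success = successes, failure = totals - successes)
  rownames(tab) <- groups
  if (any(colSums(tab) == 0)) {
    stop("a margin of the table is zero; the test statistic is undefined")
  }
  if (is.null(correct)) correct <- length(successes) == 2L
  if (length(successes) != 2L) correct <- FALSE
  out <- stats::chisq.test(tab, correct = correct)
  out$data.name <- paste(deparse(substitute(successes)), "of",
                         deparse(substitute(totals)))
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value obtained by summing the probabilities of all
#' tables (with the observed margins) whose hypergeometric probability does
#' not exceed that of the observed table -- the conventional two-sided
#' definition, as implemented in [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value (numeric scalar).
#' @examples
#' fisher_exact_2x2(matrix(c(167, 175, 8, 0), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    stop("`table` must be a 2x2 matrix")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("`table` must contain non-negative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Per-group survival summary with mortality attribution
#'
#' Aggregates prey survival per predator group,
#' \eqn{1 - (consumed + dead\_unconsumed) / offered}, and compares each
#' experimental group against the predator-free control with Fisher's exact
#' test. Mortality in a group is attributed to predation when its survival
#' is significantly below the control's.
#'
#' @param trials trial data.frame including control rows (see
#'   [read_trials()]); excluded rows are dropped.
#' @param control_label value of `predator_group` identifying the control
#'   (default `"control"`).
#' @param alpha significance level for attribution (default 0.05).
#' @return data.frame (class `survival_summary`) with one row per group:
#'   `group`, `offered`, `died`, `survival` (proportion),
#'   `p_vs_control`, `predation_attributed`.
#' @export
survival_summary <- function(trials, control_label = "control",
                             alpha = 0.05) {
  d <- usable_trials(trials)
  if (!"predator_group" %in% names(d)) {
    stop("`trials` must have a `predator_group` column")
  }
  if (!control_label %in% d$predator_group) {
    stop("no control group (predator_group == \"", control_label,
         "\") in `trials`")
  }
  agg <- do.call(rbind, lapply(split(d, d$predator_group), function(g) {
    data.frame(group = g$predator_group[1L],
               offered = sum(g$density_offered),
               died = sum(g$consumed + g$dead_unconsumed),
               stringsAsFactors = FALSE)
  }))
  agg$survival <- 1 - agg$died / agg$offered
  ctl <- agg[agg$group == control_label, ]
  agg$p_vs_control <- vapply(seq_len(nrow(agg)), function(i) {
    if (agg$group[i] == control_label) return(NA_real_)
    tab <- matrix(c(agg$offered[i] - agg$died[i], agg$died[i],
                    ctl$offered - ctl$died, ctl$died),
                  nrow = 2L, byrow = TRUE)
    fisher_exact_2x2(tab)
  }, numeric(1))
  agg$predation_attributed <- !is.na(agg$p_vs_control) &
    agg$p_vs_control < alpha & agg$survival < ctl$survival
  rownames(agg) <- NULL
  class(agg) <- c("survival_summary", "data.frame")
  agg
}
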