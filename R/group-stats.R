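#' Two-sample t-test between genotypes
#'
#' Pooled-variance (Student) two-tailed t-test on one metric of a group
#' table, comparing the two genotypes present. The pooled form matches
#' the assumption of similar group variances; set `welch = TRUE` for the
#' unequal-variance form.
#'
#' @param table data.frame with columns `subject_id`, `genotype`,
#'   `metric`, `value` (one row per subject for the chosen metric), or
#'   with arbitrary metric columns when `metric` names one of them.
#' @param metric name of the metric to test.
#' @param welch use the Welch correction instead of pooling.
#' @param twoSD optionally pre-filter each group to values within two
#'   standard deviations of its mean before testing (off by default: it
#'   discards about 5 percent of clean data).
#' @return list with `t`, `df`, `p`, `n` (per-group counts, surfaced
#'   because usable n can vary by metric), `mean_by_genotype`.
#' @examples
#' tab <- data.frame(subject_id = 1:6,
#'                   genotype = rep(c("WT", "HET"), each = 3),
#'                   metric = "x", value = c(1, 2, 3, 4, 5, 6))
#' ttestBetweenGenotypes(tab, "x")
#' @export
ttestBetweenGenotypes <- function(table, metric, welch = FALSE,
                                  twoSD = FALSE) {
  df <- .metric_rows(table, metric)
  groups <- split(df$value, df$genotype)
  if (length(groups) != 2L)
    stop("need exactly 2 genotypes, found ", length(groups))
  if (twoSD)
    groups <- lapply(groups, function(v)
      v[abs(v - mean(v)) <= 2 * stats::sd(v)])
  if (any(lengths(groups) < 2L))
    stop("each genotype needs at least 2 subjects")
  tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = lengths(groups),
       mean_by_genotype = vapply(groups, mean, numeric(1)))
}

.metric_rows <- function(table, metric) {
  if ("metric" %in% names(table)) {
    out <- table[table$metric == metric, , drop = FALSE]
    if (!nrow(out)) stop("no rows for metric '", metric, "'")
    stopifnot(all(is.finite(out$value)))
    out
  } else {
    if (!metric %in% names(table)) stop("no column '", metric, "'")
    data.frame(subject_id = table$subject_id, genotype = table$genotype,
               value = table[[metric]])
  }
}

#' Two-way repeated-measures ANOVA with Sidak post hoc
#'
#' Mixed design: genotype between subjects, time (or condition) within
#' subjects, subject nested in genotype. Implemented as the classical
#' sums-of-squares decomposition via `aov` with an error stratum for
#' subjects; requires a complete (balanced within subject) design. Each
#' time point is additionally compared between genotypes with a pooled
#' t-test, Sidak-adjusted for the number of time points
#' (`p' = 1 - (1 - p)^m`).
#'
#' @param table data.frame with columns `subject_id`, `genotype`, `time`,
#'   `value`.
#' @param adjust `"sidak"` (default), `"bonferroni"` or `"holm"` for the
#'   per-time comparisons.
#' @return list with `genotype`, `time`, `interaction` (each `F`, `df1`,
#'   `df2`, `p`) and `posthoc` (data.frame per time point with raw and
#'   adjusted p).
#' @export
rmAnovaTwoWay <- function(table, adjust = c("sidak", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  need <- c("subject_id", "genotype", "time", "value")
  stopifnot(all(need %in% names(table)), all(is.finite(table$value)))
  tab <- data.frame(subject = factor(table$subject_id),
                    genotype = factor(table$genotype),
                    time = factor(table$time),
                    value = table$value)
  counts <- table(tab$subject, tab$time)
  if (any(counts != 1L))
    stop("design must be complete: one value per subject x time")
  fit <- stats::aov(value ~ genotype * time + Error(subject), data = tab)
  sm <- summary(fit)
  btw <- sm[["Error: subject"]][[1L]]
  wth <- sm[["Error: Within"]][[1L]]
  pick <- function(strat, term) {
    i <- match(term, trimws(rownames(strat)))
    list(F = strat[i, "F value"], df1 = strat[i, "Df"],
         df2 = strat[nrow(strat), "Df"], p = strat[i, "Pr(>F)"])
  }
  m <- nlevels(tab$time)
  post <- do.call(rbind, lapply(levels(tab$time), function(tl) {
    sub <- tab[tab$time == tl, ]
    g <- split(sub$value, sub$genotype)
    tt <- stats::t.test(g[[1L]], g[[2L]], var.equal = TRUE)
    data.frame(time = tl, t = unname(tt$statistic), p_raw = tt$p.value)
  }))
  post$p_adj <- switch(adjust,
    sidak = 1 - (1 - post$p_raw)^m,
    bonferroni = pmin(1, post$p_raw * m),
    holm = stats::p.adjust(post$p_raw, "holm"))
  list(genotype = pick(btw, "genotype"),
       time = pick(wth, "time"),
       interaction = pick(wth, "genotype:time"),
       posthoc = post)
}
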