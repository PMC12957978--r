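#' Group summary (n, mean, SD)
#'
#' Container for printed demographic summaries of the form
#' "mean +/- SD (n)"; the sample SD is used throughout.
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("group summary requires n >= 2")
  if (sd < 0) stop("sd must be nonnegative")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

.as_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2) stop("each group needs at least 2 values")
  group_summary(length(x), mean(x), stats::sd(x))
}

#' Independent two-sample t statistic
#'
#' Works from raw values or printed summaries. `"pooled"` uses the
#' equal-variance pooled-SD form with df = n_a + n_b - 2; `"welch"` uses
#' the unequal-variance form with Welch-Satterthwaite df.
#'
#' @param a,b Numeric vectors or [group_summary()] objects.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
two_sample_t <- function(a, b, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  a <- .as_summary(a)
  b <- .as_summary(b)
  if (variance_mode == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 == 0) stop("zero pooled variance")
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    if (va + vb == 0) stop("zero variance in both groups")
    t <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' The plain Pearson statistic (no continuity correction), with expected
#' counts from the marginals and df = (r - 1)(c - 1).
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @return List with `chisq`, `df` and `p`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid contingency table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Wilcoxon rank-sum z statistic
#'
#' Mann-Whitney test via the normal approximation with midranks for ties
#' and the tie-corrected variance; no continuity correction.
#'
#' @param x,y Numeric vectors (one per group).
#' @return List with `z`, the rank-sum `W` of `x`, `U` and two-sided `p`.
#' @export
rank_sum_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one value")
  all_v <- c(x, y)
  r <- rank(all_v)  # midranks
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) stop("zero rank variance: all values identical")
  z <- (W - n1 * (N + 1) / 2) / sqrt(v)
  list(z = z, W = W, U = W - n1 * (n1 + 1) / 2,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Rank-based ANCOVA (rank-transform, regress, Kruskal-Wallis)
#'
#' Nonparametric covariate adjustment for group comparisons that violate
#' normality: the dependent variable and the covariate are rank-transformed
#' (midranks), the dependent ranks are adjusted by least-squares regression
#' on the covariate ranks (intercept included), and the Kruskal-Wallis
#' test is applied to the residuals across groups.
#'
#' @param dep Numeric dependent values.
#' @param group Group labels (>= 2 groups, >= 2 subjects per group).
#' @param covariate Numeric covariate (e.g. age).
#' @return List with `H`, `df` and `p` (Kruskal-Wallis on the adjusted
#'   residuals).
#' @export
rank_ancova <- function(dep, group, covariate) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("rank ANCOVA requires at least two groups")
  if (any(table(group) < 2)) stop("each group needs at least two subjects")
  rd <- rank(dep)
  if (length(unique(covariate)) == 1) {
    warning("constant covariate: falling back to a plain Kruskal-Wallis test")
    res <- stats::kruskal.test(rd, group)
  } else {
    rc <- rank(covariate)
    resid <- stats::residuals(stats::lm(rd ~ rc))
    res <- stats::kruskal.test(resid, group)
  }
  list(H = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' One-way ANCOVA F for the group factor
#'
#' Parametric group comparison adjusting for one covariate: the Type II F
#' for the group factor, i.e. the comparison of `dep ~ covariate` against
#' `dep ~ covariate + group`.
#'
#' @param dep Numeric dependent values.
#' @param group Group labels.
#' @param covariate Numeric covariate.
#' @return List with `F`, `df` (numerator, denominator) and `p`.
#' @export
ancova_f <- function(dep, group, covariate) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("ANCOVA requires at least two groups")
  full <- stats::lm(dep ~ covariate + group)
  if (any(is.na(stats::coef(full)))) stop("singular design")
  reduced <- stats::lm(dep ~ covariate)
  cmp <- stats::anova(reduced, full)
  list(F = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]), p = cmp$`Pr(>F)`[2])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-metric group comparison table with FDR column
#'
#' For each metric column, compares the groups by [ancova_f()] (or
#' [rank_ancova()]) controlling for the covariate, then appends
#' BH-adjusted p-values across metrics.
#'
#' @param features Data frame with metric columns plus `group`.
#' @param metrics Metric column names (default [all_features()] present).
#' @param covariate Numeric covariate vector (same order as rows).
#' @param method `"ancova"` or `"rank_ancova"`.
#' @return Data frame: metric, per-group mean and SD, statistic, p, fdr.
#' @export
metric_comparison_table <- function(features, covariate,
                                    metrics = intersect(all_features(),
                                                        names(features)),
                                    method = c("ancova", "rank_ancova")) {
  method <- match.arg(method)
  grp <- as.factor(features$group)
  rows <- lapply(metrics, function(mname) {
    v <- features[[mname]]
    res <- if (method == "ancova") ancova_f(v, grp, covariate)
           else rank_ancova(v, grp, covariate)
    stat <- if (method == "ancova") res$F else res$H
    means <- tapply(v, grp, mean)
    sds <- tapply(v, grp, stats::sd)
    out <- data.frame(metric = mname, statistic = stat, p = res$p)
    for (g in levels(grp)) {
      out[[paste0("mean_", g)]] <- means[[g]]
      out[[paste0("sd_", g)]] <- sds[[g]]
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p)
  tab
}
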