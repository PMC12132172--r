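# Shared statistical machinery: rank-sum with exact enumeration,
# Kruskal-Wallis + Conover-Iman post hoc, one-way ANOVA + Tukey HSD,
# BH adjustment, correlations. All tests are two-sided.

#' Construct a test-result record
#'
#' Light container used by every statistical routine: statistic, raw and
#' (optionally) adjusted p-value, a method label and bookkeeping notes.
#'
#' @param statistic test statistic.
#' @param p_raw two-sided p-value.
#' @param p_adjusted adjusted p-value (NA when no adjustment applies).
#' @param method method label.
#' @param n sample sizes per group.
#' @param notes free-text notes (ties, approximation used, ...).
#' @return an object of class `phys_test`.
#' @export
phys_test <- function(statistic, p_raw, p_adjusted = NA_real_,
                      method = "", n = NULL, notes = NULL) {
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, method = method, n = n,
                 notes = notes),
            class = "phys_test")
}

#' @export
print.phys_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p_raw), sep = "")
  if (!is.na(x$p_adjusted)) cat(", adjusted p =", format(x$p_adjusted))
  if (!is.null(x$notes)) cat("\n  note:", x$notes)
  cat("\n")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by complete enumeration of rank assignments (handling ties via
#' midranks) when `n1 + n2 <= 12` or when forced; otherwise a normal
#' approximation with tie correction and continuity correction. The
#' exact two-sided p-value is the probability, over all equally likely
#' group assignments, of a rank sum at least as far from its expectation
#' as observed.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return a `phys_test` (statistic = rank sum of `x`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_raw  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  all_tied <- length(unique(c(x, y))) == 1L
  if (all_tied) {
    return(phys_test(W, 1, method = "Wilcoxon rank-sum (degenerate)",
                     n = c(n1, n2), notes = "all values identical"))
  }
  use_exact <- (mode == "exact") || (mode == "auto" && N <= 12)

  if (use_exact) {
    combos <- combn(N, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-9)
    phys_test(W, p, method = "Wilcoxon rank-sum (exact enumeration)",
              n = c(n1, n2),
              notes = if (anyDuplicated(c(x, y))) "midranks for ties")
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (abs(W - EW) - 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    phys_test(W, p,
              method = "Wilcoxon rank-sum (normal approximation)",
              n = c(n1, n2),
              notes = "tie and continuity corrected")
  }
}

rank_sum_groups <- function(groups) {
  if (!is.list(groups)) stop("`groups` must be a list", call. = FALSE)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups
}

#' Kruskal-Wallis test with Conover-Iman post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H test (tie-corrected, chi-square p-value) via
#' [stats::kruskal.test()], followed by Conover-Iman pairwise t statistics
#' on the pooled ranks with the omnibus-conditional variance estimate
#' `S^2 (N - 1 - H) / (N - k)` on `N - k` degrees of freedom, and
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   `n >= 2`; with 2 groups the omnibus degenerates to a rank-sum-type
#'   test).
#' @return list with `omnibus` (a `phys_test`) and `pairwise`
#'   (data.frame: `group1`, `group2`, `statistic`, `p_raw`,
#'   `p_adjusted`).
#' @export
kruskal_wallis_conover <- function(groups) {
  groups <- rank_sum_groups(groups)
  k <- length(groups)
  if (k < 2L) stop("at least 2 groups are required", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  kw <- kruskal.test(values, g)
  H <- unname(kw$statistic)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale2 <- S2 * (N - 1 - H) / (N - k)
  pairs <- combn(names(groups), 2)
  stat <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(scale2 * (1 / ns[[a]] + 1 / ns[[b]]))
    t <- (rbar[[a]] - rbar[[b]]) / se
    stat[j] <- t
    p_raw[j] <- 2 * pt(-abs(t), df = N - k)
  }
  list(
    omnibus = phys_test(H, unname(kw$p.value),
                        method = "Kruskal-Wallis rank sum test",
                        n = as.integer(ns)),
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          statistic = stat, p_raw = p_raw,
                          p_adjusted = benjamini_hochberg(p_raw),
                          stringsAsFactors = FALSE))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Omnibus F test and Tukey honest significant difference contrasts via
#' [stats::aov()] and [stats::TukeyHSD()] (studentized-range p-values).
#' Optionally applies Benjamini-Hochberg across the Tukey p-values, the
#' convention used for isoform-composition comparisons.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   `n >= 2`).
#' @param bh additionally BH-adjust the Tukey p-values (default the
#'   adjusted column simply repeats the Tukey family-wise p).
#' @return list with `omnibus` (a `phys_test`) and `pairwise`
#'   (data.frame: `group1`, `group2`, `estimate`, `p_raw`,
#'   `p_adjusted`).
#' @export
anova_tukey <- function(groups, bh = FALSE) {
  groups <- rank_sum_groups(groups)
  if (length(groups) < 2L) stop("at least 2 groups are required",
                                call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (all(vapply(groups, function(v) var(v) == 0, logical(1)))) {
    stop("zero within-group variance in every group: F undefined",
         call. = FALSE)
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  Fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  p_tukey <- tk[, "p adj"]
  list(
    omnibus = phys_test(Fstat, p, method = "one-way ANOVA",
                        n = as.integer(ns)),
    pairwise = data.frame(
      group1 = vapply(nm, `[`, character(1), 1),
      group2 = vapply(nm, `[`, character(1), 2),
      estimate = tk[, "diff"],
      p_raw = p_tukey,
      p_adjusted = if (bh) benjamini_hochberg(p_tukey) else p_tukey,
      row.names = NULL, stringsAsFactors = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values `min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the input order.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite numbers in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Correlation coefficient with two-sided test
#'
#' @param x,y numeric vectors, `n >= 3`, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `phys_test` (statistic = correlation coefficient).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length n >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  phys_test(unname(ct$estimate), ct$p.value,
            method = paste0(if (method == "pearson") "Pearson" else
              "Spearman", " correlation"),
            n = length(x))
}
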