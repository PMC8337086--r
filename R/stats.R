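# The statistical procedures used across the analyses, wrapped behind a
# uniform TestResult so every module reports method, n, and correction
# the same way. Heavy lifting is delegated to base R (wilcox.test,
# kruskal.test, aov/t.test, lm) and nortest (Anderson-Darling).

test_result <- function(statistic, p, method, n, correction = "none",
                        factor = 1L) {
  p_corr <- min(1, p * factor)
  structure(list(statistic = unname(statistic), p = unname(p),
                 p_corrected = p_corr, method = method, n = n,
                 correction = correction, factor = factor),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s (n = %s)\n", x$method,
              x$statistic, x$p,
              if (x$correction != "none")
                sprintf(", %s-corrected p = %.4g (x%d)", x$correction,
                        x$p_corrected, x$factor) else "",
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided. Uses the exact permutation distribution when both groups
#' have at most `exact_max_n` observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @param exact_max_n exact enumeration threshold per group
#' @param exact override the automatic exact/approximate choice
#' @return a `TestResult`
#' @export
rank_sum <- function(a, b, exact_max_n = 10L, exact = NULL) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L)
    return(test_result(0, 1, "Wilcoxon rank sum", c(length(a), length(b))))
  ties <- any(duplicated(c(a, b)))
  if (is.null(exact)) exact <- !ties && length(a) <= exact_max_n &&
      length(b) <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  test_result(wt$statistic, wt$p.value,
              paste0("Wilcoxon rank sum (",
                     if (exact && !ties) "exact" else "normal approx.", ")"),
              c(length(a), length(b)))
}

#' Kruskal-Wallis omnibus test
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2)
#' @return a `TestResult` (H statistic with tie correction, chi-square p)
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  if (length(unique(unlist(groups))) == 1L)
    return(test_result(0, 1, "Kruskal-Wallis", lengths(groups)))
  kt <- stats::kruskal.test(groups)
  test_result(kt$statistic, kt$p.value, "Kruskal-Wallis", lengths(groups))
}

#' Pairwise tests against a control group with Bonferroni correction
#'
#' Runs [rank_sum()] (or pooled-variance two-sample t tests) of every
#' non-control group against the control and multiplies each raw p by
#' the number of comparisons performed (capped at 1).
#'
#' @param groups named list of numeric vectors
#' @param control name of the control group in `groups`
#' @param method "rank_sum" or "t"
#' @return list of `TestResult`, one per comparison, named by group
#' @export
pairwise_vs_control <- function(groups, control, method = c("rank_sum", "t")) {
  method <- match.arg(method)
  stopifnot(control %in% names(groups))
  others <- setdiff(names(groups), control)
  k <- length(others)
  res <- lapply(others, function(g) {
    if (method == "rank_sum") {
      r <- rank_sum(groups[[control]], groups[[g]])
    } else {
      tt <- stats::t.test(groups[[control]], groups[[g]], var.equal = TRUE)
      r <- test_result(tt$statistic, tt$p.value, "two-sample t (pooled)",
                       c(length(groups[[control]]), length(groups[[g]])))
    }
    test_result(r$statistic, r$p, r$method, r$n,
                correction = "bonferroni", factor = k)
  })
  names(res) <- others
  res
}

#' One-way ANOVA with Bonferroni-corrected pairwise t tests
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2)
#' @return list with `omnibus` (`TestResult`, F statistic) and
#'   `pairwise` (list of `TestResult` for every group pair, pooled-
#'   variance t, Bonferroni factor = number of pairs)
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(vals) == 0) {
    omnibus <- test_result(0, 1, "one-way ANOVA", lengths(groups))
  } else {
    a <- stats::anova(stats::aov(vals ~ fac))
    omnibus <- test_result(a$`F value`[1], a$`Pr(>F)`[1], "one-way ANOVA",
                           lengths(groups))
  }
  prs <- utils::combn(names(groups), 2, simplify = FALSE)
  k <- length(prs)
  pairwise <- lapply(prs, function(p) {
    x <- groups[[p[1]]]; y <- groups[[p[2]]]
    if (stats::var(c(x, y)) == 0) {
      r <- test_result(0, 1, "two-sample t (pooled)", c(length(x), length(y)),
                       correction = "bonferroni", factor = k)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      r <- test_result(tt$statistic, tt$p.value, "two-sample t (pooled)",
                       c(length(x), length(y)),
                       correction = "bonferroni", factor = k)
    }
    r
  })
  names(pairwise) <- vapply(prs, paste, "", collapse = " vs ")
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Anderson-Darling normality test
#'
#' Case 3 (mean and SD estimated from the sample) with the usual
#' small-sample correction; the decision compares p against 0.05.
#' Zero-variance input is non-normal by convention.
#'
#' @param x numeric vector, n >= 5
#' @return list `A2` (corrected statistic), `p`, `normal` (logical
#'   decision at alpha = 0.05)
#' @export
anderson_darling <- function(x) {
  if (length(x) < 5) stop("Anderson-Darling test needs n >= 5")
  if (stats::var(x) == 0) return(list(A2 = Inf, p = 0, normal = FALSE))
  at <- nortest::ad.test(x)
  list(A2 = unname(at$statistic), p = at$p.value, normal = at$p.value >= 0.05)
}

#' Linear regression slope with 95% confidence interval
#'
#' @param x,y numeric vectors (>= 3 points; x not all equal)
#' @return list `slope`, `intercept`, `slope_ci` (95%), `slope_se`,
#'   `r_squared`, `residual_sd`
#' @export
linreg_ci <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("degenerate predictor: x values all equal")
  fit <- stats::lm(y ~ x)
  # noise-free synthetic inputs fit exactly; the resulting
  # "essentially perfect fit" warning is expected, not a defect
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = as.numeric(ci),
       slope_se = sm$coefficients["x", "Std. Error"],
       r_squared = sm$r.squared,
       residual_sd = sm$sigma)
}
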