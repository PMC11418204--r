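#' Robust outlier detection with FDR control (ROUT)
#'
#' Flags outliers in a univariate sample using the ROUT procedure
#' specialised to a constant model: a robust location fit (the median),
#' a robust scale estimate (RSDR) taken as the 68.27th percentile of the
#' absolute residuals with the small-sample correction `n/(n - K)` (here
#' `K = 1` fitted parameter), and a step-down FDR-controlled test of each
#' residual at rate `q`. Residuals are converted to two-sided p-values via
#' the t distribution with `n - K` degrees of freedom; points are examined
#' from the most extreme inward, the i-th most extreme being flagged while
#' its p-value stays below `q * (n - i + 1) / n`.
#'
#' @param values Numeric vector of at least 3 finite values.
#' @param q Target false-discovery rate for outlier calls, in (0, 1).
#'   Defaults to 0.01, i.e. Q = 1%.
#' @return An object of class `rout_report`: a list with `flagged` (logical
#'   mask aligned to `values`), `q`, `rsdr` (robust scale used), and
#'   `method_detail` (text describing the robust-fit variant).
#' @examples
#' rout_outliers(c(rnorm(20), 10))
#' @export
rout_outliers <- function(values, q = 0.01) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (any(!is.finite(values))) stop("`values` must be finite")
  n <- length(values)
  if (n < 3L) stop("insufficient-n: ROUT needs at least 3 values, got ", n)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("`q` must be a single number in (0, 1)")

  K <- 1L # constant model: one fitted parameter (the location)
  resid <- values - stats::median(values)
  p68 <- stats::quantile(abs(resid), probs = 0.6827, names = FALSE, type = 7)
  rsdr <- p68 * n / (n - K)

  flagged <- logical(n)
  if (rsdr > 0) {
    pvals <- 2 * stats::pt(abs(resid) / rsdr, df = n - K, lower.tail = FALSE)
    ord <- order(pvals) # most extreme residual first
    for (i in seq_len(n)) {
      alpha_i <- q * i / n # BH ladder: i-th most extreme vs i*q/n
      if (pvals[ord[i]] < alpha_i) flagged[ord[i]] <- TRUE else break
    }
  }
  structure(
    list(
      flagged = flagged, q = q, rsdr = rsdr,
      method_detail = paste(
        "constant-model robust fit (median);",
        "RSDR = 68.27th percentile of |residuals| * n/(n-K), K = 1;",
        "step-down FDR test of t = |residual|/RSDR, df = n-K:",
        "i-th most extreme residual flagged while its two-sided p < i*q/n"
      )
    ),
    class = "rout_report"
  )
}

#' @export
print.rout_report <- function(x, ...) {
  cat("ROUT outlier report (Q =", format(x$q), ")\n")
  cat("  flagged:", sum(x$flagged), "of", length(x$flagged),
      "| RSDR =", format(x$rsdr, digits = 4), "\n")
  invisible(x)
}

# Brown-Forsythe one-way ANOVA (F* statistic; equal variances not assumed).
# F* = sum ni (mi - m)^2 / sum (1 - ni/N) si^2, with Satterthwaite df2.
brown_forsythe_anova <- function(groups) {
  ni <- lengths(groups)
  N <- sum(ni)
  k <- length(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  grand <- sum(ni * mi) / N
  num <- sum(ni * (mi - grand)^2)
  den <- sum((1 - ni / N) * vi)
  if (den <= 0) { # all groups constant
    fstar <- if (num > 0) Inf else 0
    p <- if (num > 0) 0 else 1
    return(list(statistic = fstar, p.value = p, df1 = k - 1, df2 = NA_real_))
  }
  fstar <- num / den
  ci <- (1 - ni / N) * vi / den
  df2 <- 1 / sum(ci^2 / (ni - 1))
  p <- stats::pf(fstar, k - 1, df2, lower.tail = FALSE)
  list(statistic = fstar, p.value = p, df1 = k - 1, df2 = df2)
}

#' Normality-gated group comparison
#'
#' Applies the Shapiro-Wilk test to each group at alpha = 0.05. If every
#' group is consistent with normality, a heteroscedastic ANOVA branch is
#' taken: the Welch ANOVA statistic and p-value are reported (decision
#' p-value) together with the Brown-Forsythe F* statistic. Otherwise a
#' Kruskal-Wallis test is used. A group with zero variance makes the
#' Shapiro-Wilk statistic undefined; such input is routed to
#' Kruskal-Wallis with a warning. `p_adj` is left `NA` until
#' [bh_adjust()] is applied across a test family by the caller.
#'
#' @param groups Named list of numeric vectors, one per group; at least 2
#'   groups with at least 3 finite values each.
#' @return A list of class `group_test` with `test_used` (one of
#'   `"welch_anova"`, `"kruskal_wallis"`), `statistic`, `p_raw`, `p_adj`
#'   (`NA`), `normality_p_per_group`, and (on the ANOVA branch)
#'   `brown_forsythe` with its own statistic and p-value.
#' @export
normality_gated_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  for (g in names(groups)) {
    v <- groups[[g]]
    if (!is.numeric(v) || length(v) < 3L || any(!is.finite(v)))
      stop("group '", g, "' must have >= 3 finite numeric values")
  }

  sw <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::shapiro.test(v)$p.value
  }, numeric(1))
  degenerate <- names(groups)[is.na(sw)]
  if (length(degenerate))
    warning("zero-variance group(s) routed to Kruskal-Wallis: ",
            paste(degenerate, collapse = ", "))

  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))

  if (!length(degenerate) && all(sw >= 0.05)) {
    bf <- brown_forsythe_anova(groups)
    w <- stats::oneway.test(vals ~ fac, var.equal = FALSE)
    w_stat <- unname(w$statistic)
    w_p <- w$p.value
    res <- list(
      test_used = "welch_anova", statistic = w_stat, p_raw = w_p,
      p_adj = NA_real_, normality_p_per_group = sw,
      brown_forsythe = list(statistic = bf$statistic, p = bf$p.value)
    )
  } else {
    kw <- stats::kruskal.test(vals, fac)
    res <- list(
      test_used = "kruskal_wallis", statistic = unname(kw$statistic),
      p_raw = kw$p.value, p_adj = NA_real_, normality_p_per_group = sw,
      degenerate_groups = degenerate
    )
  }
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  cat("Group test:", x$test_used, "| statistic =",
      format(x$statistic, digits = 4), "| p =", format(x$p_raw, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of p-values.
#'
#' @param p_values Numeric vector of p-values, all in \[0, 1\].
#' @return Adjusted p-values aligned to the input positions.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("`p_values` must be numeric")
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values outside [0, 1] at position(s): ",
                     paste(which(!ok), collapse = ", "))
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation with the p-value from the t transform.
#' Zero-variance input returns an undefined-correlation sentinel
#' (`r = NA`, `p = NA`) with a warning, never an error.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with a missing
#'   value in either vector are dropped.
#' @return A list with elements `r`, `p`, and `n` (pairs used).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    warning("fewer than 3 complete pairs; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
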