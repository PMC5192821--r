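# Statistical layer: Shapiro-Wilk normality screening and pairwise Pearson
# correlations with two-sided p-values at alpha = .05.

#' Pearson correlation between two plot-level variables
#'
#' Sample Pearson r with the two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Pairs with a missing value in either variable are dropped pairwise
#' (plots whose NRI is undefined are excluded only from NRI
#' correlations). With zero variance in either variable the correlation
#' is undefined and `r`/`p` are returned as `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @param var_x,var_y variable names carried into the result.
#' @param alpha significance level (default .05).
#' @return one-row data.frame: `var_x`, `var_y`, `n`, `r`, `p`,
#'   `significant`.
#' @export
pearson_cor <- function(x, y, var_x = "x", var_y = "y", alpha = 0.05) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  data.frame(var_x = var_x, var_y = var_y, n = n, r = r, p = p,
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Correlation table over variable pairs
#'
#' One [pearson_cor()] row per requested pair of columns of a per-plot
#' metrics table, in the order given (stable output ordering). No
#' multiple-testing correction is applied by default, matching common
#' practice for exploratory plot-level correlation grids; `adjust =
#' "holm"` flags significance on Holm-adjusted p-values instead (the
#' reported `p` stays unadjusted).
#'
#' @param metrics data.frame of per-plot variables.
#' @param pairs a list of length-2 character vectors, or a 2-column
#'   matrix/data.frame of variable names.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with columns `var_x`, `var_y`, `n`, `r`, `p`,
#'   `significant` (empty with zero rows for an empty pair list).
#' @export
correlation_table <- function(metrics, pairs, alpha = 0.05,
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  metrics <- as.data.frame(metrics)
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      as.character(unlist(pairs[i, ], use.names = FALSE)))
  if (length(pairs) == 0L)
    return(data.frame(var_x = character(), var_y = character(),
                      n = integer(), r = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    if (length(pr) != 2L)
      stop("each pair must name exactly two variables", call. = FALSE)
    miss <- setdiff(pr, names(metrics))
    if (length(miss))
      stop("unknown variable(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- metrics[[pr[1L]]]; y <- metrics[[pr[2L]]]
    n_ok <- sum(is.finite(x) & is.finite(y))
    if (n_ok < 3L) {
      # too few complete pairs after pairwise deletion: undefined, not fatal
      data.frame(var_x = pr[1L], var_y = pr[2L], n = n_ok, r = NA_real_,
                 p = NA_real_, significant = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      pearson_cor(x, y, var_x = pr[1L], var_y = pr[2L], alpha = alpha)
    }
  }))
  if (adjust == "holm") {
    padj <- stats::p.adjust(out$p, method = "holm")
    out$significant <- !is.na(padj) & padj < alpha
  }
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality screen over analysis variables
#'
#' Royston-algorithm Shapiro-Wilk test (via [stats::shapiro.test()]) for
#' each named column, reporting whether it passes at `alpha`. Used to
#' decide/record which soil variables required the log transform.
#'
#' @param metrics data.frame of per-plot variables.
#' @param vars character vector of column names (default: all numeric
#'   columns).
#' @param alpha significance level.
#' @return data.frame: `variable`, `n`, `W`, `p`, `normal`.
#' @export
shapiro_screen <- function(metrics, vars = NULL, alpha = 0.05) {
  metrics <- as.data.frame(metrics)
  if (is.null(vars))
    vars <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  miss <- setdiff(vars, names(metrics))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- metrics[[v]]
    x <- x[is.finite(x)]
    if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0)
      stop(sprintf("shapiro_wilk undefined for variable '%s'", v),
           call. = FALSE)
    sw <- stats::shapiro.test(x)
    data.frame(variable = v, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, normal = sw$p.value >= alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
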