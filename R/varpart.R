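#' Adjusted coefficient of determination
#'
#' Ezekiel's adjustment: `1 - (1 - r2) (n - 1) / (n - p - 1)`. May be
#' negative for weak fits.
#'
#' @param r2 R-squared in `[0, 1]`.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]", call. = FALSE)
  if (n <= p + 1) stop("need n >= p + 2", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# R-squared of the multiple OLS regression of y on the named columns.
.ols_r2 <- function(y, table, cols) {
  X <- cbind(1, as.matrix(table[, cols, drop = FALSE]))
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# Adjusted R-squared of a predictor-set model; r2_source switches between the
# default OLS fit and the SAR trend pseudo-R2 (sensitivity option, needs W).
.set_adj_r2 <- function(y, table, cols, r2_source = "ols", W = NULL) {
  n <- length(y)
  p <- length(cols)
  r2 <- if (r2_source == "ols") {
    .ols_r2(y, table, cols)
  } else {
    sar_error_fit(y, as.matrix(table[, cols, drop = FALSE]), W)$pseudo_r2
  }
  adjusted_r2(min(max(r2, 0), 1), n, p)
}

.check_cols <- function(table, cols) {
  missing <- setdiff(cols, colnames(table))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Two-set variation partitioning on adjusted R-squared
#'
#' Decomposes the adjusted R-squared of `y` on the union of two predictor
#' sets into the fraction explained uniquely by each set and the fraction
#' explained jointly, by inclusion-exclusion over the three fitted models.
#' Fractions may be negative and are reported as computed.
#'
#' @param y Response vector.
#' @param set1,set2 Character vectors of column names in `table`.
#' @param table Data frame holding the predictor columns.
#' @param names Length-2 labels for the two sets (used in fraction labels).
#' @param r2_source `"ols"` (default) or `"sar_trend"` (sensitivity option).
#' @param W Spatial weights, required when `r2_source = "sar_trend"`.
#' @return A `partition_result`: list with `design = "two_set"`, `groups`,
#'   `fractions` (named: `pure_<n1>`, `pure_<n2>`, `shared`), `residual`,
#'   and `full_adj_r2`.
#' @export
varpart2 <- function(y, set1, set2, table, names = c("X1", "X2"),
                     r2_source = c("ols", "sar_trend"), W = NULL) {
  r2_source <- match.arg(r2_source)
  .check_cols(table, c(set1, set2))
  A <- .set_adj_r2(y, table, set1, r2_source, W)
  B <- .set_adj_r2(y, table, set2, r2_source, W)
  AB <- .set_adj_r2(y, table, union(set1, set2), r2_source, W)
  fr <- c(AB - B, AB - A, A + B - AB)
  names(fr) <- c(paste0("pure_", names[1]), paste0("pure_", names[2]), "shared")
  structure(list(design = "two_set", groups = names, fractions = fr,
                 residual = 1 - AB, full_adj_r2 = AB),
            class = "partition_result")
}

#' Three-set variation partitioning on adjusted R-squared
#'
#' Standard inclusion-exclusion over the seven models (three single-set,
#' three pairwise-union, one full-union), yielding three pure fractions,
#' three pairwise-shared fractions, and one all-shared fraction; the seven
#' fractions sum to the full-model adjusted R-squared.
#'
#' @inheritParams varpart2
#' @param set3 Third predictor set.
#' @param names Length-3 labels.
#' @return A `partition_result` with `design = "three_set"` and fractions
#'   `pure_<i>`, `shared_<i><j>`, `shared_<123>`.
#' @export
varpart3 <- function(y, set1, set2, set3, table, names = c("X1", "X2", "X3"),
                     r2_source = c("ols", "sar_trend"), W = NULL) {
  r2_source <- match.arg(r2_source)
  .check_cols(table, c(set1, set2, set3))
  f <- function(...) .set_adj_r2(y, table, Reduce(union, list(...)), r2_source, W)
  R1 <- f(set1); R2 <- f(set2); R3 <- f(set3)
  R12 <- f(set1, set2); R13 <- f(set1, set3); R23 <- f(set2, set3)
  R123 <- f(set1, set2, set3)
  g <- R1 + R2 + R3 - R12 - R13 - R23 + R123
  fr <- c(R123 - R23,                 # pure 1
          R123 - R13,                 # pure 2
          R123 - R12,                 # pure 3
          R1 + R2 - R12 - g,          # shared 1&2 only
          R1 + R3 - R13 - g,          # shared 1&3 only
          R2 + R3 - R23 - g,          # shared 2&3 only
          g)                          # shared by all three
  names(fr) <- c(paste0("pure_", names),
                 paste0("shared_", c(paste0(names[1], names[2]),
                                     paste0(names[1], names[3]),
                                     paste0(names[2], names[3]),
                                     paste0(names[1], names[2], names[3]))))
  structure(list(design = "three_set", groups = names, fractions = fr,
                 residual = 1 - R123, full_adj_r2 = R123),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(x$design, "variation partition (groups:",
      paste(x$groups, collapse = ", "), ")\n")
  print(round(c(x$fractions, residual = x$residual), 4))
  invisible(x)
}

#' The fixed environmental-variable groups used throughout the analysis
#'
#' `C` current climate, `H` historical climate change, `V` within-region
#' heterogeneity, plus the current-climate subgroups: `T` temperature-
#' related, `P` precipitation-related, `E` climate extremes, `S` climate
#' seasonality.
#'
#' @return Named list of character vectors of column names.
#' @export
variable_groups <- function() {
  list(
    C = c("T_mean", "T_min", "T_seas", "P_mean", "P_min", "P_seas"),
    H = c("T_anom", "T_vel", "P_anom", "P_vel"),
    V = c("E_sd", "T_sd", "P_sd"),
    T = c("T_mean", "T_min", "T_seas"),
    P = c("P_mean", "P_min", "P_seas"),
    E = c("T_min", "P_min"),
    S = c("T_seas", "P_seas")
  )
}
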