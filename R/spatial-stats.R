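#' Build a row-standardized spatial weights matrix from region centroids
#'
#' Links regions by great-circle distance between centroids, either to their
#' k nearest neighbours (asymmetric links allowed) or to all regions within a
#' distance cutoff, then row-standardizes so every non-empty row sums to 1.
#' Equidistant candidates are broken deterministically by region order.
#'
#' @param centroids Data frame with `region_id`, `lon`, `lat` (degrees).
#' @param k Number of nearest neighbours (default 8); ignored if
#'   `dist_cutoff` is given.
#' @param dist_cutoff Optional distance threshold in km.
#' @return A `spatial_weights` object: list with `W` (n x n matrix), `ids`,
#'   `scheme`, and `no_neighbours` (ids of empty rows).
#' @export
build_weights <- function(centroids, k = 8, dist_cutoff = NULL) {
  centroids <- as.data.frame(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(abs(centroids$lon) > 180) || any(abs(centroids$lat) > 90)) {
    stop("coordinates outside [-180,180] x [-90,90]", call. = FALSE)
  }
  ids <- as.character(centroids$region_id)
  D <- geosphere::distm(cbind(centroids$lon, centroids$lat),
                        fun = geosphere::distHaversine) / 1000
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (is.null(dist_cutoff)) {
    k <- min(k, n - 1L)
    for (i in seq_len(n)) {
      cand <- setdiff(seq_len(n), i)
      ord <- cand[order(D[i, cand], cand)]
      W[i, ord[seq_len(k)]] <- 1
    }
    scheme <- list(type = "knn", k = k)
  } else {
    W[D <= dist_cutoff] <- 1
    diag(W) <- 0
    scheme <- list(type = "distance", cutoff_km = dist_cutoff)
  }
  rs <- rowSums(W)
  no_neigh <- ids[rs == 0]
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  structure(list(W = W, ids = ids, scheme = scheme,
                 no_neighbours = no_neigh, dist_km = D),
            class = "spatial_weights")
}

.weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Moran's I spatial autocorrelation statistic
#'
#' @param values Numeric vector, one value per region (same order as `W`).
#' @param W A `spatial_weights` object or numeric matrix.
#' @return Moran's I; its expectation under no autocorrelation is
#'   `-1/(n-1)`.
#' @export
morans_i <- function(values, W) {
  Wm <- .weights_matrix(W)
  n <- length(values)
  stopifnot(nrow(Wm) == n)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("zero variance in values", call. = FALSE)
  s0 <- sum(Wm)
  if (s0 == 0) stop("weights matrix has no links", call. = FALSE)
  (n / s0) * as.numeric(z %*% Wm %*% z) / sum(z^2)
}

#' Profile log-likelihood of the SAR error model at a fixed lambda
#'
#' For the model `y = X beta + u`, `u = lambda W u + eps`, with
#' `eps ~ N(0, sigma^2 I)`: beta and sigma^2 are concentrated out at the
#' given lambda, leaving
#' `ll(lambda) = -n/2 (log(2 pi sigma_hat^2) + 1) + log|I - lambda W|`.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @param Wm Weights matrix.
#' @param lambda Spatial error parameter.
#' @param ev Optional precomputed eigenvalues of `Wm`.
#' @return Log-likelihood value.
#' @export
sar_profile_loglik <- function(y, X, Wm, lambda, ev = NULL) {
  if (is.null(ev)) ev <- eigen(Wm, only.values = TRUE)$values
  n <- length(y)
  ys <- y - lambda * as.numeric(Wm %*% y)
  Xs <- X - lambda * (Wm %*% X)
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  logdet <- sum(log(Mod(1 - lambda * ev)))
  -n / 2 * (log(2 * pi * rss / n) + 1) + logdet
}

#' Maximum-likelihood fit of a simultaneous autoregressive error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps` iid normal, by
#' profiling the likelihood over `lambda` (log-determinant from the
#' eigenvalues of `W`) and estimating `beta` by GLS at the optimum. The
#' search interval is the open interval between the reciprocals of the
#' extreme real eigenvalues of `W`, shrunk by `1e-6`; a coarse grid locates
#' the basin before bounded optimization at tolerance `1e-8`. With an empty
#' weights matrix the model reduces to OLS with `lambda = 0`.
#'
#' @param y Response vector.
#' @param X Predictor matrix (no intercept column; one is added), or `NULL`
#'   for an intercept-only model.
#' @param W A `spatial_weights` object or numeric matrix.
#' @param ev Optional precomputed eigenvalues of the weights matrix, to
#'   amortize the eigendecomposition over repeated fits with the same `W`.
#' @return A `sar_fit` list: `coefficients`, `se`, `lambda`, `loglik`,
#'   `pseudo_r2` (trend-only: `1 - RSS(X beta)/TSS(y)`), `n`, `p`,
#'   `converged`.
#' @export
sar_error_fit <- function(y, X = NULL, W, ev = NULL) {
  Wm <- .weights_matrix(W)
  n <- length(y)
  X <- if (is.null(X)) matrix(numeric(0), n, 0) else as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd) - 1L
  if (n <= p + 2) stop("need n > p + 2", call. = FALSE)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xd))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  if (is.null(ev)) ev <- eigen(Wm, only.values = TRUE)$values
  ev_real <- Re(ev[abs(Im(ev)) < 1e-8])
  no_spatial <- max(Mod(ev)) < 1e-12

  if (no_spatial) {
    lambda_hat <- 0
    converged <- TRUE
  } else {
    e_max <- max(ev_real)
    e_min <- min(ev_real)
    hi <- if (e_max > 0) 1 / e_max - 1e-6 else 1 - 1e-6
    lo <- if (e_min < 0) 1 / e_min + 1e-6 else -1 + 1e-6
    grid <- seq(lo, hi, length.out = 41)
    ll_grid <- vapply(grid, function(l) sar_profile_loglik(y, Xd, Wm, l, ev),
                      numeric(1))
    i_best <- which.max(ll_grid)
    bracket <- c(grid[max(1L, i_best - 1L)], grid[min(length(grid), i_best + 1L)])
    opt <- stats::optimize(function(l) -sar_profile_loglik(y, Xd, Wm, l, ev),
                           interval = bracket, tol = 1e-8)
    lambda_hat <- opt$minimum
    converged <- is.finite(opt$objective)
  }

  ys <- y - lambda_hat * as.numeric(Wm %*% y)
  Xs <- Xd - lambda_hat * (Wm %*% Xd)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  vcov_beta <- sigma2 * solve(crossprod(Xs))
  se <- sqrt(diag(vcov_beta))
  trend <- as.numeric(Xd %*% beta)
  tss <- sum((y - mean(y))^2)
  loglik <- sar_profile_loglik(y, Xd, Wm, lambda_hat, ev)
  structure(list(coefficients = beta, se = se, lambda = lambda_hat,
                 loglik = loglik,
                 pseudo_r2 = 1 - sum((y - trend)^2) / tss,
                 sigma2 = sigma2, n = n, p = p, converged = converged),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR error model (ML): n =", x$n, " lambda =", signif(x$lambda, 4),
      " pseudo-R2 (trend) =", signif(x$pseudo_r2, 4), "\n")
  print(data.frame(estimate = x$coefficients, se = x$se,
                   z = x$coefficients / x$se))
  invisible(x)
}

#' Standardized SAR regression coefficient of y on a single predictor
#'
#' Both variables are z-scored (mean 0, sd 1 with the n-1 denominator)
#' before fitting the SAR error model, so the slope is invariant to affine
#' rescaling of either variable.
#'
#' @param y Response vector (non-constant).
#' @param x Single predictor vector (non-constant).
#' @param W A `spatial_weights` object or matrix.
#' @param ev Optional precomputed eigenvalues of the weights matrix.
#' @return A list with `std_coef` (the slope) and `fit` (the full `sar_fit`).
#' @export
standardized_sar <- function(y, x, W, ev = NULL) {
  if (stats::sd(y) == 0) stop("response is constant", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  zy <- (y - mean(y)) / stats::sd(y)
  zx <- (x - mean(x)) / stats::sd(x)
  fit <- sar_error_fit(zy, matrix(zx, ncol = 1), W, ev = ev)
  list(std_coef = unname(fit$coefficients[2]), fit = fit)
}
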