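#' Build a penalized univariate smooth term
#'
#' Constructs a cubic B-spline basis of rank `df_max + 1` for one predictor,
#' with interior knots at quantiles of the training values, a second-order
#' coefficient-difference (P-spline) wiggliness penalty, and a separate
#' identity penalty on the wiggliness-penalty null space (the double-penalty
#' shrinkage construction: the second penalty can shrink the constant/linear
#' component of the smooth to zero, removing the term entirely). The basis
#' rank caps the term at `df_max` effective degrees of freedom once the
#' sum-to-zero centring is absorbed.
#'
#' @param values numeric training values of the predictor (>= 10 distinct).
#' @param df_max maximum effective degrees of freedom (default 4).
#' @param name predictor name carried in the term.
#' @return object of class `SmoothTerm`: basis knots and range, penalty
#'   matrices `S` (wiggliness) and `U` (null-space shrinkage), centring
#'   constants, smoothing parameters `lambda`/`lambda_star` (NA until fitted).
#' @export
build_smooth <- function(values, df_max = 4, name = "x") {
  values <- values[is.finite(values)]
  ud <- unique(values)
  if (length(ud) < 10)
    stop(sprintf("predictor '%s' has fewer than 10 distinct values", name))
  if (stats::sd(values) == 0)
    stop(sprintf("predictor '%s' is constant", name))
  K <- df_max + 1L
  n_int <- K - 4L
  lo <- min(values); hi <- max(values)
  interior <- if (n_int > 0)
    stats::quantile(values, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
  else numeric(0)
  interior <- pmin(pmax(interior, lo + 1e-8 * (hi - lo)), hi - 1e-8 * (hi - lo))
  knots <- c(rep(lo, 4), interior, rep(hi, 4))
  D2 <- diff(diag(K), differences = 2)
  S <- crossprod(D2)
  # null space of S: coefficient vectors constant or linear in basis index
  N <- qr.Q(qr(cbind(rep(1, K), seq_len(K) - (K + 1) / 2)))
  U <- N %*% t(N)
  term <- structure(
    list(name = name, knots = knots, lo = lo, hi = hi, K = K,
         S = S, U = U, colmeans = NULL,
         lambda = NA_real_, lambda_star = NA_real_),
    class = "SmoothTerm")
  term$colmeans <- colMeans(eval_smooth(term, values, centre = FALSE))
  term
}

#' Evaluate a smooth term's basis at new values
#'
#' Values outside the training range are clamped to it (constant
#' extrapolation of the basis).
#'
#' @param term a `SmoothTerm`.
#' @param x numeric values.
#' @param centre subtract the training column means (the sum-to-zero
#'   centring used in the model design)?
#' @return n x K basis matrix.
#' @export
eval_smooth <- function(term, x, centre = TRUE) {
  xc <- pmin(pmax(x, term$lo), term$hi)
  B <- splines::splineDesign(term$knots, xc, ord = 4, outer.ok = FALSE)
  if (centre && !is.null(term$colmeans))
    B <- sweep(B, 2, term$colmeans)
  B
}

#' Build the low-rank spatial smooth over coordinates
#'
#' A Gaussian radial basis over (x, y) with centres chosen by k-means on the
#' training coordinates (a space-filling design over the data support),
#' bandwidth the median inter-centre distance, and a ridge penalty on the
#' coefficients so the whole surface can shrink to zero.
#'
#' @param x,y training coordinates (m).
#' @param rank number of basis centres (default 30).
#' @param seed integer seed for the k-means initialisation.
#' @return object of class `SpatialTerm`.
#' @export
build_spatial_term <- function(x, y, rank = 30, seed = 1L) {
  xy <- unique(cbind(x, y))
  k <- min(rank, nrow(xy))
  set.seed(split_seed(seed, 17))
  centres <- if (nrow(xy) > k)
    stats::kmeans(xy, centers = k, iter.max = 50, nstart = 1)$centers
  else xy
  dc <- stats::dist(centres)
  sigma <- if (length(dc)) max(stats::median(dc), 1e-6) else 1
  term <- structure(
    list(centres = centres, sigma = sigma, K = nrow(centres),
         S = diag(nrow(centres)), U = matrix(0, nrow(centres), nrow(centres)),
         colmeans = NULL, lambda = NA_real_, lambda_star = 0),
    class = "SpatialTerm")
  term$colmeans <- colMeans(eval_spatial(term, x, y, centre = FALSE))
  term
}

#' Evaluate the spatial basis at coordinates
#'
#' @param term a `SpatialTerm`.
#' @param x,y coordinates.
#' @param centre subtract training column means?
#' @return n x K basis matrix.
#' @export
eval_spatial <- function(term, x, y, centre = TRUE) {
  B <- exp(-(outer(x, term$centres[, 1], "-")^2 +
             outer(y, term$centres[, 2], "-")^2) / (2 * term$sigma^2))
  if (centre && !is.null(term$colmeans)) B <- sweep(B, 2, term$colmeans)
  B
}
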