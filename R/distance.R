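#' Jensen-Shannon divergence between two distributions
#'
#' JSD(P, Q) = [KL(P || M) + KL(Q || M)] / 2 with M the equal-weight
#' mixture of P and Q, in natural log units, so the value lies in
#' [0, ln 2]. Inputs must share a support: two `discrete` distributions on
#' the same integer support, or two `continuous_density` distributions on
#' the same grid (continuous densities are compared via their grid weights).
#'
#' @param P,Q [individual_distribution()] objects of matching kind, or bare
#'   probability vectors of equal length.
#' @return Non-negative scalar, at most `log(2)`.
#' @export
jsd <- function(P, Q) {
  pq <- common_densities(P, Q)
  p <- pq$p; q <- pq$q
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log(a[i]) - log(m[i])))
  }
  d <- (kl(p) + kl(q)) / 2
  max(0, min(d, log(2)))
}

#' Wasserstein-1 distance between two distributions
#'
#' The one-dimensional earth-mover distance, the integral of
#' `|F_P(x) - F_Q(x)|`. For discrete count distributions on a common
#' support this is the exact sum of absolute CDF differences times the
#' (unit) bin widths; for two empirical samples, the equivalent
#' quantile-function form on the step CDFs.
#'
#' @inheritParams jsd
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(P, Q) {
  if (is_empirical(P) || is_empirical(Q)) {
    stopifnot(is_empirical(P), is_empirical(Q))
    return(wasserstein1_sample(P$values, Q$values))
  }
  pq <- common_densities(P, Q)
  dx <- if (is.null(pq$x)) 1 else diff(pq$x)
  cp <- cumsum(pq$p); cq <- cumsum(pq$q)
  if (length(dx) == 1L && is.null(pq$x)) {
    d <- sum(abs(cp - cq))               # unit bins, top bin CDF diff is 0
  } else {
    # trapezoid on |F_P - F_Q| would smooth the step CDFs; for densities on
    # a grid use left-step CDF increments over the grid spacing
    d <- sum(abs(utils::head(cp, -1) - utils::head(cq, -1)) * dx)
  }
  if (d < 1e-14) 0 else d
}

# exact W1 between two empirical step CDFs (arbitrary sample sizes)
wasserstein1_sample <- function(x, y) {
  xs <- sort(x); ys <- sort(y)
  breaks <- sort(unique(c(xs, ys)))
  if (length(breaks) < 2L) return(0)
  Fx <- stats::ecdf(xs)(utils::head(breaks, -1))
  Fy <- stats::ecdf(ys)(utils::head(breaks, -1))
  d <- sum(abs(Fx - Fy) * diff(breaks))
  if (d < 1e-14) 0 else d
}

is_empirical <- function(P)
  inherits(P, "individual_distribution") && P$kind == "empirical_sample"

# extract a pair of comparable density vectors (and grid for continuous)
common_densities <- function(P, Q) {
  if (is.numeric(P) && is.numeric(Q)) {
    stopifnot(length(P) == length(Q))
    return(list(p = check_density(P), q = check_density(Q), x = NULL))
  }
  stopifnot(inherits(P, "individual_distribution"),
            inherits(Q, "individual_distribution"),
            P$status != "failed", Q$status != "failed")
  if (P$kind == "parametric") P <- discretize(P)
  if (Q$kind == "parametric") Q <- discretize(Q)
  stopifnot(P$kind == Q$kind)
  if (P$kind == "discrete") {
    K <- max(length(P$density), length(Q$density))
    list(p = check_density(pad_density(P$density, K)),
         q = check_density(pad_density(Q$density, K)), x = NULL)
  } else if (P$kind == "continuous_density") {
    if (length(P$grid) != length(Q$grid) ||
        any(abs(P$grid - Q$grid) > 1e-9))
      stop("continuous densities must share a grid")
    w <- grid_weights(P$grid)
    list(p = check_density(P$density * w), q = check_density(Q$density * w),
         x = P$grid)
  } else stop("unsupported distribution kind for density comparison")
}

# trapezoid quadrature weights, renormalised so masses sum to 1
grid_weights <- function(x) {
  n <- length(x)
  w <- c(diff(x)[1] / 2, (x[-(1:2)] - x[1:(n - 2)]) / 2, diff(x)[n - 1] / 2)
  w
}

check_density <- function(p, tol = 1e-6) {
  stopifnot(all(p >= -1e-12))
  s <- sum(p)
  if (abs(s - 1) > tol) stop("density does not sum/integrate to 1 (sum = ",
                             format(s), ")")
  p / s
}

pad_density <- function(p, K) {
  if (length(p) >= K) return(p)
  # tail bin stays at the end of the enlarged support
  c(utils::head(p, -1), rep(0, K - length(p)), utils::tail(p, 1))
}

#' Pairwise distance matrix across individuals for one gene
#'
#' @param dists named list of [individual_distribution()] objects, in
#'   individual order (names are individual ids).
#' @param metric `"was"` (Wasserstein-1, default) or `"jsd"`.
#' @param gene_id optional gene label carried in the result.
#' @return A `dist_matrix` object: the symmetric n x n matrix with zero
#'   diagonal, with attributes `metric` and `gene_id`. If any distribution
#'   has status `"failed"`, returns `NULL` (the gene is untestable).
#' @export
build_distance_matrix <- function(dists, metric = c("was", "jsd"),
                                  gene_id = NULL) {
  metric <- match.arg(metric)
  n <- length(dists)
  stopifnot(n >= 3)
  if (any(vapply(dists, function(d) d$status == "failed", logical(1))))
    return(NULL)
  # discretize parametric fits once, on a common support
  if (all(vapply(dists, function(d) d$kind == "parametric", logical(1)))) {
    K <- max(vapply(dists, support_bound, integer(1)))
    dists <- lapply(dists, discretize, K = K)
  }
  fun <- if (metric == "was") wasserstein1 else jsd
  D <- matrix(0, n, n, dimnames = list(names(dists), names(dists)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- fun(dists[[i]], dists[[j]])
    D[i, j] <- D[j, i] <- if (d < 1e-14) 0 else d
  }
  structure(D, metric = metric, gene_id = gene_id, class = c("dist_matrix", "matrix"))
}
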