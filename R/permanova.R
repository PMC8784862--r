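#' Gower-centered kernel of a distance matrix
#'
#' Computes `A = -D^2 / 2` (elementwise square), double-centers it,
#' `G = (I - 11'/n) A (I - 11'/n)`, and truncates negative eigenvalues of
#' `G` to zero so the kernel is positive semidefinite. Row and column sums
#' of the result are zero (truncation preserves this: the all-ones vector is
#' in the null space, so every eigenvector with nonzero eigenvalue is
#' orthogonal to it).
#'
#' @param D symmetric distance matrix (e.g. from
#'   [build_distance_matrix()]).
#' @return A `centered_kernel` matrix with attribute `n_negative_eigen`,
#'   the number of eigenvalues truncated.
#' @export
gower_center <- function(D) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm_) + gm
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  neg <- e$values < 0
  lam <- pmax(e$values, 0)
  G <- e$vectors %*% (lam * t(e$vectors))
  G <- (G + t(G)) / 2
  dimnames(G) <- dimnames(D)
  structure(G, n_negative_eigen = sum(neg & abs(e$values) > 1e-12),
            class = c("centered_kernel", "matrix"))
}

#' Build a design matrix from individual metadata
#'
#' Intercept + variable of interest + individual-level covariates, rows in
#' the given individual order. A two-level factor/character variable of
#' interest is coded 0/1.
#'
#' @param indiv_meta data frame with column `individual`.
#' @param x_column name of the variable of interest.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param individuals individual ids fixing the row order; default the
#'   order in `indiv_meta`.
#' @return Numeric matrix with columns `(Intercept)`, `x_column`,
#'   covariates.
#' @export
design_matrix <- function(indiv_meta, x_column, covariates = character(),
                          individuals = indiv_meta$individual) {
  idx <- match(individuals, indiv_meta$individual)
  stopifnot(!anyNA(idx))
  im <- indiv_meta[idx, , drop = FALSE]
  if (!x_column %in% names(im)) stop("x_column '", x_column, "' not found")
  x <- im[[x_column]]
  if (!is.numeric(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2L)
      stop("non-numeric variable of interest must have exactly 2 levels")
    x <- as.numeric(as.character(x) == lev[2L])
  }
  Z <- cbind(`(Intercept)` = 1, x)
  colnames(Z)[2L] <- x_column
  for (cv in covariates) {
    v <- im[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found in indiv_meta")
    Z <- cbind(Z, as.numeric(v))
    colnames(Z)[ncol(Z)] <- cv
  }
  rownames(Z) <- individuals
  if (qr(Z)$rank < ncol(Z)) stop("design matrix is rank deficient")
  Z
}

#' Distance-based pseudo-F statistic
#'
#' `F = tr(H G H) / tr[(I - H) G (I - H)]` with `H = Z (Z'Z)^-1 Z'` the hat
#' matrix of the full design (intercept, variable of interest, covariates).
#' Because `H` is idempotent the traces are computed as `tr(Q'GQ)` and
#' `tr(G) - tr(Q'GQ)` from a thin QR of `Z`.
#'
#' @param G a [gower_center()] kernel (any symmetric matrix is accepted).
#' @param Z numeric design matrix, full column rank, `nrow(Z) > ncol(Z)`.
#' @return Scalar F; `NA` with attribute `degenerate = TRUE` when the
#'   residual trace vanishes (saturated design).
#' @export
pseudo_F <- function(G, Z) {
  G <- unclass(G)
  stopifnot(nrow(G) == ncol(G), nrow(Z) == nrow(G))
  if (nrow(Z) < ncol(Z) + 1L) stop("need n >= q + 1")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("design matrix is rank deficient")
  Q <- qr.Q(qz)
  num <- sum(Q * (G %*% Q))            # tr(Q' G Q) = tr(H G H)
  den <- sum(diag(G)) - num            # tr((I-H) G (I-H)), H idempotent
  if (den < 1e-12) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  max(num, 0) / den
}

#' Per-gene permutation test result
#'
#' @param gene_id gene label.
#' @param F_obs observed pseudo-F.
#' @param pvalue permutation p-value.
#' @param n_perm_used permutations actually evaluated.
#' @param status `"ok"`, `"fit_failed"` or `"degenerate"`.
#' @param seed per-gene seed used for the permutation stream.
#' @return A `test_result` list.
#' @export
test_result <- function(gene_id, F_obs = NA_real_, pvalue = NA_real_,
                        n_perm_used = NA_integer_, status = "ok",
                        seed = NA_integer_) {
  structure(list(gene_id = gene_id, F_stat = as.numeric(F_obs),
                 pvalue = as.numeric(pvalue),
                 n_perm_used = as.integer(n_perm_used), status = status,
                 seed = seed),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result %s: F=%.4g p=%.4g (%d perms, %s)\n",
              x$gene_id, x$F_stat, x$pvalue, x$n_perm_used, x$status))
  invisible(x)
}

# PERMANOVA-S style redraw of X given covariates
resample_x <- function(x, covars) {
  binary <- all(x %in% c(0, 1))
  if (ncol(covars) == 0L) {
    if (binary) return(sample(x)) else return(sample(x))
  }
  if (binary) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, covars), x,
                                           family = stats::binomial()))
    p <- fit$fitted.values
    stats::rbinom(length(x), 1L, p)
  } else {
    fit <- stats::lm.fit(cbind(1, covars), x)
    fit$fitted.values + sample(fit$residuals)
  }
}

#' Permutation test of association between a kernel and a phenotype
#'
#' Computes the observed pseudo-F, then rebuilds the design `n_perm` times
#' with only the variable-of-interest column permuted (or redrawn given the
#' covariates in `resample` mode), reusing the same kernel `G` throughout —
#' permuting X with G fixed is algebraically identical to permuting G's
#' rows and columns with X fixed. P-value uses the add-one estimator
#' `(1 + #\{F_b >= F_obs\}) / (1 + B)`; ties count as exceedances.
#'
#' For a binary variable with few distinct reassignments (`choose(n, n1) <=
#' n_perm`) the null is enumerated exhaustively and the p-value is the
#' exact proportion of assignments (observed included) with `F >= F_obs`.
#' With `early_stop = TRUE` (default) permutation stops after `n_min`
#' permutations once the running p-value exceeds 0.5 — clearly null genes
#' get cheap, coarse p-values; small p-values always use the full budget.
#'
#' @param G a [gower_center()] kernel.
#' @param Z design matrix from [design_matrix()].
#' @param x_col name of the variable-of-interest column in `Z`.
#' @param n_perm maximum number of permutations (>= 99).
#' @param seed optional integer seed for the permutation stream.
#' @param mode `"permute"` (default) or `"resample"`.
#' @param early_stop logical; adaptive stopping as described.
#' @param n_min permutations before early stopping may trigger.
#' @param gene_id label for the result.
#' @return A [test_result()].
#' @export
permutation_test <- function(G, Z, x_col, n_perm = 999, seed = NULL,
                             mode = c("permute", "resample"),
                             early_stop = TRUE, n_min = 100,
                             gene_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 99, x_col %in% colnames(Z))
  if (!is.null(seed)) set.seed(seed)
  F_obs <- pseudo_F(G, Z)
  if (is.na(F_obs))
    return(test_result(gene_id, status = "degenerate", seed = seed))
  x <- Z[, x_col]
  covars <- Z[, setdiff(colnames(Z), c("(Intercept)", x_col)), drop = FALSE]
  binary <- all(x %in% c(0, 1))
  if (binary && min(table(x)) < 3L)
    warning("severe group imbalance (a group has < 3 individuals): ",
            "few distinct permutations exist; the p-value is coarse")

  Zp <- Z
  tol <- 1e-12
  if (binary && mode == "permute" &&
      choose(length(x), sum(x == 1)) <= n_perm) {
    idx1 <- utils::combn(length(x), sum(x == 1))
    Fs <- apply(idx1, 2L, function(ii) {
      xp <- numeric(length(x)); xp[ii] <- 1
      Zp[, x_col] <- xp
      tryCatch(pseudo_F(G, Zp), error = function(e) NA_real_)
    })
    p <- mean(Fs >= F_obs - tol, na.rm = TRUE)
    return(test_result(gene_id, F_obs, p, ncol(idx1), "ok", seed))
  }

  exc <- 0L; b <- 0L
  for (i in seq_len(n_perm)) {
    xp <- if (mode == "permute") sample(x) else resample_x(x, covars)
    Zp[, x_col] <- xp
    Fb <- tryCatch(pseudo_F(G, Zp), error = function(e) NA_real_)
    b <- b + 1L
    if (!is.na(Fb) && Fb >= F_obs - tol) exc <- exc + 1L
    if (early_stop && b >= n_min && (1 + exc) / (1 + b) > 0.5) break
  }
  test_result(gene_id, F_obs, (1 + exc) / (1 + b), b, "ok", seed)
}
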