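#' Pseudo-bulk count matrix
#'
#' Sums each gene's counts over all cells of the same individual, giving a
#' genes x individuals integer matrix (column order follows
#' `indiv_meta$individual`).
#'
#' @param data a [cell_data()] object.
#' @return Integer matrix with gene row names and individual column names.
#' @export
pseudobulk <- function(data) {
  stopifnot(inherits(data, "cell_data"))
  inds <- data$indiv_meta$individual
  m <- as.matrix(data$counts)
  grp <- factor(data$cell_meta$individual, levels = inds)
  pb <- t(rowsum(t(m), grp))
  storage.mode(pb) <- "integer"
  pb
}

#' Negative binomial Wald test on pseudo-bulk counts
#'
#' The pseudo-bulk baseline: per gene, an NB regression of the
#' per-individual summed counts on intercept + variable of interest (+
#' covariates) with a log total-depth offset, and a Wald test on the
#' variable-of-interest coefficient. This deliberately plain mean-model
#' baseline detects mean shifts but is blind to variance-only signals.
#' Falls back to Poisson when the NB dispersion estimation fails; `NA` when
#' neither fit converges.
#'
#' @param pb matrix from [pseudobulk()].
#' @param x numeric vector (length = individuals) of the variable of
#'   interest; must not be constant.
#' @param covariates optional numeric matrix of individual-level
#'   covariates.
#' @param offset log total-depth offset; default `log(colSums(pb))`.
#' @return Data frame with columns `gene_id`, `estimate` (log fold change
#'   per unit of `x`), `pvalue`.
#' @export
nb_pseudobulk_test <- function(pb, x, covariates = NULL, offset = NULL) {
  x <- as.numeric(x)
  stopifnot(ncol(pb) == length(x))
  if (stats::var(x) == 0) stop("variable of interest is constant")
  if (is.null(offset)) offset <- log(colSums(pb))
  covariates <- if (is.null(covariates)) matrix(numeric(0), length(x), 0)
  else as.matrix(covariates)
  stopifnot(length(x) >= ncol(covariates) + 3L)
  dat <- data.frame(x = x, covariates, check.names = FALSE)
  rhs <- paste(c("x", sprintf("`%s`", colnames(covariates))), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs, "+ offset(off)"))
  one <- function(y) {
    dat$y <- y; dat$off <- offset
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(form, data = dat)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      fit <- tryCatch(suppressWarnings(
        stats::glm(form, data = dat, family = stats::poisson())),
        error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
    co <- summary(fit)$coefficients
    if (!"x" %in% rownames(co)) return(c(NA_real_, NA_real_))
    c(co["x", 1L], co["x", 4L])
  }
  est <- t(apply(pb, 1L, one))
  data.frame(gene_id = rownames(pb), estimate = est[, 1L],
             pvalue = est[, 2L], stringsAsFactors = FALSE)
}

#' Storey q-values with fixed lambda = 0.5
#'
#' `pi0 = mean(p > 0.5) / 0.5` clamped to `(0, 1]`, then
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank_j`, clamped to
#' `[0, 1]`. With `pi0 = 1` this is exactly Benjamini-Hochberg. NAs are
#' passed through.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param pi0 override the null-proportion estimate (e.g. 1 for BH).
#' @param lambda tuning point of the Storey estimator (default 0.5).
#' @return Numeric vector of q-values with attribute `pi0`.
#' @export
storey_qvalues <- function(pvals, pi0 = NULL, lambda = 0.5) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  stopifnot(length(p) >= 10L, all(p >= 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) pi0 <- mean(p > lambda) / (1 - lambda)
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p, decreasing = TRUE)
  q_sorted <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  out <- rep(NA_real_, length(pvals))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Estimated proportion of differentially expressed genes
#'
#' `1 - pi0_hat = 1 - 2 * mean(p > 0.5)`, clamped to `[0, 1]`: under the
#' null the p-values are uniform, so twice the fraction above 0.5 estimates
#' the null proportion.
#'
#' @param pvals numeric vector of p-values (NAs dropped).
#' @return Scalar in `[0, 1]`.
#' @export
de_proportion <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  max(0, min(1, 1 - 2 * mean(p > 0.5)))
}

#' Pseudo-dispersion from moments
#'
#' Inverts the NB mean-variance relation `var = mu + mu^2/theta`:
#' `theta_hat = mu^2 / (var - mu)`. When `var <= mu` (no overdispersion)
#' the sentinel `Inf` is returned and flagged in the `underdispersed`
#' attribute.
#'
#' @param mu,var estimated mean(s) and variance(s), positive; vectorised.
#' @return Numeric vector with logical attribute `underdispersed`.
#' @export
pseudo_dispersion <- function(mu, var) {
  stopifnot(all(mu > 0), all(var > 0), length(mu) == length(var))
  under <- var <= mu
  out <- ifelse(under, Inf, mu^2 / (var - mu))
  attr(out, "underdispersed") <- under
  out
}

#' Per-individual moment association test (exploratory, non-canonical)
#'
#' Computes a per-individual scalar summary of one gene — the mean or the
#' pseudo-dispersion of that individual's counts — and runs the same
#' Gower/pseudo-F permutation machinery on the absolute-difference distance
#' matrix of the summaries. A rough way to ask whether a detected signal
#' lives in the mean or in the dispersion; it is not part of the canonical
#' per-gene test.
#'
#' @param data a [cell_data()] object.
#' @param gene gene id.
#' @param x_column variable of interest in `data$indiv_meta`.
#' @param summary `"mean"` or `"dispersion"`.
#' @param n_perm,seed passed to [permutation_test()].
#' @return A [test_result()].
#' @export
moment_association_test <- function(data, gene, x_column,
                                    summary = c("mean", "dispersion"),
                                    n_perm = 999, seed = 1) {
  summary <- match.arg(summary)
  i <- match(gene, data$gene_ids)
  if (is.na(i)) stop("gene '", gene, "' not found")
  y <- as.numeric(data$counts[i, ])
  inds <- data$indiv_meta$individual
  val <- vapply(inds, function(id) {
    yy <- y[data$cell_meta$individual == id]
    if (summary == "mean") mean(yy)
    else {
      m <- mean(yy); v <- stats::var(yy)
      if (m <= 0 || v <= 0) return(NA_real_)
      th <- pseudo_dispersion(m, v)
      if (is.infinite(th)) NA_real_ else log(th)
    }
  }, numeric(1))
  if (anyNA(val)) return(test_result(gene, status = "fit_failed", seed = seed))
  D <- abs(outer(val, val, "-"))
  dimnames(D) <- list(inds, inds)
  Z <- design_matrix(data$indiv_meta, x_column, character(), inds)
  permutation_test(gower_center(D), Z, x_column, n_perm = n_perm,
                   seed = seed, gene_id = gene)
}
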