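#' Individual-level expression distribution container
#'
#' One individual's gene-expression law for a single gene, in one of four
#' representations: `parametric` (zero-inflated negative binomial with zero
#' proportion `pi`, mean `mu`, overdispersion `theta`; `pi = 0` gives plain
#' NB and `theta = Inf` the Poisson limit), `discrete` (a probability vector
#' over integer counts 0..K, tail mass folded into the top bin),
#' `continuous_density` (grid + density values), or `empirical_sample`
#' (covariate-adjusted expression values, one per cell).
#'
#' @param kind one of `"parametric"`, `"discrete"`, `"continuous_density"`,
#'   `"empirical_sample"`.
#' @param pi,mu,theta ZINB parameters (parametric kind).
#' @param density probability vector over `support` (discrete kind) or
#'   density values over `grid` (continuous kind).
#' @param support integer support 0..K (discrete kind).
#' @param grid numeric grid (continuous kind).
#' @param values adjusted expression values (empirical_sample kind).
#' @param status one of `"ok"`, `"fallback_nb"`, `"fallback_poisson"`,
#'   `"failed"`.
#' @return An object of class `individual_distribution`.
#' @export
individual_distribution <- function(kind, pi = NA_real_, mu = NA_real_,
                                    theta = NA_real_, density = NULL,
                                    support = NULL, grid = NULL,
                                    values = NULL, status = "ok") {
  kind <- match.arg(kind, c("parametric", "discrete", "continuous_density",
                            "empirical_sample"))
  if (status != "failed") {
    if (kind == "parametric") {
      stopifnot(is.finite(pi), pi >= 0, pi < 1, is.finite(mu), mu > 0,
                theta > 0)
    } else if (kind == "discrete") {
      stopifnot(!is.null(density), all(density >= -1e-12),
                abs(sum(density) - 1) < 1e-10)
    } else if (kind == "continuous_density") {
      stopifnot(!is.null(density), !is.null(grid),
                length(density) == length(grid))
    } else {
      stopifnot(!is.null(values))
    }
  }
  structure(list(kind = kind, pi = pi, mu = mu, theta = theta,
                 density = density, support = support, grid = grid,
                 values = values, status = status),
            class = "individual_distribution")
}

#' @export
print.individual_distribution <- function(x, ...) {
  cat("individual_distribution [", x$kind, ", status=", x$status, "]\n",
      sep = "")
  if (x$kind == "parametric" && x$status != "failed")
    cat(sprintf("  pi=%.4g  mu=%.4g  theta=%.4g\n", x$pi, x$mu, x$theta))
  invisible(x)
}

failed_distribution <- function(kind = "parametric")
  individual_distribution(kind, status = "failed")

# ZINB pmf; theta = Inf is the Poisson limit, pi = 0 plain NB
dzinb <- function(y, pi, mu, theta) {
  nb <- if (is.finite(theta)) stats::dnbinom(y, size = theta, mu = mu)
        else stats::dpois(y, lambda = mu)
  pi * (y == 0) + (1 - pi) * nb
}

rzinb <- function(n, pi, mu, theta) {
  nb <- if (is.finite(theta)) stats::rnbinom(n, size = theta, mu = mu)
        else stats::rpois(n, lambda = mu)
  nb * (stats::runif(n) >= pi)
}

as_covar_matrix <- function(covars, n) {
  if (is.null(covars)) return(matrix(numeric(0), nrow = n, ncol = 0))
  covars <- as.matrix(covars)
  stopifnot(nrow(covars) == n)
  covars
}

default_ref_covars <- function(covars) apply(covars, 2L, stats::median)

#' Fit an individual's conditional negative binomial distribution
#'
#' Fits an NB log-linear regression of one individual's per-cell counts on
#' cell-level covariates (log read depth at minimum) and returns the
#' conditional NB distribution at a reference covariate value — by default
#' the per-covariate median, so distributions of different individuals are
#' comparable at a common read depth. If the dispersion estimate exceeds
#' `1e4` (no evidence of overdispersion) the fit collapses to Poisson
#' (`theta = Inf`, status `fallback_poisson`).
#'
#' @param counts integer vector of one individual's per-cell counts for
#'   one gene.
#' @param covars numeric matrix of cell-level covariates (rows = cells);
#'   `NULL` for an intercept-only fit.
#' @param ref_covars numeric vector, the covariate value at which the
#'   conditional distribution is evaluated; defaults to column medians of
#'   `covars`. For pooled analyses pass the medians over *all* cells.
#' @param min_cells minimum number of cells required (default 10).
#' @return An [individual_distribution()] of kind `"parametric"` with
#'   `pi = 0`; status `"failed"` for all-zero or zero-variance input or an
#'   unfittable model.
#' @export
fit_nb_individual <- function(counts, covars = NULL, ref_covars = NULL,
                              min_cells = 10) {
  counts <- as.numeric(counts)
  n <- length(counts)
  covars <- as_covar_matrix(covars, n)
  if (n < max(min_cells, ncol(covars) + 2L)) return(failed_distribution())
  if (all(counts == 0) || stats::var(counts) == 0) return(failed_distribution())
  if (is.null(ref_covars)) ref_covars <- default_ref_covars(covars)

  dat <- data.frame(y = counts, covars, check.names = FALSE)
  form <- if (ncol(covars)) stats::as.formula(
    paste("y ~", paste(sprintf("`%s`", colnames(covars)), collapse = " + ")))
  else y ~ 1
  newd <- if (ncol(covars)) {
    nd <- as.data.frame(as.list(ref_covars))
    names(nd) <- colnames(covars)
    nd
  } else data.frame(row.names = "ref")

  fit <- tryCatch(suppressWarnings(MASS::glm.nb(form, data = dat)),
                  error = function(e) NULL)
  if (!is.null(fit) && fit$converged && is.finite(fit$theta) &&
      fit$theta <= 1e4) {
    mu <- as.numeric(exp(stats::predict(fit, newdata = newd)))
    if (is.finite(mu) && mu > 0)
      return(individual_distribution("parametric", pi = 0, mu = mu,
                                     theta = fit$theta, status = "ok"))
  }
  # Poisson fallback: no overdispersion, or NB iteration failed
  pfit <- tryCatch(suppressWarnings(
    stats::glm(form, data = dat, family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(pfit) || !pfit$converged) return(failed_distribution())
  mu <- as.numeric(exp(stats::predict(pfit, newdata = newd)))
  if (!is.finite(mu) || mu <= 0) return(failed_distribution())
  individual_distribution("parametric", pi = 0, mu = mu, theta = Inf,
                          status = "fallback_poisson")
}

# negative log-likelihood of the ZINB regression
zinb_nll <- function(par, y, X, Xz) {
  p <- ncol(X); pz <- ncol(Xz)
  beta <- par[seq_len(p)]
  gamma <- par[p + seq_len(pz)]
  theta <- exp(par[p + pz + 1L])
  mu <- exp(drop(X %*% beta))
  pi <- stats::plogis(drop(Xz %*% gamma))
  is0 <- y == 0
  ll0 <- log(pi[is0] + (1 - pi[is0]) *
               stats::dnbinom(0, size = theta, mu = mu[is0]) + 1e-300)
  ll1 <- log(1 - pi[!is0] + 1e-300) +
    stats::dnbinom(y[!is0], size = theta, mu = mu[!is0], log = TRUE)
  -(sum(ll0) + sum(ll1))
}

#' Fit an individual's conditional zero-inflated negative binomial
#'
#' Maximum-likelihood ZINB regression: log link for the NB mean, logit link
#' for the zero-inflation probability, both on the supplied cell-level
#' covariates (the zero part can be restricted to an intercept with
#' `zero_covars = "intercept"`). Returns the conditional (`pi`, `mu`,
#' `theta`) at the reference covariate value. If the zero-inflation estimate
#' collapses (conditional `pi < 1e-4`) or the optimisation fails, the fit
#' falls back to [fit_nb_individual()] with status `"fallback_nb"`.
#'
#' @inheritParams fit_nb_individual
#' @param zero_covars `"same"` (default: the NB covariates also drive the
#'   zero component) or `"intercept"`.
#' @return An [individual_distribution()] of kind `"parametric"`.
#' @export
fit_zinb_individual <- function(counts, covars = NULL, ref_covars = NULL,
                                min_cells = 10, zero_covars = c("same", "intercept")) {
  zero_covars <- match.arg(zero_covars)
  counts <- as.numeric(counts)
  n <- length(counts)
  covars <- as_covar_matrix(covars, n)
  if (n < max(min_cells, ncol(covars) + 2L)) return(failed_distribution())
  if (all(counts == 0) || stats::var(counts) == 0) return(failed_distribution())
  if (is.null(ref_covars)) ref_covars <- default_ref_covars(covars)
  nb <- fit_nb_individual(counts, covars, ref_covars, min_cells)
  if (nb$status == "failed") return(nb)
  if (!any(counts == 0)) {            # nothing for the zero component to do
    nb$status <- "fallback_nb"
    return(nb)
  }

  X <- cbind(1, covars)
  Xz <- if (zero_covars == "same") X else X[, 1L, drop = FALSE]
  # start from the NB fit: recover its linear predictor via a log-linear fit
  start_beta <- tryCatch({
    f <- suppressWarnings(stats::glm(counts ~ covars, family = stats::poisson()))
    unname(stats::coef(f))
  }, error = function(e) c(log(mean(counts) + 0.01), rep(0, ncol(covars))))
  start <- c(start_beta, c(stats::qlogis(0.05), rep(0, ncol(Xz) - 1L)),
             log(if (is.finite(nb$theta)) nb$theta else 100))
  opt <- tryCatch(suppressWarnings(
    stats::optim(start, zinb_nll, y = counts, X = X, Xz = Xz,
                 method = "BFGS", control = list(maxit = 300))),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par))) {
    nb$status <- "fallback_nb"
    return(nb)
  }
  p <- ncol(X); pz <- ncol(Xz)
  xref <- c(1, ref_covars)
  mu <- exp(sum(xref * opt$par[seq_len(p)]))
  zref <- if (zero_covars == "same") xref else 1
  pi <- stats::plogis(sum(zref * opt$par[p + seq_len(pz)]))
  theta <- exp(opt$par[p + pz + 1L])
  if (!is.finite(mu) || mu <= 0 || !is.finite(pi)) {
    nb$status <- "fallback_nb"
    return(nb)
  }
  if (pi < 1e-4) {                    # zero inflation collapsed: plain NB
    nb$status <- "fallback_nb"
    return(nb)
  }
  if (theta > 1e4) theta <- Inf
  individual_distribution("parametric", pi = pi, mu = mu, theta = theta,
                          status = "ok")
}

# smallest K with ZINB upper-tail mass beyond K below tol
support_bound <- function(dist, tol = 1e-6, cap = NULL) {
  q <- if (is.finite(dist$theta))
    stats::qnbinom(tol / max(1 - dist$pi, 1e-12), size = dist$theta,
                   mu = dist$mu, lower.tail = FALSE)
  else stats::qpois(tol / max(1 - dist$pi, 1e-12), lambda = dist$mu,
                    lower.tail = FALSE)
  K <- as.integer(q) + 1L
  if (!is.null(cap)) K <- min(K, as.integer(cap))
  max(K, 1L)
}

#' Discretize a parametric distribution onto 0..K
#'
#' Evaluates the ZINB/NB/Poisson pmf on 0..K-1 and folds all remaining tail
#' mass into bin K, so the result is an exact probability vector. If `K` is
#' omitted it is chosen as the smallest value leaving tail mass below 1e-6.
#'
#' @param dist a parametric [individual_distribution()].
#' @param K top bin index (support is 0..K).
#' @return An [individual_distribution()] of kind `"discrete"`.
#' @export
discretize <- function(dist, K = NULL) {
  stopifnot(inherits(dist, "individual_distribution"),
            dist$kind == "parametric", dist$status != "failed")
  if (is.null(K)) K <- support_bound(dist)
  K <- as.integer(K)
  stopifnot(K >= 1L)
  p <- dzinb(0:(K - 1L), dist$pi, dist$mu, dist$theta)
  tail <- max(0, 1 - sum(p))
  if (tail > 0.1)
    warning("discretization support too small: top bin holds ",
            format(tail, digits = 3), " of the mass")
  individual_distribution("discrete", density = c(p, tail), support = 0:K,
                          status = dist$status)
}

#' Covariate-adjusted log expression values
#'
#' The non-parametric path: regresses `log1p(count)` on the cell-level
#' covariates by ordinary least squares and returns, per cell, the fitted
#' value at the reference covariates plus that cell's residual — expression
#' values standardised to a common (median) read depth.
#'
#' @inheritParams fit_nb_individual
#' @return An [individual_distribution()] of kind `"empirical_sample"`.
#' @export
adjust_log_counts <- function(counts, covars = NULL, ref_covars = NULL) {
  counts <- as.numeric(counts)
  n <- length(counts)
  covars <- as_covar_matrix(covars, n)
  if (n < ncol(covars) + 2L) return(failed_distribution("empirical_sample"))
  if (is.null(ref_covars)) ref_covars <- default_ref_covars(covars)
  y <- log1p(counts)
  if (ncol(covars) == 0L)
    return(individual_distribution("empirical_sample", values = y))
  fit <- stats::lm.fit(cbind(1, covars), y)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  at_ref <- sum(c(1, ref_covars) * beta)
  individual_distribution("empirical_sample",
                          values = at_ref + unname(fit$residuals))
}

#' Gaussian kernel density estimate of an adjusted-expression sample
#'
#' Silverman's rule-of-thumb bandwidth on the sample values; evaluated on
#' `grid` and renormalised to integrate to 1 by the trapezoid rule.
#'
#' @param sample an `empirical_sample` [individual_distribution()].
#' @param grid numeric vector of evaluation points (sorted).
#' @return An [individual_distribution()] of kind `"continuous_density"`,
#'   or status `"failed"` when all values coincide (zero bandwidth).
#' @export
kde_density <- function(sample, grid) {
  stopifnot(inherits(sample, "individual_distribution"),
            sample$kind == "empirical_sample")
  if (sample$status == "failed") return(failed_distribution("continuous_density"))
  x <- sample$values
  if (length(unique(x)) < 2L) return(failed_distribution("continuous_density"))
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(failed_distribution("continuous_density"))
  d <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)),
              numeric(1))
  area <- trapezoid(grid, d)
  if (area <= 0) return(failed_distribution("continuous_density"))
  individual_distribution("continuous_density", density = d / area,
                          grid = grid)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Read a per-cell distribution-parameter table
#'
#' Schema: TSV/CSV with header, one row per (gene, cell); either ZINB
#' columns `gene, cell, mu, theta, pi` or Poisson columns `gene, cell,
#' lambda` (as produced by external denoisers).
#'
#' @param path file path.
#' @return Data frame with a `dialect` attribute, `"zinb"` or `"poisson"`.
#' @export
read_cell_distribution_table <- function(path) {
  tab <- read_table_auto(path)
  if (all(c("gene", "cell", "mu", "theta", "pi") %in% names(tab))) {
    stopifnot(all(tab$mu > 0), all(tab$theta > 0),
              all(tab$pi >= 0 & tab$pi < 1))
    attr(tab, "dialect") <- "zinb"
  } else if (all(c("gene", "cell", "lambda") %in% names(tab))) {
    stopifnot(all(tab$lambda >= 0))
    attr(tab, "dialect") <- "poisson"
  } else stop("unrecognised cell-distribution table schema")
  tab
}

table_params <- function(table, cells, gene = NULL) {
  if (!is.null(gene)) table <- table[table$gene == gene, , drop = FALSE]
  idx <- match(cells, table$cell)
  if (anyNA(idx))
    stop("cells missing from the distribution table: ",
         paste(utils::head(cells[is.na(idx)], 5L), collapse = ", "))
  tab <- table[idx, , drop = FALSE]
  if ("lambda" %in% names(tab))
    data.frame(pi = 0, mu = tab$lambda, theta = Inf)
  else data.frame(pi = tab$pi, mu = tab$mu, theta = tab$theta)
}

#' Aggregate cell-level distributions into an individual-level density
#'
#' The individual's density is the equal-weight mixture of its cells'
#' ZINB (or Poisson) pmfs, evaluated on 0..K with per-cell tail mass folded
#' into the top bin — the direct-computation route for denoiser output.
#'
#' @param table a [read_cell_distribution_table()] data frame (or any data
#'   frame with columns `cell` and either `mu`,`theta`,`pi` or `lambda`).
#' @param cells character vector: one individual's cell ids.
#' @param K top bin of the common support 0..K.
#' @param gene optional gene id to filter `table` by its `gene` column.
#' @return An [individual_distribution()] of kind `"discrete"`.
#' @export
aggregate_cell_distributions <- function(table, cells, K, gene = NULL) {
  par <- table_params(table, cells, gene)
  K <- as.integer(K)
  acc <- numeric(K + 1L)
  for (i in seq_len(nrow(par))) {
    p <- dzinb(0:(K - 1L), par$pi[i], par$mu[i], par$theta[i])
    acc <- acc + c(p, max(0, 1 - sum(p)))
  }
  individual_distribution("discrete", density = acc / nrow(par),
                          support = 0:K)
}

#' Sample counts from cell-level distributions
#'
#' Draws `m` counts from each cell's ZINB/Poisson distribution (the
#' sampling route for denoiser output, which keeps covariate adjustment
#' available downstream via [fit_nb_individual()]).
#'
#' @inheritParams aggregate_cell_distributions
#' @param m draws per cell.
#' @param seed optional integer seed.
#' @return Integer vector of length `m * length(cells)`, ordered cell by
#'   cell.
#' @export
sample_from_cell_distributions <- function(table, cells, m, gene = NULL,
                                           seed = NULL) {
  stopifnot(m >= 1)
  par <- table_params(table, cells, gene)
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(seq_len(nrow(par)), function(i)
    rzinb(m, par$pi[i], par$mu[i], par$theta[i])))
}
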