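#' Per-gene individual-parameter model
#'
#' A multivariate normal law for one gene's individual-level parameters on
#' latent scales: `mu` = log NB mean, `phi` = log overdispersion, `pi` =
#' logit zero-inflation proportion, `sig` = log of the standard deviation
#' of the cell-level log mean. Individuals are draws from this law.
#'
#' @param m length-4 latent mean vector `(mu, phi, pi, sig)`.
#' @param Sigma 4x4 symmetric positive semidefinite latent covariance.
#' @param nb_only if `TRUE`, the zero-inflation channel is collapsed
#'   (`pi = 0` for every individual).
#' @return A `gene_param_model` object.
#' @export
gene_param_model <- function(m, Sigma, nb_only = FALSE) {
  stopifnot(length(m) == 4L, all(dim(Sigma) == c(4L, 4L)),
            max(abs(Sigma - t(Sigma))) < 1e-10)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("Sigma is not positive semidefinite")
  structure(list(m = as.numeric(m), Sigma = unname(Sigma),
                 nb_only = isTRUE(nb_only)),
            class = "gene_param_model")
}

#' Generate a bank of plausible gene-parameter models
#'
#' A self-contained stand-in for models estimated from a reference
#' single-cell dataset: synthetic latent means spanning low to moderately
#' expressed genes (log mean in \[-2, 2\], log overdispersion in \[-1, 2\],
#' zero-inflation logit in \[-3, 0\] minus the log mean — dropout
#' anticorrelates with abundance — and cell-level log-mean sd in
#' \[0.1, 0.6\]) with modest between-individual spread and weak random
#' cross-correlations. Covariances are built as `diag(s) R diag(s)` with a
#' random correlation matrix `R`, so positive semidefiniteness is
#' guaranteed by construction.
#'
#' @param n_genes number of models in the bank.
#' @param seed integer seed.
#' @param nb_only collapse the zero-inflation channel in every model.
#' @return List of [gene_param_model()] objects.
#' @export
default_param_model <- function(n_genes = 100, seed = 1, nb_only = FALSE) {
  set.seed(seed)
  lapply(seq_len(n_genes), function(g) {
    lmu <- stats::runif(1, -2, 2)
    # dropout anticorrelates with abundance: highly expressed genes get a
    # more negative zero-inflation logit
    m <- c(lmu, stats::runif(1, -1, 2),
           stats::runif(1, -3, 0) - lmu, log(stats::runif(1, 0.1, 0.6)))
    s <- c(stats::runif(1, 0.05, 0.20), stats::runif(1, 0.10, 0.30),
           stats::runif(1, 0.20, 0.50), stats::runif(1, 0.05, 0.15))
    A <- matrix(stats::rnorm(16, sd = 0.4), 4L)
    R <- stats::cov2cor(A %*% t(A) + diag(4L) * 3)
    gene_param_model(m, diag(s) %*% R %*% diag(s), nb_only = nb_only)
  })
}

#' Draw individual-level parameters from a gene model
#'
#' Draws `n` latent 4-vectors from `N(m, Sigma)` and back-transforms to the
#' natural scales: NB mean `mu = exp`, overdispersion `theta = exp`,
#' zero proportion `pi = plogis`, cell-level log-mean sd `sigma = exp`.
#'
#' @param model a [gene_param_model()].
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return Data frame with columns `mu`, `theta`, `pi`, `sigma`.
#' @export
draw_individual_params <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "gene_param_model"))
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(model$Sigma, symmetric = TRUE)
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(stats::rnorm(4L * n), 4L, n)
  lat <- model$m + S %*% z
  pi <- if (model$nb_only) rep(0, n) else stats::plogis(lat[3L, ])
  data.frame(mu = exp(lat[1L, ]), theta = exp(lat[2L, ]), pi = pi,
             sigma = exp(lat[4L, ]))
}

#' Simulate one gene's cell-level counts
#'
#' For individual `i`, cell log-means are drawn from
#' `Normal(log(mu_i) - sigma_i^2/2, sigma_i)` (the lognormal mean
#' correction keeps the average cell mean equal to `mu_i`), and each cell's
#' count from `ZINB(pi_i, cell mean, theta_i)`.
#'
#' @param params data frame from [draw_individual_params()], one row per
#'   individual.
#' @param k cells per individual.
#' @param seed optional integer seed.
#' @return List with `counts` (integer vector of length `nrow(params) * k`)
#'   and `individual` (parallel index vector).
#' @export
simulate_gene <- function(params, k, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(params)
  counts <- integer(0)
  for (i in seq_len(n)) {
    s <- params$sigma[i]
    cell_mu <- exp(stats::rnorm(k, log(params$mu[i]) - s^2 / 2, s))
    y <- if (is.finite(params$theta[i]))
      stats::rnbinom(k, size = params$theta[i], mu = cell_mu)
    else stats::rpois(k, cell_mu)
    if (params$pi[i] > 0) y <- y * (stats::runif(k) >= params$pi[i])
    counts <- c(counts, y)
  }
  list(counts = counts, individual = rep(seq_len(n), each = k))
}

# cell-level count variance implied by (mu, theta, pi, sigma):
# W | L ~ NB(L, theta), L lognormal with mean mu and log-sd sigma,
# Y = Bern(1 - pi) * W
implied_variance <- function(mu, theta, pi, sigma) {
  a <- 1 + 1 / theta                       # theta = Inf gives the Poisson a = 1
  varW <- mu - mu^2 + a * mu^2 * exp(sigma^2)
  (1 - pi) * varW + pi * (1 - pi) * mu^2
}

#' Inject a mean or variance differential-expression signal
#'
#' `meanDE`: multiplies the case-group NB means by `r_m` (or `1/r_m` for
#' `direction = -1`), leaving all variance channels untouched. `varDE`:
#' rescales the cell-level log-mean spread (`sigma`) of each case
#' individual so that the implied cell-level count variance is multiplied
#' by `r_v` while the mean is held exactly fixed — a dispersion-only signal
#' that a pseudo-bulk mean comparison cannot see. The required `sigma'`
#' solves `VarW' = r_v VarW + (r_v - 1) pi mu^2` for the NB component,
#' which always has a real solution for `r_v >= 1`.
#'
#' @param case_params data frame from [draw_individual_params()] (the case
#'   group).
#' @param label `"meanDE"` or `"varDE"`.
#' @param r_m,r_v fold changes (>= 1); defaults 1.2 and 1.5.
#' @param direction +1 (up in cases) or -1 (down); applies to `meanDE`.
#' @return The modified parameter data frame.
#' @export
inject_signal <- function(case_params, label = c("meanDE", "varDE"),
                          r_m = 1.2, r_v = 1.5, direction = 1) {
  label <- match.arg(label)
  stopifnot(r_m >= 1, r_v >= 1, direction %in% c(-1, 1))
  p <- case_params
  if (label == "meanDE") {
    p$mu <- p$mu * r_m^direction
  } else {
    a <- 1 + 1 / p$theta
    varW <- p$mu - p$mu^2 + a * p$mu^2 * exp(p$sigma^2)
    varW2 <- r_v * varW + (r_v - 1) * p$pi * p$mu^2
    p$sigma <- sqrt(log((varW2 - p$mu + p$mu^2) / (a * p$mu^2)))
  }
  p
}

#' Simulation configuration
#'
#' Defaults follow the two-group design: equal case/control groups, 360
#' cells per individual, 1.2-fold mean and 1.5-fold variance signals, and
#' a meanDE/varDE/EE gene layout.
#'
#' @param n_cases,n_controls group sizes.
#' @param cells_per_individual cells simulated per individual.
#' @param n_meanDE,n_varDE,n_EE gene layout.
#' @param fold_mean,fold_var effect sizes (>= 1).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 10, n_controls = 10,
                       cells_per_individual = 360, n_meanDE = 1000,
                       n_varDE = 1000, n_EE = 6000, fold_mean = 1.2,
                       fold_var = 1.5, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, cells_per_individual >= 1,
            fold_mean >= 1, fold_var >= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 cells_per_individual = cells_per_individual,
                 n_meanDE = n_meanDE, n_varDE = n_varDE, n_EE = n_EE,
                 n_genes = n_meanDE + n_varDE + n_EE,
                 fold_mean = fold_mean, fold_var = fold_var, seed = seed),
            class = "sim_config")
}

#' Simulate a full multi-subject single-cell dataset with ground truth
#'
#' For each gene: draws individual-level (mu, theta, pi, sigma) from its
#' parameter model, injects the configured mean or variance signal into the
#' case group (meanDE genes first, then varDE, then EE), simulates
#' cell-level ZINB counts, and records the truth label. Signal direction is
#' a per-gene fair coin. Read depth is the realized per-cell column sum of
#' the simulated matrix.
#'
#' @param model_bank list of [gene_param_model()] (recycled with a warning
#'   and small latent-mean jitter if shorter than the gene layout).
#' @param config a [sim_config()].
#' @return List with `data` (a [cell_data()] object; `indiv_meta$status`
#'   is 1 for cases, 0 for controls) and `truth` (data frame `gene_id`,
#'   `label`, `fold`, `direction`).
#' @export
simulate_dataset <- function(model_bank, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nb <- length(model_bank)
  recycle <- ng > nb
  if (recycle)
    warning("model bank (", nb, ") shorter than gene layout (", ng,
            "); models recycled with latent-mean jitter")
  n1 <- config$n_cases; n2 <- config$n_controls
  n <- n1 + n2; k <- config$cells_per_individual
  labels <- c(rep("meanDE", config$n_meanDE), rep("varDE", config$n_varDE),
              rep("EE", config$n_EE))
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  ind_ids <- c(sprintf("case%02d", seq_len(n1)),
               sprintf("ctrl%02d", seq_len(n2)))
  counts <- matrix(0L, ng, n * k)
  direction <- integer(ng); fold <- numeric(ng)
  for (g in seq_len(ng)) {
    model <- model_bank[[(g - 1L) %% nb + 1L]]
    if (recycle && g > nb)
      model$m <- model$m + stats::rnorm(4L, sd = 0.05)
    par <- draw_individual_params(model, n)
    direction[g] <- sample(c(-1L, 1L), 1L)
    fold[g] <- switch(labels[g], meanDE = config$fold_mean,
                      varDE = config$fold_var, EE = 1)
    if (labels[g] != "EE") {
      case <- inject_signal(par[seq_len(n1), , drop = FALSE], labels[g],
                            r_m = config$fold_mean, r_v = config$fold_var,
                            direction = direction[g])
      par[seq_len(n1), ] <- case
    }
    counts[g, ] <- simulate_gene(par, k)$counts
  }
  cell_ids <- paste0(rep(ind_ids, each = k), "_c", rep(seq_len(k), n))
  dimnames(counts) <- list(gene_ids, cell_ids)
  cm <- data.frame(cell = cell_ids, individual = rep(ind_ids, each = k),
                   stringsAsFactors = FALSE)
  im <- data.frame(individual = ind_ids,
                   status = c(rep(1L, n1), rep(0L, n2)),
                   stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids, label = labels, fold = fold,
                      direction = direction, stringsAsFactors = FALSE)
  list(data = cell_data(counts, cm, im), truth = truth)
}
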