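test_that("NB fit recovers conditional mean and dispersion from simulation", {
  set.seed(41)
  n <- 2000
  log_rd <- rnorm(n, log(1e4), 0.4)
  # mean proportional to read depth: log mu = log(5) + (log_rd - median)
  mu_cell <- 5 * exp(log_rd - median(log_rd))
  y <- rnbinom(n, size = 2, mu = mu_cell)
  fit <- fit_nb_individual(y, cbind(log_rd = log_rd),
                           ref_covars = median(log_rd))
  expect_equal(fit$status, "ok")
  expect_equal(fit$pi, 0)
  expect_lt(abs(fit$mu - 5) / 5, 0.05)
  expect_lt(abs(fit$theta - 2) / 2, 0.20)
})

test_that("NB fit degenerates gracefully", {
  expect_equal(fit_nb_individual(rep(0, 50))$status, "failed")
  expect_equal(fit_nb_individual(rep(3, 50))$status, "failed")
  expect_equal(fit_nb_individual(c(1, 2, 3))$status, "failed")  # < min_cells
})

test_that("Poisson data collapses to the Poisson fallback or large theta", {
  set.seed(42)
  y <- rpois(2000, 3)
  fit <- fit_nb_individual(y)
  expect_true(fit$status %in% c("ok", "fallback_poisson"))
  expect_lt(abs(fit$mu - 3) / 3, 0.05)
  vr <- fit$mu + fit$mu^2 / fit$theta  # fitted variance/mean ratio near 1
  expect_lte(vr / fit$mu, 1.1)
})

test_that("ZINB fit recovers the zero-inflation proportion", {
  set.seed(43)
  n <- 5000
  y <- rnbinom(n, size = 2, mu = 5) * (runif(n) >= 0.3)
  fit <- fit_zinb_individual(y, min_cells = 10)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$pi - 0.3), 0.05)
  expect_lt(abs(fit$mu - 5) / 5, 0.10)
})

test_that("ZINB agrees with glmmTMB on an intercept-only fit", {
  set.seed(44)
  n <- 3000
  y <- rnbinom(n, size = 1.5, mu = 4) * (runif(n) >= 0.25)
  fit <- fit_zinb_individual(y)
  tmb <- glmmTMB::glmmTMB(y ~ 1, ziformula = ~1, data = data.frame(y = y),
                          family = glmmTMB::nbinom2)
  mu_tmb <- exp(unname(glmmTMB::fixef(tmb)$cond))
  pi_tmb <- plogis(unname(glmmTMB::fixef(tmb)$zi))
  theta_tmb <- glmmTMB::sigma(tmb)
  expect_lt(abs(fit$mu - mu_tmb) / mu_tmb, 0.02)
  expect_lt(abs(fit$pi - pi_tmb), 0.02)
  expect_lt(abs(fit$theta - theta_tmb) / theta_tmb, 0.05)
})

test_that("pure NB data triggers the NB fallback of the ZINB fit", {
  set.seed(45)
  y <- rnbinom(5000, size = 2, mu = 5)
  fit <- fit_zinb_individual(y)
  expect_true(fit$status == "fallback_nb" || fit$pi < 0.02)
})

test_that("zero-variance input fails the ZINB fit", {
  expect_equal(fit_zinb_individual(rep(4, 100))$status, "failed")
})

test_that("discretize matches analytic pmfs and conserves mass and mean", {
  pois1 <- individual_distribution("parametric", pi = 0, mu = 1, theta = Inf)
  d <- discretize(pois1, K = 50)
  expect_equal(d$density[1], exp(-1), tolerance = 1e-12)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  nb <- individual_distribution("parametric", pi = 0, mu = 2, theta = 1)
  d2 <- discretize(nb, K = 200)
  expect_equal(sum(d2$density), 1, tolerance = 1e-12)
  expect_equal(sum(d2$density * 0:200), 2, tolerance = 1e-6)
  # degenerate pi = 1 is rejected by the container invariant
  expect_error(individual_distribution("parametric", pi = 1, mu = 1,
                                       theta = 1))
  # too-small support warns about the heavy top bin
  big <- individual_distribution("parametric", pi = 0, mu = 50, theta = 2)
  expect_warning(discretize(big, K = 3), "top bin")
})

test_that("adjust_log_counts removes exactly the covariate effect", {
  # constant covariates: adjusted values are the raw log1p counts
  y <- c(0, 1, 4, 2, 7, 0, 3, 1, 5, 2)
  adj <- adjust_log_counts(y, cbind(z = rep(2, 10)), ref_covars = 2)
  expect_equal(adj$values, log1p(y), tolerance = 1e-12)
  # exactly linear response: residuals vanish, all values hit the reference
  ld <- seq(1, 2, length.out = 20)
  y2 <- expm1(2 + 1 * ld)  # log1p(y2) = 2 + ld exactly
  adj2 <- adjust_log_counts(y2, cbind(log_rd = ld),
                            ref_covars = median(ld))
  expect_equal(adj2$values, rep(2 + median(ld), 20), tolerance = 1e-8)
  # simulated y = 2*logdepth + noise: adjusted variance ~= noise variance
  set.seed(46)
  ld3 <- rnorm(4000, 9, 0.5)
  noise <- rnorm(4000, 0, 0.3)
  yl <- 2 * ld3 + noise
  adj3 <- adjust_log_counts(expm1(yl), cbind(log_rd = ld3),
                            ref_covars = median(ld3))
  expect_lt(abs(var(adj3$values) - 0.09) / 0.09, 0.10)
  # too few cells for the design
  expect_equal(adjust_log_counts(c(1, 2), cbind(a = 1:2))$status, "failed")
})

test_that("KDE integrates to 1 and matches the normal density", {
  set.seed(47)
  x <- rnorm(20000)
  s <- individual_distribution("empirical_sample", values = x)
  grid <- seq(-5, 5, length.out = 512)
  k <- kde_density(s, grid)
  expect_equal(trapz_test(grid, k$density), 1, tolerance = 1e-6)
  at0 <- k$density[which.min(abs(grid))]
  expect_lt(abs(at0 - dnorm(0)) / dnorm(0), 0.10)
  # degenerate: identical values have zero bandwidth
  s0 <- individual_distribution("empirical_sample", values = rep(1, 50))
  expect_equal(kde_density(s0, grid)$status, "failed")
})

test_that("cell-distribution aggregation equals the hand-computed mixture", {
  tab <- data.frame(gene = "g", cell = paste0("c", 1:5),
                    lambda = 1:5)
  agg <- aggregate_cell_distributions(tab, paste0("c", 1:5), K = 100,
                                      gene = "g")
  oracle <- rowMeans(sapply(1:5, function(l) {
    p <- dpois(0:99, l); c(p, 1 - sum(p))
  }))
  expect_equal(agg$density, oracle, tolerance = 1e-12)
  expect_equal(sum(agg$density), 1, tolerance = 1e-12)
  # mixture mean of Poisson(1) and Poisson(3) is 2
  tab2 <- data.frame(gene = "g", cell = c("a", "b"), lambda = c(1, 3))
  agg2 <- aggregate_cell_distributions(tab2, c("a", "b"), K = 60)
  expect_equal(sum(agg2$density * 0:60), 2, tolerance = 1e-9)
  # order invariance
  agg3 <- aggregate_cell_distributions(tab, paste0("c", 5:1), K = 100,
                                       gene = "g")
  expect_equal(agg3$density, agg$density)
  # identical ZINB cells aggregate to the discretized ZINB
  tabz <- data.frame(gene = "g", cell = c("a", "b"), mu = 4, theta = 2,
                     pi = 0.2)
  aggz <- aggregate_cell_distributions(tabz, c("a", "b"), K = 80)
  one <- discretize(individual_distribution("parametric", pi = 0.2, mu = 4,
                                            theta = 2), K = 80)
  expect_equal(aggz$density, one$density, tolerance = 1e-12)
  # missing cells are reported
  expect_error(aggregate_cell_distributions(tab, c("c1", "nope"), K = 10),
               "nope")
})

test_that("sampling from cell distributions has the right size and mean", {
  tab <- data.frame(gene = "g", cell = paste0("c", 1:10),
                    mu = 5, theta = 2, pi = 0.3)
  s <- sample_from_cell_distributions(tab, paste0("c", 1:10), m = 5,
                                      seed = 48)
  expect_length(s, 50L)
  big <- sample_from_cell_distributions(tab, "c1", m = 1e5, seed = 49)
  expect_lt(abs(mean(big) - 0.7 * 5) / (0.7 * 5), 0.01)
})

test_that("conditional fits are read-depth consistent", {
  # doubling every cell's depth while keeping the per-depth law fixed
  # leaves the conditional distribution at the new median unchanged
  set.seed(50)
  n <- 4000
  ld <- rnorm(n, 8, 0.4)
  mu1 <- 3 * exp(ld - median(ld))
  y1 <- rnbinom(n, size = 2, mu = mu1)
  f1 <- fit_nb_individual(y1, cbind(log_rd = ld), ref_covars = median(ld))
  ld2 <- ld + log(2)
  mu2 <- 3 * exp(ld2 - median(ld2))
  y2 <- rnbinom(n, size = 2, mu = mu2)
  f2 <- fit_nb_individual(y2, cbind(log_rd = ld2), ref_covars = median(ld2))
  expect_lt(abs(f1$mu - f2$mu) / f1$mu, 0.10)
})

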