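test_that("Gower centering matches the 2x2 closed form", {
  d <- 3.7
  D <- matrix(c(0, d, d, 0), 2)
  G <- gower_center(D)
  expect_equal(unclass(G), (d^2 / 4) * matrix(c(1, -1, -1, 1), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(gower_center(matrix(0, 3, 3))), matrix(0, 3, 3),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("Gower kernel of points on a line is PSD with rank <= 1", {
  set.seed(61)
  x <- rnorm(8)
  D <- abs(outer(x, x, "-"))
  A <- -0.5 * D^2
  C <- diag(8) - 1 / 8
  ev <- eigen(C %*% A %*% C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)          # classical MDS: no negative eigenvalues
  expect_lte(sum(ev > 1e-10), 1L)      # rank 1
  G <- gower_center(D)
  expect_lt(max(abs(rowSums(G))), 1e-10 * nrow(G) * max(abs(G)) + 1e-12)
  expect_gte(min(eigen(unclass(G), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("negative eigenvalues are truncated, zero row sums preserved", {
  set.seed(62)
  # a non-Euclidean distance matrix (random, symmetrized) has negative
  # Gower eigenvalues; the kernel must come back PSD with centered rows
  M <- matrix(runif(49, 0.5, 2), 7); M <- (M + t(M)) / 2; diag(M) <- 0
  G <- gower_center(M)
  expect_gt(attr(G, "n_negative_eigen"), 0L)
  ev <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("pseudo-F matches the dense-matrix formula and is reorder-invariant", {
  set.seed(63)
  # two well-separated pairs on a line
  x <- c(0, 0.5, 4, 4.5)
  D <- abs(outer(x, x, "-"))
  G <- gower_center(D)
  Z <- cbind(1, c(0, 0, 1, 1))
  colnames(Z) <- c("(Intercept)", "grp")
  F1 <- pseudo_F(G, Z)
  expect_gt(F1, 10)
  expect_equal(F1, pseudo_F_oracle(unclass(G), Z), tolerance = 1e-12)
  # simultaneous reordering leaves F unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(pseudo_F(unclass(G)[perm, perm], Z[perm, , drop = FALSE]),
               F1, tolerance = 1e-12)
  # intercept-only design: double centering kills the numerator
  Z0 <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  expect_equal(pseudo_F(G, Z0), 0, tolerance = 1e-12)
})

test_that("pseudo-F agrees with vegan's adonis2 after df rescaling", {
  set.seed(64)
  pts <- matrix(rnorm(12 * 3), 12)
  grp <- rep(c(0, 1), each = 6)
  D <- as.matrix(dist(pts))
  G <- gower_center(D)
  Z <- cbind(`(Intercept)` = 1, grp = grp)
  F_ours <- pseudo_F(G, Z)
  ad <- vegan::adonis2(as.dist(D) ~ grp, data = data.frame(grp = grp),
                       permutations = 2)
  # adonis2 F = (SSB/dfB)/(SSW/dfW); ours is SSB/SSW
  F_adonis <- ad$F[1]
  dfB <- ad$Df[1]; dfW <- ad$Df[2]
  expect_equal(F_ours, F_adonis * dfB / dfW, tolerance = 1e-8)
})

test_that("permuting X is equivalent to permuting the kernel", {
  set.seed(65)
  for (r in 1:50) {
    n <- sample(6:12, 1)
    pts <- matrix(rnorm(n * 2), n)
    G <- gower_center(as.matrix(dist(pts)))
    x <- rbinom(n, 1, 0.5)
    if (var(x) == 0) x[1] <- 1 - x[1]
    Z <- cbind(`(Intercept)` = 1, x = x)
    perm <- sample(n)
    Zp <- Z; Zp[, "x"] <- x[perm]
    # F with x permuted and G fixed equals F with G's rows/columns
    # permuted (by the inverse) and x fixed
    F1 <- pseudo_F(G, Zp)
    F2 <- pseudo_F(unclass(G)[order(perm), order(perm)], Z)
    expect_equal(F1, F2, tolerance = 1e-12)
  }
})

test_that("exhaustive enumeration matches brute force at n = 4", {
  set.seed(66)
  x <- c(0, 0.3, 4, 5)
  D <- abs(outer(x, x, "-"))
  G <- gower_center(D)
  Z <- cbind(`(Intercept)` = 1, grp = c(1, 1, 0, 0))
  res <- suppressWarnings(
    permutation_test(G, Z, "grp", n_perm = 999, seed = 1))
  expect_equal(res$n_perm_used, 6L)  # choose(4, 2) assignments
  # brute force over all 6 assignments with the dense oracle
  Fs <- apply(combn(4, 2), 2, function(ii) {
    z <- cbind(1, as.numeric(seq_len(4) %in% ii))
    pseudo_F_oracle(unclass(G), z)
  })
  F_obs <- pseudo_F_oracle(unclass(G), Z)
  expect_equal(res$pvalue, mean(Fs >= F_obs - 1e-12))
  expect_equal(res$pvalue, 2 / 6)  # the complementary assignment ties F
})

test_that("p-value floor and add-one formula", {
  set.seed(67)
  # large n so sampling (not enumeration) is used
  pts <- c(rnorm(10, 0), rnorm(10, 8))
  G <- gower_center(abs(outer(pts, pts, "-")))
  Z <- cbind(`(Intercept)` = 1, grp = rep(c(1, 0), each = 10))
  res <- permutation_test(G, Z, "grp", n_perm = 199, seed = 2,
                          early_stop = FALSE)
  expect_equal(res$n_perm_used, 199L)
  expect_gte(res$pvalue, 1 / (res$n_perm_used + 1))
  # perfectly separated groups: observed F should rarely be beaten
  expect_lt(res$pvalue, 0.05)
})

test_that("warnings for imbalance and degenerate designs", {
  set.seed(68)
  pts <- rnorm(6)
  G <- gower_center(abs(outer(pts, pts, "-")))
  Z <- cbind(`(Intercept)` = 1, grp = c(1, 0, 0, 0, 0, 0))
  expect_warning(permutation_test(G, Z, "grp", n_perm = 99, seed = 1),
                 "imbalance")
})

test_that("design_matrix validates and encodes two-level factors", {
  im <- data.frame(individual = c("a", "b", "c", "d"),
                   status = c("case", "ctrl", "case", "ctrl"),
                   age = c(40, 50, 60, 70))
  Z <- design_matrix(im, "status", "age")
  expect_equal(colnames(Z), c("(Intercept)", "status", "age"))
  expect_equal(unname(Z[, "status"]), c(0, 1, 0, 1))  # 'ctrl' is level 2
  expect_error(design_matrix(im, "nope"), "not found")
  im$const <- 1
  expect_error(design_matrix(im, "const"), "2 levels|rank deficient")
})
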