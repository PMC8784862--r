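# tiny deterministic cell_data fixture: 3 genes x 4 cells, 2 individuals
toy_cell_data <- function() {
  counts <- matrix(c(1L, 0L, 2L, 3L,
                     0L, 4L, 0L, 1L,
                     2L, 1L, 1L, 0L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  cm <- data.frame(cell = paste0("c", 1:4),
                   individual = c("A", "A", "B", "B"))
  im <- data.frame(individual = c("A", "B"), status = c(1, 0))
  cell_data(counts, cm, im)
}

# simulated cell_data with a given layout at desk scale
small_sim <- function(n_meanDE = 0, n_varDE = 0, n_EE = 10, k = 50,
                      n_cases = 5, n_controls = 5, seed = 1,
                      fold_mean = 1.2, fold_var = 1.5, bank_seed = 99) {
  bank <- default_param_model(n_meanDE + n_varDE + n_EE, seed = bank_seed)
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    cells_per_individual = k, n_meanDE = n_meanDE,
                    n_varDE = n_varDE, n_EE = n_EE, fold_mean = fold_mean,
                    fold_var = fold_var, seed = seed)
  simulate_dataset(bank, cfg)
}

# random discrete density on 0..K
random_density <- function(K, concentration = 1) {
  w <- stats::rgamma(K + 1L, shape = concentration)
  w / sum(w)
}

# independent Riemann-sum oracle for the W1 CDF integral on {0..K}
was_oracle <- function(p, q) {
  Fp <- cumsum(p); Fq <- cumsum(q)
  sum(abs(Fp - Fq) * 1)  # unit bins; top-bin CDFs are both 1
}

# brute-force JSD by direct summation of the KL terms
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (term(p) + term(q)) / 2
}

trapz_test <- function(x, y)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

wasserstein1_shifted <- function(c) {
  P <- individual_distribution("empirical_sample", values = rep(0 + c, 5))
  Q <- individual_distribution("empirical_sample", values = rep(2 + c, 5))
  wasserstein1(P, Q)
}

failed_dist_helper <- function()
  individual_distribution("parametric", status = "failed")

# dense-matrix evaluation of the trace-ratio pseudo-F
pseudo_F_oracle <- function(G, Z) {
  H <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  I_H <- diag(nrow(Z)) - H
  sum(diag(H %*% G %*% H)) / sum(diag(I_H %*% G %*% I_H))
}
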