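gene_seed <- function(seed, i)
  as.integer((as.numeric(seed) %% 65536 * 32749 + i * 9973 + 1) %% 2147483629)

# fit one gene's per-individual distributions; returns a named list of
# individual_distribution or NULL when any individual fails
fit_gene_distributions <- function(y, cells_by_ind, covars, ref_covars,
                                   fit, metric, min_cells, zero_covars,
                                   denoised = NULL, gene = NULL,
                                   m_sample = 5, seed = NULL) {
  inds <- names(cells_by_ind)
  if (fit %in% c("nb", "zinb")) {
    fitter <- if (fit == "nb") fit_nb_individual else
      function(cc, cv, rv, mc) fit_zinb_individual(cc, cv, rv, mc,
                                                   zero_covars = zero_covars)
    dists <- lapply(cells_by_ind, function(ii)
      fitter(y[ii], covars[ii, , drop = FALSE], ref_covars, min_cells))
  } else if (fit %in% c("kde", "empirical")) {
    dists <- lapply(cells_by_ind, function(ii) {
      if (length(ii) < min_cells) return(failed_distribution("empirical_sample"))
      adjust_log_counts(y[ii], covars[ii, , drop = FALSE], ref_covars)
    })
    if (fit == "kde" || metric == "jsd") {
      if (any(vapply(dists, function(d) d$status == "failed", logical(1))))
        return(NULL)
      vals <- unlist(lapply(dists, `[[`, "values"))
      bws <- vapply(dists, function(d) {
        if (length(unique(d$values)) < 2L) return(NA_real_)
        stats::bw.nrd0(d$values)
      }, numeric(1))
      if (anyNA(bws)) return(NULL)
      pad <- 3 * max(bws)
      grid <- seq(min(vals) - pad, max(vals) + pad, length.out = 512L)
      dists <- lapply(dists, kde_density, grid = grid)
    }
  } else if (fit == "denoised") {
    if (is.null(denoised)) stop("fit='denoised' needs a cell-distribution table")
    tab <- denoised[denoised$gene == gene, , drop = FALSE]
    if (nrow(tab) == 0L) return(NULL)
    route <- attr(denoised, "route")
    if (identical(route, "sample")) {
      if (!is.null(seed)) set.seed(seed)
      dists <- lapply(cells_by_ind, function(ii) {
        cells <- rownames(covars)[ii]
        cnt <- sample_from_cell_distributions(tab, cells, m_sample)
        cv <- covars[rep(ii, each = m_sample), , drop = FALSE]
        fit_nb_individual(cnt, cv, ref_covars, min_cells)
      })
    } else {
      par <- table_params(tab, tab$cell)
      Kd <- max(vapply(seq_len(nrow(par)), function(i)
        support_bound(list(pi = par$pi[i], mu = par$mu[i],
                           theta = par$theta[i])), integer(1)))
      dists <- lapply(cells_by_ind, function(ii)
        aggregate_cell_distributions(tab, rownames(covars)[ii], K = Kd))
    }
  } else stop("unknown fit method: ", fit)
  names(dists) <- inds
  if (any(vapply(dists, function(d) d$status == "failed", logical(1))))
    return(NULL)
  dists
}

one_gene_test <- function(y, gene, gene_index, cells_by_ind, covars,
                          ref_covars, Z, x_column, config, denoised = NULL) {
  sd_g <- gene_seed(config$seed, gene_index)
  dists <- fit_gene_distributions(y, cells_by_ind, covars, ref_covars,
                                  config$fit, config$metric,
                                  config$min_cells, config$zero_covars,
                                  denoised = denoised, gene = gene,
                                  m_sample = config$m_sample, seed = sd_g)
  if (is.null(dists))
    return(test_result(gene, status = "fit_failed", seed = sd_g))
  if (config$fit == "empirical" && config$metric == "was") {
    n <- length(dists)
    D <- matrix(0, n, n, dimnames = list(names(dists), names(dists)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- wasserstein1(dists[[i]], dists[[j]])
  } else {
    D <- build_distance_matrix(dists, metric = config$metric, gene_id = gene)
    if (is.null(D))
      return(test_result(gene, status = "fit_failed", seed = sd_g))
  }
  G <- gower_center(D)
  permutation_test(G, Z, x_column, n_perm = config$n_perm, seed = sd_g,
                   mode = config$mode, early_stop = config$early_stop,
                   gene_id = gene)
}

#' Individual-level differential expression by distribution distances
#'
#' The main fitting function. For every gene it (1) estimates each
#' individual's expression distribution across that individual's cells,
#' conditioning on cell-level covariates (negative binomial regression by
#' default), (2) computes the pairwise distance matrix between individuals
#' (Wasserstein-1 by default), and (3) tests association between the
#' distance structure and the variable of interest, adjusting for
#' individual-level covariates, with a Gower-centered pseudo-F statistic
#' and a permutation p-value. Distances are computed once per gene; only
#' the design is permuted.
#'
#' @param data a [cell_data()] object (already gene-filtered, see
#'   [filter_genes()]).
#' @param x_column name of the variable of interest in `data$indiv_meta`
#'   (binary 0/1, two-level factor, or continuous).
#' @param fit distribution estimator: `"nb"` (default), `"zinb"`, `"kde"`,
#'   `"empirical"`, or `"denoised"` (requires `denoised_table`).
#' @param metric `"was"` (default) or `"jsd"`.
#' @param cell_covars names of cell-level covariate columns in
#'   `data$cell_meta`; default `"log_rd"`.
#' @param indiv_covars names of individual-level covariate columns in
#'   `data$indiv_meta`; default none.
#' @param n_perm maximum permutations per gene (default 999; use 9999 for
#'   final analyses).
#' @param seed global integer seed; each gene gets an independent seed
#'   derived from it and the gene index, so results do not depend on worker
#'   count or gene subsetting order.
#' @param mode `"permute"` (default) or `"resample"` (redraw X given the
#'   covariates; can be unstable at small n).
#' @param min_cells minimum cells per individual; fewer marks the gene
#'   `fit_failed` for that individual.
#' @param early_stop adaptive stopping of clearly-null permutation runs
#'   (see [permutation_test()]).
#' @param zero_covars for `fit = "zinb"`: `"same"` or `"intercept"`.
#' @param denoised_table a [read_cell_distribution_table()] data frame for
#'   `fit = "denoised"`.
#' @param denoised_route `"aggregate"` (average the cell densities;
#'   default) or `"sample"` (draw `m_sample` counts per cell and refit NB,
#'   which keeps covariate adjustment).
#' @param m_sample counts drawn per cell on the sampling route (default 5).
#' @param workers number of parallel workers (forked; results identical for
#'   any value).
#' @return An object of class `distde` with elements `results` (data frame:
#'   `gene_id`, `F_stat`, `pvalue`, `n_perm_used`, `status`), `config`,
#'   `call`, `n_individuals`. Methods: `print`, `summary` (adds q-values,
#'   the null-proportion estimate and the DE-proportion estimate), `plot`,
#'   `as.data.frame`.
#' @export
distde <- function(data, x_column, fit = c("nb", "zinb", "kde", "empirical",
                                           "denoised"),
                   metric = c("was", "jsd"), cell_covars = "log_rd",
                   indiv_covars = character(), n_perm = 999, seed = 1,
                   mode = c("permute", "resample"), min_cells = 10,
                   early_stop = TRUE, zero_covars = "same",
                   denoised_table = NULL,
                   denoised_route = c("aggregate", "sample"), m_sample = 5,
                   workers = 1) {
  stopifnot(inherits(data, "cell_data"))
  fit <- match.arg(fit)
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  denoised_route <- match.arg(denoised_route)
  if (fit == "denoised") {
    if (is.null(denoised_table)) stop("fit='denoised' requires denoised_table")
    attr(denoised_table, "route") <- denoised_route
  }
  missing_cv <- setdiff(cell_covars, names(data$cell_meta))
  if (length(missing_cv)) stop("cell covariates not in cell_meta: ",
                               paste(missing_cv, collapse = ", "))
  config <- list(fit = fit, metric = metric, n_perm = n_perm, seed = seed,
                 mode = mode, min_cells = min_cells, early_stop = early_stop,
                 zero_covars = zero_covars, m_sample = m_sample,
                 cell_covars = cell_covars, indiv_covars = indiv_covars,
                 x_column = x_column)

  inds <- data$indiv_meta$individual
  cells_by_ind <- lapply(inds, function(id) which(data$cell_meta$individual == id))
  names(cells_by_ind) <- inds
  covars <- as.matrix(data$cell_meta[, cell_covars, drop = FALSE])
  rownames(covars) <- data$cell_ids
  ref_covars <- apply(covars, 2L, stats::median)
  Z <- design_matrix(data$indiv_meta, x_column, indiv_covars, inds)

  dense <- as.matrix(data$counts)
  run1 <- function(i) one_gene_test(dense[i, ], data$gene_ids[i], i,
                                    cells_by_ind, covars, ref_covars, Z,
                                    x_column, config, denoised_table)
  res <- if (workers > 1 && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(nrow(dense)), run1, mc.cores = workers)
  } else lapply(seq_len(nrow(dense)), run1)

  results <- data.frame(
    gene_id = vapply(res, `[[`, "", "gene_id"),
    F_stat = vapply(res, `[[`, 0, "F_stat"),
    pvalue = vapply(res, `[[`, 0, "pvalue"),
    n_perm_used = vapply(res, function(r) as.integer(r$n_perm_used), 0L),
    status = vapply(res, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  structure(list(results = results, config = config, call = match.call(),
                 n_individuals = length(inds), ref_covars = ref_covars),
            class = "distde")
}

#' Test a single gene
#'
#' Runs the full per-gene chain (distribution fits, distance matrix, Gower
#' centering, permutation test) for one gene of a [cell_data()] object,
#' with the same defaults and per-gene seeding as [distde()].
#'
#' @inheritParams distde
#' @param gene gene id present in `data$gene_ids`.
#' @return A [test_result()].
#' @export
test_gene <- function(data, gene, x_column, ...) {
  i <- match(gene, data$gene_ids)
  if (is.na(i)) stop("gene '", gene, "' not found")
  fitobj <- distde(data_subset_genes(data, i), x_column, ...)
  r <- fitobj$results
  # re-derive the per-gene seed from the gene's position in the full object
  test_result(r$gene_id, r$F_stat, r$pvalue, r$n_perm_used, r$status,
              gene_seed(fitobj$config$seed, 1L))
}

data_subset_genes <- function(data, idx) {
  data$counts <- data$counts[idx, , drop = FALSE]
  data$gene_ids <- data$gene_ids[idx]
  data
}

#' @export
print.distde <- function(x, ...) {
  st <- table(x$results$status)
  cat("distde fit: ", nrow(x$results), " genes, ", x$n_individuals,
      " individuals\n", sep = "")
  cat("  estimator: ", x$config$fit, " + ", x$config$metric,
      ", up to ", x$config$n_perm, " permutations (seed ", x$config$seed,
      ")\n", sep = "")
  cat("  status: ", paste(names(st), as.integer(st), sep = "=",
                          collapse = ", "), "\n", sep = "")
  ok <- x$results$pvalue[x$results$status == "ok"]
  if (length(ok))
    cat("  p-values: min ", format(min(ok), digits = 3), ", ",
        sum(ok < 0.05), " below 0.05\n", sep = "")
  invisible(x)
}

#' @rdname distde
#' @param object,x a `distde` object.
#' @param ... unused.
#' @export
summary.distde <- function(object, ...) {
  res <- object$results
  ok <- res$status == "ok" & !is.na(res$pvalue)
  res$qvalue <- NA_real_
  pi0 <- NA_real_; de_prop <- NA_real_
  if (sum(ok) >= 10L) {
    qv <- storey_qvalues(res$pvalue[ok])
    res$qvalue[ok] <- qv
    pi0 <- attr(qv, "pi0")
    de_prop <- de_proportion(res$pvalue[ok])
  }
  structure(list(results = res, pi0 = pi0, de_proportion = de_prop,
                 config = object$config, n_individuals = object$n_individuals),
            class = "summary.distde")
}

#' @export
print.summary.distde <- function(x, ...) {
  cat("distde summary: ", nrow(x$results), " genes\n", sep = "")
  cat(sprintf("  estimated null proportion (pi0, lambda = 0.5): %.3f\n", x$pi0))
  cat(sprintf("  estimated DE proportion (1 - 2*p0(0.5)):       %.3f\n",
              x$de_proportion))
  ok <- !is.na(x$results$qvalue)
  for (cut in c(0.05, 0.1, 0.2))
    cat(sprintf("  genes with q-value <= %.2f: %d\n", cut,
                sum(x$results$qvalue[ok] <= cut)))
  invisible(x)
}

#' @export
as.data.frame.distde <- function(x, ...) x$results

#' @export
as.data.frame.summary.distde <- function(x, ...) x$results

#' @rdname distde
#' @export
plot.distde <- function(x, ...) {
  p <- x$results$pvalue[x$results$status == "ok"]
  graphics::hist(p, breaks = seq(0, 1, by = 0.05),
                 main = "Permutation p-values", xlab = "p-value",
                 col = "grey80", border = "white", ...)
  graphics::abline(h = length(p) / 20, lty = 2)
  invisible(x)
}
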