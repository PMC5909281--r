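#' Pearson correlation between true and estimated proportions
#'
#' Thin wrapper around the sample Pearson correlation coefficient, the
#' accuracy measure used throughout the parameter-recovery benchmarks.
#' Requires at least three pairs and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return a single correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 3L) stop("Pearson correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation is undefined for zero-variance input")
  }
  stats::cor(x, y)
}

#' Compare an estimate with the simulation truth
#'
#' Pairs true and estimated donor proportions (matching on donor ID when
#' both are named) and reports the Pearson correlation and the maximum
#' absolute error.
#'
#' @param true_theta true proportion vector, optionally named by donor.
#' @param estimate a fitted [pool_em()] object or a numeric proportion
#'   vector, optionally named.
#' @param grid_cell optional label (e.g. `c(N, M, X)`) carried into the
#'   report.
#' @return object of class `recovery_report`: list with `pairs` (data
#'   frame donor_id/true/estimated, ordered by donor_id), `pearson_r`
#'   (`NA` when fewer than 3 donors), and `max_abs_error`.
#' @export
evaluate_recovery <- function(true_theta, estimate, grid_cell = NULL) {
  est <- if (inherits(estimate, "pool_em")) coef(estimate) else estimate
  if (!is.numeric(est)) stop("`estimate` must be a pool_em fit or numeric")
  if (length(est) != length(true_theta)) {
    stop("true and estimated vectors have different lengths")
  }
  ids <- names(est)
  if (!is.null(ids) && !is.null(names(true_theta))) {
    if (!setequal(ids, names(true_theta))) {
      stop("donor IDs of the estimate do not match those of the truth")
    }
    true_theta <- true_theta[ids]
  }
  if (is.null(ids)) ids <- paste0("donor", seq_along(est))
  ord <- order(ids)
  pairs <- data.frame(donor_id = ids[ord],
                      true_proportion = as.numeric(true_theta)[ord],
                      estimated_proportion = as.numeric(est)[ord],
                      stringsAsFactors = FALSE)
  r <- if (length(est) >= 3L && stats::sd(true_theta) > 0 &&
           stats::sd(est) > 0) {
    pearson_r(pairs$true_proportion, pairs$estimated_proportion)
  } else NA_real_
  structure(list(pairs = pairs, pearson_r = r,
                 max_abs_error = max(abs(pairs$true_proportion -
                                           pairs$estimated_proportion)),
                 grid_cell = grid_cell),
            class = "recovery_report")
}

#' @export
#' @method print recovery_report
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report")
  if (!is.null(x$grid_cell)) {
    cat(" [", paste(x$grid_cell, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  cat(sprintf("  donors: %d   Pearson R: %s   max |error|: %.4g\n",
              nrow(x$pairs),
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.4f", x$pearson_r)),
              x$max_abs_error))
  invisible(x)
}

#' Run a simulation benchmark grid
#'
#' For every combination of donor count, SNP count and depth, simulates an
#' independent pool, fits the EM estimator, and scores recovery.  One
#' replicate per cell by default; more replicates rerun each cell with
#' fresh seeds so correlations can be averaged for stability.
#'
#' Iterations per cell follow the pool-size rule used throughout: 500 for
#' pools of up to ten donors, 2000 otherwise; pass `iterations` to
#' override.
#'
#' @param cells data frame with columns `n_donors`, `n_snps`, `depth`
#'   (one row per grid cell).
#' @param iterations EM iteration budget, or `NULL` for the pool-size
#'   rule.
#' @param tol early-stopping tolerance forwarded to [pool_em()].
#' @param seed master seed; per-run seeds are derived from it
#'   deterministically.
#' @param replicates independent repeats per cell.
#' @param out optional path; when given, the result table is also written
#'   as TSV.
#' @return data frame with one row per run: `n_donors`, `n_snps`,
#'   `depth`, `replicate`, `seed`, `pearson_r`, `max_abs_error`.
#' @examples
#' cells <- expand.grid(n_donors = 5, n_snps = c(500, 2000), depth = 10)
#' run_grid(cells, seed = 1)
#' @export
run_grid <- function(cells, iterations = NULL, tol = 0, seed = 1,
                     replicates = 1, out = NULL) {
  cells <- as.data.frame(cells)
  need <- c("n_donors", "n_snps", "depth")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("`cells` is missing column(s): ",
                         paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  n_runs <- nrow(cells) * replicates
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  rows <- vector("list", n_runs)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (rep in seq_len(replicates)) {
      k <- k + 1L
      cell <- cells[i, ]
      sim <- simulate_pool(cell$n_donors, cell$n_snps, cell$depth,
                           seed = run_seeds[k])
      iters <- if (is.null(iterations)) {
        if (cell$n_donors <= 10L) 500L else 2000L
      } else iterations
      fit <- pool_em(sim$panel, sim$counts, iterations = iters, tol = tol)
      rep_report <- evaluate_recovery(sim$true_theta, fit)
      rows[[k]] <- data.frame(
        n_donors = cell$n_donors, n_snps = cell$n_snps, depth = cell$depth,
        replicate = rep, seed = run_seeds[k],
        pearson_r = rep_report$pearson_r,
        max_abs_error = rep_report$max_abs_error)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
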