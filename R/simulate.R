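#' Simulate minor-allele frequencies
#'
#' Draws one MAF per SNP from a uniform distribution, by default on
#' \[0.05, 0.5\] -- the common-variant range used throughout the
#' simulation framework.
#'
#' @param n_snps number of SNPs M.
#' @param maf_range length-2 numeric, lower and upper MAF bound.
#' @return numeric vector of length `n_snps`.
#' @export
simulate_mafs <- function(n_snps, maf_range = c(0.05, 0.5)) {
  check_range(maf_range, "maf_range", lo = 0, hi = 0.5, strict_lo = TRUE)
  stats::runif(n_snps, maf_range[1], maf_range[2])
}

#' Simulate a donor genotype panel under Hardy-Weinberg equilibrium
#'
#' For a SNP with minor-allele frequency f, each donor independently gets
#' genotype RR, RA or AA with probability \eqn{f^2}, \eqn{2f(1-f)} and
#' \eqn{(1-f)^2}.  In simulated panels the R allele therefore plays the
#' minor-allele role; the EM estimator is symmetric in the allele
#' labelling, so this differs from real-data panels (where R is the
#' reference allele) only in notation.
#'
#' Genotypes are drawn donor by donor (column-major), each donor's
#' R-allele count at a SNP being one Binomial(2, f) draw.
#'
#' @param mafs per-SNP minor-allele frequencies in (0, 1).
#' @param n_donors number of donors N.
#' @return a [donor_panel] with placeholder SNP positions `sim:1..M`.
#' @export
simulate_genotypes <- function(mafs, n_donors) {
  if (any(mafs <= 0) || any(mafs >= 1)) stop("`mafs` must lie in (0, 1)")
  n_donors <- as.integer(n_donors)
  if (n_donors < 1L) stop("`n_donors` must be >= 1")
  M <- length(mafs)
  g <- matrix(as.raw(0L), M, n_donors)
  for (n in seq_len(n_donors)) {
    g[, n] <- as.raw(stats::rbinom(M, 2L, mafs))
  }
  donor_panel(g)
}

#' Simulate true pool proportions from copy numbers
#'
#' Each donor receives an integer copy number drawn uniformly from
#' `copy_range` (inclusive), representing how many genome copies of that
#' donor went into the pool; the true proportion is the normalized copy
#' number.
#'
#' @param n_donors number of donors N.
#' @param copy_range length-2 integer, inclusive bounds of the uniform
#'   copy-number distribution (default 1..10000).
#' @return list with integer `copy_numbers` and numeric `true_theta`
#'   summing to 1.
#' @export
simulate_true_proportions <- function(n_donors, copy_range = c(1L, 10000L)) {
  n_donors <- as.integer(n_donors)
  if (n_donors < 1L) stop("`n_donors` must be >= 1")
  copy_range <- as.integer(copy_range)
  if (length(copy_range) != 2L || anyNA(copy_range) ||
      copy_range[1] < 1L || copy_range[1] > copy_range[2]) {
    stop("`copy_range` must be increasing positive integers")
  }
  copies <- copy_range[1] + sample.int(copy_range[2] - copy_range[1] + 1L,
                                       n_donors, replace = TRUE) - 1L
  list(copy_numbers = copies, true_theta = copies / sum(copies))
}

#' Simulate pooled sequencing reads
#'
#' At each SNP the pooled R-allele probability is
#' \eqn{P_{m,R} = \sum_n d_{m,n}\theta_n} (the donor-weighted dosage);
#' exactly `depth` reads are drawn per SNP, the number of R reads being
#' Binomial(`depth`, \eqn{P_{m,R}}) and the rest A reads.
#'
#' @param panel a [donor_panel].
#' @param true_theta simplex vector of true donor proportions.
#' @param depth integer reads per SNP (coverage X).
#' @return an [allele_counts] aligned with `panel`; attribute `p_r` holds
#'   the per-SNP R-allele probabilities.
#' @export
simulate_reads <- function(panel, true_theta, depth) {
  stopifnot_panel(panel)
  true_theta <- check_theta(true_theta, n_donors(panel))
  depth <- as.integer(depth)
  if (depth < 1L) stop("`depth` must be >= 1")
  p_r <- .em_totals(panel$genotypes, true_theta)
  r <- stats::rbinom(n_snps(panel), depth, p_r)
  out <- allele_counts(r, depth - r, snps = panel$snps)
  attr(out, "p_r") <- p_r
  out
}

#' Simulate a complete mixed pool
#'
#' Composes the full generative model used to benchmark the estimator:
#' uniform MAFs, Hardy-Weinberg genotypes for N donors, uniform integer
#' copy numbers defining the true proportions, and fixed-depth binomial
#' read sampling.  With a `seed`, the result is a pure function of the
#' arguments.  The draw order is fixed (MAFs, then genotypes donor by
#' donor, then copy numbers, then reads), so each stage is reproducible.
#'
#' @param n_donors number of donors N.
#' @param n_snps number of SNPs M.
#' @param depth reads per SNP X.
#' @param maf_range,copy_range see [simulate_mafs()] and
#'   [simulate_true_proportions()].
#' @param seed optional integer seed (sets the R RNG).
#' @return an object of class `pool_sim`: list with `panel`
#'   ([donor_panel]), `counts` ([allele_counts]), `true_theta`,
#'   `copy_numbers`, `mafs`, `p_r`, and the call parameters in `params`.
#' @examples
#' sim <- simulate_pool(n_donors = 5, n_snps = 100, depth = 10, seed = 1)
#' sim
#' fit <- pool_em(sim$panel, sim$counts, iterations = 500)
#' cor(sim$true_theta, coef(fit))
#' @export
simulate_pool <- function(n_donors, n_snps, depth,
                          maf_range = c(0.05, 0.5),
                          copy_range = c(1L, 10000L), seed = NULL) {
  n_donors <- as.integer(n_donors)
  n_snps <- as.integer(n_snps)
  depth <- as.integer(depth)
  if (anyNA(c(n_donors, n_snps, depth)) ||
      n_donors < 1L || n_snps < 1L || depth < 1L) {
    stop("`n_donors`, `n_snps` and `depth` must be positive integers")
  }
  check_range(maf_range, "maf_range", lo = 0, hi = 0.5, strict_lo = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mafs <- simulate_mafs(n_snps, maf_range)
  panel <- simulate_genotypes(mafs, n_donors)
  truth <- simulate_true_proportions(n_donors, copy_range)
  counts <- simulate_reads(panel, truth$true_theta, depth)
  structure(list(
    panel = panel,
    counts = counts,
    true_theta = truth$true_theta,
    copy_numbers = truth$copy_numbers,
    mafs = mafs,
    p_r = attr(counts, "p_r"),
    params = list(n_donors = n_donors, n_snps = n_snps, depth = depth,
                  maf_range = maf_range, copy_range = copy_range,
                  seed = seed)
  ), class = "pool_sim")
}

#' @export
#' @method print pool_sim
print.pool_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("Simulated mixed pool: %d donors, %d SNPs, depth %dX\n",
              p$n_donors, p$n_snps, p$depth))
  cat(sprintf("  true proportions: min %.4g, max %.4g (copy numbers %d..%d)\n",
              min(x$true_theta), max(x$true_theta),
              min(x$copy_numbers), max(x$copy_numbers)))
  if (!is.null(p$seed)) cat("  seed:", p$seed, "\n")
  invisible(x)
}

check_range <- function(x, name, lo, hi, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2] ||
      (if (strict_lo) x[1] <= lo else x[1] < lo) || x[2] > hi) {
    stop("`", name, "` must be an increasing pair within (",
         lo, ", ", hi, "]")
  }
  invisible(x)
}
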