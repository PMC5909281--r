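#' Uniform starting proportions
#'
#' The EM iteration starts from equal proportions for every donor,
#' \eqn{\theta_n^0 = 1/N}, renormalized so the simplex sum is exactly 1.
#'
#' @param n_donors positive integer, the number of donors N.
#' @return numeric vector of length `n_donors` summing to 1.
#' @examples
#' em_initialize(4)
#' @export
em_initialize <- function(n_donors) {
  n_donors <- as.integer(n_donors)
  if (length(n_donors) != 1L || is.na(n_donors) || n_donors < 1L) {
    stop("`n_donors` must be a positive integer")
  }
  theta <- rep(1 / n_donors, n_donors)
  theta / sum(theta)
}

#' Expected allele totals under a proportion estimate
#'
#' For the current estimate \eqn{\theta}, the expected fraction of pooled
#' reads carrying the R allele at SNP m is
#' \deqn{Total_{m,R} = \sum_n d_{m,n} \theta_n,}
#' where \eqn{d_{m,n}} is donor n's R-allele dosage (RR = 1, RA = 0.5,
#' AA = 0), and \eqn{Total_{m,A} = \sum_n (1 - d_{m,n})\theta_n}.  Because
#' \eqn{\theta} lies on the simplex, the two totals sum to 1 at every SNP.
#'
#' @param panel a [donor_panel]
#' @param theta numeric proportion vector of length `n_donors(panel)`.
#' @return list with numeric vectors `total_r` and `total_a`, one entry
#'   per SNP.
#' @examples
#' p <- donor_panel(matrix(c("RR", "AA"), 1, 2))
#' expected_allele_totals(p, c(0.6, 0.4))
#' @export
expected_allele_totals <- function(panel, theta) {
  stopifnot_panel(panel)
  theta <- check_theta(theta, n_donors(panel))
  total_r <- .em_totals(panel$genotypes, theta)
  list(total_r = total_r, total_a = sum(theta) - total_r)
}

#' Per-donor likelihood scores
#'
#' The unnormalized score apportioning the observed reads to donor n under
#' the current estimate:
#' \deqn{L_n = \sum_m \begin{cases}
#'   (\theta_n / Total_{m,R})\, Reads_{m,R} & RR \\
#'   0.5\left[(\theta_n / Total_{m,R})\, Reads_{m,R} +
#'            (\theta_n / Total_{m,A})\, Reads_{m,A}\right] & RA \\
#'   (\theta_n / Total_{m,A})\, Reads_{m,A} & AA
#' \end{cases}}
#' A term whose expected total is zero is skipped, so division by zero
#' cannot occur (reads observed at such a SNP are incompatible with every
#' donor that could contribute them and are discarded from the sum).
#' The scores always sum to the total number of non-skipped reads.
#'
#' @inheritParams expected_allele_totals
#' @param counts an [allele_counts] aligned 1:1 with `panel`.
#' @param totals precomputed [expected_allele_totals()]; computed when
#'   omitted.
#' @return numeric vector of length N of non-negative scores.
#' @examples
#' p <- donor_panel(matrix(c("RR", "AA"), 1, 2))
#' cnt <- allele_counts(3L, 1L)
#' donor_likelihood_scores(p, cnt, c(0.5, 0.5))
#' @export
donor_likelihood_scores <- function(panel, counts, theta, totals = NULL) {
  stopifnot_panel(panel)
  check_aligned(panel, counts)
  theta <- check_theta(theta, n_donors(panel))
  if (is.null(totals)) totals <- expected_allele_totals(panel, theta)
  u <- counts$r_counts / totals$total_r
  u[totals$total_r <= 0] <- 0
  v <- counts$a_counts / totals$total_a
  v[totals$total_a <= 0] <- 0
  scores <- .em_scores(panel$genotypes, theta, u - v, sum(v))
  names(scores) <- panel$donor_ids
  scores
}

#' One EM iteration
#'
#' Re-estimates the donor proportions from the likelihood scores:
#' \eqn{\theta_n^{t+1} = L_n / \sum_n L_n}.
#'
#' @inheritParams donor_likelihood_scores
#' @return updated numeric proportion vector (named by donor), summing
#'   to 1.
#' @examples
#' p <- donor_panel(matrix(c("RR", "AA"), 1, 2))
#' em_step(p, allele_counts(3L, 1L), em_initialize(2))
#' @export
em_step <- function(panel, counts, theta) {
  scores <- donor_likelihood_scores(panel, counts, theta)
  s <- sum(scores)
  if (!(s > 0)) {
    stop("degenerate input: no donor in the panel is compatible with any ",
         "observed read (all likelihood scores are zero)")
  }
  scores / s
}

#' Observed-data log-likelihood
#'
#' The log-likelihood of the read counts under the mixture model the EM
#' maximizes: each read at SNP m is an R allele with probability
#' \eqn{Total_{m,R}(\theta)}, so
#' \deqn{\ell(\theta) = \sum_m Reads_{m,R} \log Total_{m,R}
#'                    + Reads_{m,A} \log Total_{m,A},}
#' with zero-count terms skipped.  A positive count at a SNP whose expected
#' total is zero makes the data impossible under \eqn{\theta}; the function
#' then returns `-Inf` with attribute `incompatible_reads` giving the
#' number of such reads.
#'
#' @inheritParams donor_likelihood_scores
#' @return a single numeric value (possibly `-Inf`).
#' @examples
#' p <- donor_panel(matrix(c("RR", "AA"), 1, 2))
#' observed_loglik(p, allele_counts(3L, 1L), c(0.75, 0.25))
#' 3 * log(0.75) + log(0.25)
#' @export
observed_loglik <- function(panel, counts, theta) {
  stopifnot_panel(panel)
  check_aligned(panel, counts)
  theta <- check_theta(theta, n_donors(panel))
  totals <- expected_allele_totals(panel, theta)
  r <- counts$r_counts
  a <- counts$a_counts
  bad_r <- r > 0 & totals$total_r <= 0
  bad_a <- a > 0 & totals$total_a <= 0
  if (any(bad_r) || any(bad_a)) {
    ll <- -Inf
    attr(ll, "incompatible_reads") <- sum(r[bad_r]) + sum(a[bad_a])
    return(ll)
  }
  ir <- r > 0
  ia <- a > 0
  sum(r[ir] * log(totals$total_r[ir])) + sum(a[ia] * log(totals$total_a[ia]))
}

#' Estimate donor proportions in a pooled sample by EM
#'
#' Fits the donor mixture model: every sequenced read at a bi-allelic SNP
#' is assumed to originate from donor n with probability \eqn{\theta_n} and
#' to carry the R allele with probability given by that donor's genotype
#' dosage.  Starting from uniform proportions, each iteration computes the
#' expected allele totals, apportions the observed reads into per-donor
#' likelihood scores, and renormalizes.  Each iteration cannot decrease the
#' observed-data log-likelihood.
#'
#' By default the update runs for a fixed number of iterations (2000;
#' pools of ten or fewer donors converge well before 500).  Setting
#' `tol > 0` additionally stops as soon as the largest per-donor change in
#' one iteration drops to `tol` or below.
#'
#' @param panel a [donor_panel] of known genotypes for the N candidate
#'   donors.
#' @param counts an [allele_counts] with the pooled sample's per-SNP R/A
#'   read tallies.  If its SNP table is not already aligned 1:1 with the
#'   panel, use [align_counts()] first.
#' @param iterations maximum number of EM iterations t.
#' @param tol early-stopping tolerance on \eqn{\max_n |\theta_n^{t+1} -
#'   \theta_n^t|}; 0 (default) disables early stopping and runs exactly
#'   `iterations` iterations.
#' @param trace logical; record the full per-iteration estimate history
#'   (rows \eqn{\theta^0 \dots \theta^T}).
#' @param loglik logical; record the observed-data log-likelihood of every
#'   recorded estimate (adds roughly one log per covered SNP per
#'   iteration).
#' @return an object of class `pool_em` with components
#'   \describe{
#'     \item{theta}{named final proportion estimate, summing to 1}
#'     \item{iterations}{number of iterations performed}
#'     \item{converged}{`TRUE` iff early stopping triggered}
#'     \item{last_change}{max-abs change of the final iteration}
#'     \item{trace}{(optional) `(iterations+1) x N` estimate history}
#'     \item{loglik_trace}{(optional) log-likelihood per recorded estimate}
#'     \item{diagnostics}{SNPs used, total reads, reads skipped as
#'       incompatible at the final iteration}
#'   }
#'   with `print`, `summary`, `coef`, `logLik`, `fitted`, `residuals`,
#'   `plot` and `simulate` methods.
#' @examples
#' panel <- donor_panel(matrix(c("RR", "AA"), 1, 2),
#'                      donor_ids = c("alice", "bob"))
#' fit <- pool_em(panel, allele_counts(3L, 1L), iterations = 200)
#' coef(fit)   # converges to (0.75, 0.25), the closed-form MLE
#' @export
pool_em <- function(panel, counts, iterations = 2000, tol = 0,
                    trace = FALSE, loglik = FALSE) {
  stopifnot_panel(panel)
  if (!inherits(counts, "allele_counts")) stop("`counts` must be allele_counts")
  check_aligned(panel, counts)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("`iterations` must be >= 1")
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0) {
    stop("`tol` must be a single non-negative number")
  }
  if (n_snps(panel) < 1L) stop("panel has no SNPs")
  total_reads <- sum(counts$r_counts) + sum(counts$a_counts)
  if (total_reads < 1L) stop("counts contain no reads")

  res <- .em_run(panel$genotypes,
                 as.numeric(counts$r_counts), as.numeric(counts$a_counts),
                 em_initialize(n_donors(panel)),
                 iterations, tol, isTRUE(trace), isTRUE(loglik))
  if (res$degenerate) {
    stop("degenerate input: no donor in the panel is compatible with any ",
         "observed read (all likelihood scores are zero)")
  }
  theta <- res$theta
  names(theta) <- panel$donor_ids
  out <- list(
    theta = theta,
    iterations = res$iterations,
    converged = res$converged,
    last_change = res$last_change,
    diagnostics = list(
      n_snps = n_snps(panel),
      n_donors = n_donors(panel),
      total_reads = total_reads,
      skipped_r_reads = res$skipped_r_reads,
      skipped_a_reads = res$skipped_a_reads
    ),
    panel = panel,
    counts = counts,
    call = match.call()
  )
  if (isTRUE(trace)) {
    colnames(res$trace) <- panel$donor_ids
    out$trace <- res$trace
  }
  if (isTRUE(loglik)) out$loglik_trace <- res$loglik_trace
  class(out) <- "pool_em"
  out
}

check_theta <- function(theta, n) {
  if (!is.numeric(theta)) stop("`theta` must be numeric")
  if (length(theta) != n) {
    stop("`theta` has length ", length(theta), " but the panel has ", n,
         " donors")
  }
  if (anyNA(theta) || any(theta < 0)) stop("`theta` must be non-negative")
  as.numeric(theta)
}

#' @export
#' @method print pool_em
print.pool_em <- function(x, ...) {
  cat("Pooled-sample donor proportion estimate (EM)\n")
  cat(sprintf("  %d donors, %d SNPs, %d reads\n",
              x$diagnostics$n_donors, x$diagnostics$n_snps,
              x$diagnostics$total_reads))
  cat(sprintf("  %d iterations (%s), final max change %.3g\n",
              x$iterations,
              if (x$converged) "early-stopped" else "fixed budget",
              x$last_change))
  k <- min(6L, length(x$theta))
  top <- sort(x$theta, decreasing = TRUE)[seq_len(k)]
  cat("  largest proportions:\n")
  print(round(top, 5))
  invisible(x)
}

#' @export
coef.pool_em <- function(object, ...) object$theta

#' @export
logLik.pool_em <- function(object, ...) {
  ll <- if (!is.null(object$loglik_trace)) {
    object$loglik_trace[length(object$loglik_trace)]
  } else {
    as.numeric(observed_loglik(object$panel, object$counts, object$theta))
  }
  structure(ll, df = object$diagnostics$n_donors - 1L,
            nobs = object$diagnostics$total_reads, class = "logLik")
}

#' @export
fitted.pool_em <- function(object, ...) {
  expected_allele_totals(object$panel, object$theta)$total_r
}

#' Residual allele-fraction deviations
#'
#' For each SNP with at least one read, the observed R-allele fraction
#' minus the fitted expected fraction \eqn{Total_{m,R}(\hat\theta)}.
#' SNPs without reads give `NA`.
#'
#' @param object a fitted [pool_em()] object.
#' @param ... unused.
#' @export
residuals.pool_em <- function(object, ...) {
  depth <- object$counts$r_counts + object$counts$a_counts
  obs <- ifelse(depth > 0, object$counts$r_counts / depth, NA_real_)
  obs - fitted(object)
}

#' @export
summary.pool_em <- function(object, ...) {
  s <- list(
    n_donors = object$diagnostics$n_donors,
    n_snps = object$diagnostics$n_snps,
    total_reads = object$diagnostics$total_reads,
    iterations = object$iterations,
    converged = object$converged,
    last_change = object$last_change,
    theta = object$theta,
    simplex_sum = sum(object$theta),
    skipped = object$diagnostics$skipped_r_reads +
      object$diagnostics$skipped_a_reads
  )
  class(s) <- "summary.pool_em"
  s
}

#' @export
#' @method print summary.pool_em
print.summary.pool_em <- function(x, ...) {
  cat("EM donor proportion estimate\n")
  cat(sprintf("  donors: %d   SNPs: %d   reads: %d (skipped: %g)\n",
              x$n_donors, x$n_snps, x$total_reads, x$skipped))
  cat(sprintf("  iterations: %d   converged: %s   final max change: %.3g\n",
              x$iterations, x$converged, x$last_change))
  cat(sprintf("  simplex sum: %.12f\n", x$simplex_sum))
  cat("  proportion quartiles:\n")
  print(stats::quantile(x$theta))
  invisible(x)
}

#' Plot the EM estimate trajectory
#'
#' One line per donor showing the proportion estimate at every iteration
#' (requires a fit with `trace = TRUE`).
#'
#' @param x a fitted [pool_em()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
#' @method plot pool_em
plot.pool_em <- function(x, ...) {
  if (is.null(x$trace)) {
    stop("no trace recorded; refit with pool_em(..., trace = TRUE)")
  }
  graphics::matplot(x = seq_len(nrow(x$trace)) - 1L, y = x$trace,
                    type = "l", lty = 1,
                    xlab = "iteration", ylab = "estimated proportion", ...)
  invisible(x)
}

#' Simulate read counts from a fitted estimate
#'
#' Parametric bootstrap: draws new per-SNP binomial read counts at the
#' fitted expected allele fractions, with each SNP's depth equal to the
#' observed depth.
#'
#' @param object a fitted [pool_em()] object.
#' @param nsim number of replicate count sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of [allele_counts] objects of length `nsim`.
#' @export
simulate.pool_em <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted(object)
  depth <- object$counts$r_counts + object$counts$a_counts
  lapply(seq_len(nsim), function(i) {
    r <- stats::rbinom(length(p), depth, p)
    allele_counts(r, depth - r, snps = object$counts$snps)
  })
}
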