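# Shared test helpers: small random EM instances and a cache for the
# expensive benchmark cells so several tests can reuse one simulation+fit.

# Random small instance with N donors, M SNPs and at most `max_reads`
# total reads.  Guarantees (a) every read is compatible with at least one
# donor and (b) the log-likelihood has a unique maximizer on the simplex
# (the dosage rows of read-covered SNPs, plus the sum constraint, have
# full column rank), so grid-search and EM must agree.
random_instance <- function(n_donors = 2, n_snps = 2, max_reads = 6) {
  repeat {
    g <- matrix(sample(0:2, n_snps * n_donors, replace = TRUE),
                n_snps, n_donors)
    total <- sample.int(max_reads, 1)
    snp_of_read <- sample.int(n_snps, total, replace = TRUE)
    is_r <- sample(c(TRUE, FALSE), total, replace = TRUE)
    r <- tabulate(snp_of_read[is_r], nbins = n_snps)
    a <- tabulate(snp_of_read[!is_r], nbins = n_snps)
    # compatibility: an R read needs some donor with dosage > 0 there,
    # an A read some donor with dosage < 1
    ok_r <- all(r == 0 | apply(g, 1, max) > 0)
    ok_a <- all(a == 0 | apply(g, 1, min) < 2)
    if (!ok_r || !ok_a) next
    covered <- which(r + a > 0)
    if (!length(covered)) next
    design <- rbind(1, g[covered, , drop = FALSE] / 2)
    if (qr(design)$rank < n_donors) next
    return(list(panel = donor_panel(matrix(as.raw(g), n_snps, n_donors)),
                counts = allele_counts(r, a)))
  }
}

# Exhaustive simplex grid search of the observed-data log-likelihood
# (step h), the independent oracle for the EM fixed point.
grid_search_mle <- function(panel, counts, step = 0.001) {
  d <- r_dosage(panel)
  N <- ncol(d)
  r <- counts$r_counts
  a <- counts$a_counts
  if (N == 2) {
    t1 <- seq(0, 1, by = step)
    thetas <- cbind(t1, 1 - t1)
  } else if (N == 3) {
    t1 <- seq(0, 1, by = step)
    grid <- expand.grid(t1 = t1, t2 = t1)
    grid <- grid[grid$t1 + grid$t2 <= 1 + 1e-12, ]
    thetas <- cbind(grid$t1, grid$t2, pmax(0, 1 - grid$t1 - grid$t2))
  } else {
    stop("oracle supports N <= 3")
  }
  ll <- numeric(nrow(thetas))
  for (m in seq_len(nrow(d))) {
    if (r[m] == 0 && a[m] == 0) next
    tr <- as.vector(thetas %*% d[m, ])
    ta <- 1 - tr
    if (r[m] > 0) ll <- ll + r[m] * ifelse(tr > 0, log(tr), -Inf)
    if (a[m] > 0) ll <- ll + a[m] * ifelse(ta > 0, log(ta), -Inf)
  }
  thetas[which.max(ll), ]
}

# Cache of expensive simulate+fit runs keyed by cell parameters, so the
# benchmark-grid tests and the minimal-depth tests share work.
.cell_cache <- new.env(parent = emptyenv())

recovery_for_cell <- function(n_donors, n_snps, depth, seed,
                              iterations = 2000, tol = 2e-6) {
  key <- paste(n_donors, n_snps, depth, seed, iterations, tol, sep = "_")
  if (!is.null(.cell_cache[[key]])) return(.cell_cache[[key]])
  sim <- simulate_pool(n_donors, n_snps, depth, seed = seed)
  fit <- pool_em(sim$panel, sim$counts, iterations = iterations, tol = tol)
  rep <- evaluate_recovery(sim$true_theta, fit,
                           grid_cell = c(n_donors, n_snps, depth))
  .cell_cache[[key]] <- rep
  rm(sim, fit)
  gc(verbose = FALSE)
  rep
}

# The per-cell seeds run_grid would derive from a master seed, exposed so
# single cells can be reproduced outside run_grid.
grid_cell_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
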