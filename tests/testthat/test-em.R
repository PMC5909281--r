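# Core EM operations against hand-computed and closed-form values, plus
# the algebraic invariants of the update.

two_donor_panel <- function() {
  donor_panel(matrix(c("RR", "AA"), 1, 2), donor_ids = c("d1", "d2"))
}

test_that("uniform initialization lies on the simplex", {
  expect_equal(em_initialize(4), rep(0.25, 4))
  expect_equal(em_initialize(1), 1)
  expect_identical(sum(em_initialize(3)), 1)
  expect_error(em_initialize(0), "positive")
})

test_that("expected allele totals follow the dosage-weighted formula", {
  p <- two_donor_panel()
  tot <- expected_allele_totals(p, c(0.6, 0.4))
  expect_equal(tot$total_r, 0.6)
  expect_equal(tot$total_a, 0.4)

  p2 <- donor_panel(matrix(c("RA", "RA"), 1, 2))
  expect_equal(expected_allele_totals(p2, c(0.5, 0.5))$total_r, 0.5)

  p3 <- donor_panel(matrix(c("RR", "RA"), 1, 2))
  tot3 <- expected_allele_totals(p3, c(0.2, 0.8))
  expect_equal(tot3$total_r, 0.2 + 0.5 * 0.8)
  expect_equal(tot3$total_a, 0.4)

  expect_error(expected_allele_totals(p, c(0.5, 0.3, 0.2)), "length")

  # totals complement each other at every SNP for any simplex theta
  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance(3, 3)
    th <- as.vector(stats::rgamma(3, 1))
    th <- th / sum(th)
    tt <- expected_allele_totals(inst$panel, th)
    expect_equal(tt$total_r + tt$total_a, rep(1, n_snps(inst$panel)),
                 tolerance = 1e-12)
  }
})

test_that("likelihood scores match hand evaluation", {
  p <- two_donor_panel()
  cnt <- allele_counts(3L, 1L)
  sc <- donor_likelihood_scores(p, cnt, c(0.5, 0.5))
  expect_equal(unname(sc), c(3, 1))   # (0.5/0.5)*3 and (0.5/0.5)*1

  het <- donor_panel(matrix("RA", 1, 1))
  sc2 <- donor_likelihood_scores(het, allele_counts(2L, 2L), 1)
  expect_equal(unname(sc2), 4)        # 0.5*((1/0.5)*2 + (1/0.5)*2)

  sc3 <- donor_likelihood_scores(p, allele_counts(0L, 0L), c(0.5, 0.5))
  expect_equal(unname(sc3), c(0, 0))

  # scores sum to the number of reads for any compatible instance
  set.seed(11)
  for (i in 1:20) {
    inst <- random_instance(3, 2)
    th <- em_initialize(3)
    expect_equal(sum(donor_likelihood_scores(inst$panel, inst$counts, th)),
                 sum(inst$counts$r_counts) + sum(inst$counts$a_counts))
  }
})

test_that("one EM step renormalizes the scores", {
  p <- two_donor_panel()
  expect_equal(unname(em_step(p, allele_counts(3L, 1L), c(0.5, 0.5))),
               c(0.75, 0.25))
  single <- donor_panel(matrix("RA", 2, 1))
  expect_equal(unname(em_step(single, allele_counts(c(1L, 0L), c(0L, 2L)), 1)),
               1)
  same <- donor_panel(matrix(c("RR", "RR"), 1, 2))
  expect_equal(unname(em_step(same, allele_counts(5L, 0L), c(0.5, 0.5))),
               c(0.5, 0.5))
})

test_that("EM step errors when no donor is compatible with any read", {
  p <- donor_panel(matrix(c("AA", "AA"), 1, 2))
  expect_error(em_step(p, allele_counts(3L, 0L), c(0.5, 0.5)), "degenerate")
  expect_error(pool_em(p, allele_counts(3L, 0L)), "degenerate")
})

test_that("observed log-likelihood matches the direct formula", {
  p <- two_donor_panel()
  cnt <- allele_counts(3L, 1L)
  expect_equal(observed_loglik(p, cnt, c(0.75, 0.25)),
               3 * log(0.75) + log(0.25))
  expect_equal(observed_loglik(p, allele_counts(0L, 0L), c(0.75, 0.25)), 0)
  # MLE dominates any other theta on this instance
  expect_lt(observed_loglik(p, cnt, c(0.5, 0.5)),
            observed_loglik(p, cnt, c(0.75, 0.25)))
  expect_equal(observed_loglik(p, cnt, c(0.5, 0.5)), 4 * log(0.5))
  # reads impossible under theta give -Inf flagged with the read count
  ll <- observed_loglik(p, cnt, c(0, 1))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "incompatible_reads"), 3)
})

test_that("the full fit converges to the closed-form MLE", {
  p <- two_donor_panel()
  fit <- pool_em(p, allele_counts(3L, 1L), iterations = 2000)
  expect_equal(unname(coef(fit)), c(0.75, 0.25), tolerance = 1e-6)
  expect_equal(fit$iterations, 2000)
  expect_false(fit$converged)

  fit2 <- pool_em(p, allele_counts(3L, 1L), iterations = 2000, tol = 1e-12)
  expect_true(fit2$converged)
  expect_lt(fit2$iterations, 2000)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-9)
})

test_that("pool_em agrees with repeated em_step", {
  set.seed(3)
  inst <- random_instance(3, 3, max_reads = 20)
  fit <- pool_em(inst$panel, inst$counts, iterations = 25, trace = TRUE)
  th <- em_initialize(3)
  for (t in 1:25) th <- em_step(inst$panel, inst$counts, th)
  expect_equal(unname(coef(fit)), unname(th), tolerance = 1e-12)
  expect_equal(dim(fit$trace), c(26L, 3L))
  expect_equal(unname(fit$trace[1, ]), em_initialize(3))
})

test_that("every iteration conserves the simplex", {
  set.seed(21)
  for (i in 1:25) {
    nd <- sample(2:3, 1)
    inst <- random_instance(nd, sample((nd - 1):3, 1))
    fit <- pool_em(inst$panel, inst$counts, iterations = 40, trace = TRUE)
    sums <- rowSums(fit$trace)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(fit$trace >= 0))
  }
})

test_that("the observed log-likelihood never decreases across iterations", {
  set.seed(97)
  for (i in 1:100) {
    nd <- sample(2:3, 1)
    inst <- random_instance(nd, sample((nd - 1):3, 1), max_reads = 12)
    fit <- pool_em(inst$panel, inst$counts, iterations = 30, loglik = TRUE)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  }
})

test_that("scaling all counts leaves the trajectory unchanged", {
  set.seed(5)
  for (i in 1:10) {
    inst <- random_instance(3, 3, max_reads = 10)
    base <- pool_em(inst$panel, inst$counts, iterations = 30, trace = TRUE)
    for (k in c(2L, 4L)) {   # power-of-two scalings are bit-exact
      scaled <- allele_counts(inst$counts$r_counts * k,
                              inst$counts$a_counts * k)
      fitk <- pool_em(inst$panel, scaled, iterations = 30, trace = TRUE)
      expect_identical(fitk$trace, base$trace)
    }
    scaled3 <- allele_counts(inst$counts$r_counts * 3L,
                             inst$counts$a_counts * 3L)
    fit3 <- pool_em(inst$panel, scaled3, iterations = 30, trace = TRUE)
    expect_equal(fit3$trace, base$trace, tolerance = 1e-12)
  }
})

test_that("permuting donors permutes the estimate", {
  set.seed(13)
  for (i in 1:10) {
    inst <- random_instance(3, 3, max_reads = 10)
    perm <- sample(3)
    g <- matrix(inst$panel$genotypes, n_snps(inst$panel), 3)
    permuted <- donor_panel(g[, perm, drop = FALSE],
                            donor_ids = inst$panel$donor_ids[perm])
    f1 <- pool_em(inst$panel, inst$counts, iterations = 30)
    f2 <- pool_em(permuted, inst$counts, iterations = 30)
    expect_equal(unname(coef(f2)), unname(coef(f1))[perm], tolerance = 1e-12)
  }
})

test_that("donors with identical genotype rows get identical estimates", {
  set.seed(31)
  for (i in 1:10) {
    M <- sample(2:4, 1)
    g <- matrix(sample(0:2, M * 2, replace = TRUE), M, 2)
    g <- cbind(g, g[, 1])           # donor 3 duplicates donor 1
    r <- rbinom(M, 4, 0.5)
    p <- donor_panel(matrix(as.raw(g), M, 3))
    cnt <- allele_counts(r, 4L - r)
    ok <- tryCatch({
      fit <- pool_em(p, cnt, iterations = 50, trace = TRUE)
      expect_identical(fit$trace[, 1], fit$trace[, 3])
      TRUE
    }, error = function(e) grepl("degenerate", conditionMessage(e)))
    expect_true(ok)
  }
})

test_that("a donor opposite-homozygous to all reads is suppressed", {
  p <- donor_panel(matrix(c("RR", "RR", "AA", "AA"), 2, 2),
                   donor_ids = c("present", "absent"))
  cnt <- allele_counts(c(6L, 4L), c(0L, 0L))
  fit <- pool_em(p, cnt, iterations = 100)
  expect_lt(coef(fit)[["absent"]], 1e-3)
})

test_that("fit methods expose the model surface", {
  p <- two_donor_panel()
  fit <- pool_em(p, allele_counts(3L, 1L), iterations = 500, trace = TRUE,
                 loglik = TRUE)
  expect_s3_class(fit, "pool_em")
  expect_output(print(fit), "donors")
  expect_output(print(summary(fit)), "simplex sum")
  expect_equal(as.numeric(logLik(fit)),
               observed_loglik(p, allele_counts(3L, 1L), coef(fit)))
  expect_equal(fitted(fit), 0.75, tolerance = 1e-6)
  expect_equal(residuals(fit), 0, tolerance = 1e-6)
  boot <- simulate(fit, nsim = 2, seed = 1)
  expect_length(boot, 2)
  expect_equal(boot[[1]]$r_counts + boot[[1]]$a_counts, 4L)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
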