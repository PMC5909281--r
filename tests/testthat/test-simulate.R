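# The generative model: uniform MAFs, Hardy-Weinberg genotypes, uniform
# copy numbers, fixed-depth binomial reads.

test_that("MAF draws respect their uniform support and mean", {
  set.seed(1)
  m <- simulate_mafs(1e5)
  expect_true(all(m >= 0.05 & m <= 0.5))
  expect_equal(mean(m), 0.275, tolerance = 0.01 / 0.275)
  expect_equal(simulate_mafs(10, maf_range = c(0.3, 0.3)), rep(0.3, 10))
  expect_error(simulate_mafs(10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("genotype frequencies follow Hardy-Weinberg at the given MAF", {
  set.seed(2)
  p <- simulate_genotypes(rep(0.5, 2e4), 10)
  freq <- tabulate(as.integer(p$genotypes) + 1L, 3) / (2e4 * 10)
  # AA, RA, RR at f = 0.5 -> 0.25, 0.5, 0.25; 3 binomial SDs on 2e5 draws
  sd3 <- 3 * sqrt(0.25 * 0.75 / 2e5)
  expect_lt(abs(freq[1] - 0.25), sd3)
  expect_lt(abs(freq[3] - 0.25), sd3)

  pr <- simulate_genotypes(rep(0.05, 2e5), 1)
  rr <- mean(as.integer(pr$genotypes) == 2L)
  expect_equal(rr, 0.0025, tolerance = 3 * sqrt(0.0025 / 2e5) / 0.0025)
})

test_that("true proportions are normalized integer copy numbers", {
  tp <- simulate_true_proportions(4, copy_range = c(7L, 7L))
  expect_equal(tp$true_theta, rep(0.25, 4))
  expect_equal(tp$copy_numbers, rep(7L, 4))
  set.seed(3)
  tp2 <- simulate_true_proportions(50)
  expect_true(all(tp2$copy_numbers >= 1L & tp2$copy_numbers <= 10000L))
  expect_equal(sum(tp2$true_theta), 1, tolerance = 1e-12)
  expect_equal(tp2$true_theta,
               tp2$copy_numbers / sum(tp2$copy_numbers))
})

test_that("read simulation draws binomially at the pooled dosage", {
  rr_panel <- donor_panel(matrix("RR", 5, 1))
  cnt <- simulate_reads(rr_panel, 1, depth = 7)
  expect_equal(cnt$r_counts, rep(7L, 5))
  expect_equal(cnt$a_counts, rep(0L, 5))

  aa_panel <- donor_panel(matrix("AA", 5, 1))
  expect_equal(simulate_reads(aa_panel, 1, depth = 3)$r_counts, rep(0L, 5))

  # donors (RR, RA) at theta (0.5, 0.5) -> P_R = 0.75
  set.seed(4)
  M <- 1e5
  p <- donor_panel(matrix(rep(c(2L, 1L), each = M), M, 2))
  cnt2 <- simulate_reads(p, c(0.5, 0.5), depth = 1)
  expect_equal(attr(cnt2, "p_r"), rep(0.75, M))
  frac <- mean(cnt2$r_counts)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / M))
})

test_that("the composed pool satisfies its invariants and shapes", {
  sim <- simulate_pool(10, 500, 1000, seed = 9)
  expect_equal(n_snps(sim$panel), 500L)
  expect_equal(n_donors(sim$panel), 10L)
  expect_equal(sim$counts$r_counts + sim$counts$a_counts, rep(1000L, 500))
  expect_equal(sum(sim$true_theta), 1, tolerance = 1e-12)
  expect_true(all(sim$mafs >= 0.05 & sim$mafs <= 0.5))
  expect_true(all(sim$p_r >= 0 & sim$p_r <= 1))

  low <- simulate_pool(10, 2000, 1, seed = 9)
  expect_equal(low$counts$r_counts + low$counts$a_counts, rep(1L, 2000))
})

test_that("the pool is a pure function of its seed", {
  a <- simulate_pool(8, 300, 5, seed = 123)
  b <- simulate_pool(8, 300, 5, seed = 123)
  expect_identical(a$panel$genotypes, b$panel$genotypes)
  expect_identical(a$counts$r_counts, b$counts$r_counts)
  expect_identical(a$true_theta, b$true_theta)
  expect_identical(a$mafs, b$mafs)
  c <- simulate_pool(8, 300, 5, seed = 124)
  expect_false(identical(a$counts$r_counts, c$counts$r_counts))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_pool(0, 10, 1), "positive")
  expect_error(simulate_pool(2, 10, 0), "positive")
  expect_error(simulate_pool(2, 10, 1, maf_range = c(0.2, 0.1)), "maf_range")
  expect_error(simulate_true_proportions(3, copy_range = c(5L, 2L)),
               "copy_range")
})
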