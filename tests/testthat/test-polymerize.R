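test_that("propagation probabilities follow the terminal model", {
  sys4 <- default_system()
  # ideal ratios: probabilities reduce to pool fractions
  expect_equal(unname(propagation_probs(1, c(0.5, 0.25, 0.20, 0.05), sys4)),
               c(0.5, 0.25, 0.20, 0.05))
  # binary with r_12 = 2: (0.5/1) / (0.5/1 + 0.5/2) = 2/3
  sys2 <- monomer_system(c("MMA", "OEGMA"), feed = c(0.5, 0.5),
                         reactivity = matrix(c(1, 0.5, 2, 1), 2))
  expect_equal(unname(propagation_probs(1, c(0.5, 0.5), sys2)),
               c(2 / 3, 1 / 3))
  # a bare chain draws from raw pool fractions
  expect_equal(unname(propagation_probs(NA, c(2, 2), sys2)), c(0.5, 0.5))
  # single-monomer system
  sys1 <- monomer_system(data.frame(symbol = "MMA", hlb = 8.45),
                         feed = 1)
  expect_equal(unname(propagation_probs(1, 10, sys1)), 1)
  expect_error(propagation_probs(1, c(0, 0), sys2), "depleted")
})

test_that("Schulz-Zimm length sampling hits the target moments", {
  expect_equal(sample_chain_lengths(5, 100, 1), rep(100L, 5))
  expect_error(sample_chain_lengths(5, 100, 0.9), ">= 1")

  set.seed(11)
  len <- sample_chain_lengths(15000, 100, 1.2)
  expect_true(all(len >= 1))
  # moment identity: PDI = 1 + sigma^2 / mu^2 for equal monomer masses
  expect_equal(mean(len), 100, tolerance = 0.02)
  expect_equal(var(len), 100^2 * 0.2, tolerance = 0.1)
})

test_that("simulation conserves mass and is bit-reproducible", {
  b <- simulate_batch(default_system(), nc = 200, dp_target = 50, seed = 5)
  counts <- tabulate(unlist(b$chains), nbins = 4)
  expect_identical(as.numeric(counts), unname(b$consumed))
  expect_true(all(b$consumed <= b$initial_pool))

  b2 <- simulate_batch(default_system(), nc = 200, dp_target = 50, seed = 5)
  expect_identical(b$chains, b2$chains)
  b3 <- simulate_batch(default_system(), nc = 200, dp_target = 50, seed = 6)
  expect_false(identical(b$chains, b3$chains))
})

test_that("target conversion is realized within one monomer addition", {
  for (conv in c(0.3, 0.5, 0.9)) {
    b <- simulate_batch(default_system(), nc = 300, dp_target = 40,
                        conversion = conv, seed = 2)
    needed <- round(conv * sum(b$initial_pool))
    expect_lte(abs(sum(b$consumed) - needed), 1)
  }
})

test_that("ideal-ratio incorporation matches the feed", {
  b <- default_batch()
  s <- batch_summary(b)
  expect_equal(unname(s$incorporated),
               c(0.50, 0.25, 0.20, 0.05), tolerance = 0.01)
})

test_that("binary Mayo-Lewis limit reproduces the copolymer equation", {
  # r1 = 2, r2 = 0.5, f = (0.5, 0.5), conversion 1%:
  # F1 = (r1 f1^2 + f1 f2) / (r1 f1^2 + 2 f1 f2 + r2 f2^2) = 2/3
  sys <- monomer_system(c("MMA", "OEGMA"), feed = c(0.5, 0.5),
                        reactivity = matrix(c(1, 0.5, 2, 1), 2))
  b <- simulate_batch(sys, nc = 2000, dp_target = 50, conversion = 0.01,
                      pdi_target = 1.1, seed = 3)
  f1 <- vapply(b$chains, function(ch) mean(ch == 1), numeric(1))
  se <- sd(f1) / sqrt(length(f1))
  expect_lt(abs(mean(f1) - 2 / 3), 3 * se + 1e-12)
})

test_that("the more-reactive monomer drains from the pool first", {
  sys <- monomer_system(c("MMA", "OEGMA"), feed = c(0.5, 0.5),
                        reactivity = matrix(c(1, 0.5, 2, 1), 2))
  b <- simulate_batch(sys, nc = 2000, dp_target = 100, conversion = 0.6,
                      seed = 4)
  x1 <- b$pool_trajectory[, 1]
  expect_true(all(diff(x1) <= 1e-4))
  expect_lt(x1[length(x1)], x1[1])
})

test_that("dispersity control: PDI tracks its target and 1.0 is exact", {
  b <- monodisperse_batch()
  expect_identical(unique(lengths(b$chains)), 100L)
  expect_equal(batch_summary(b)$pdi, 1.0)

  b2 <- default_batch()
  expect_lte(batch_summary(b2)$pdi, 1.15 + 0.02)
})

test_that("oligomer filtering retains exactly the chains >= min_dp", {
  b <- generate_fixture("fixed_lengths", lengths = c(10, 14, 15, 20),
                        seed = 1)
  f <- filter_oligomers(b, 15)
  expect_equal(sort(lengths(f$chains)), c(15, 20))
  expect_equal(f$filtered$chains_removed, 2)
  expect_equal(sum(f$filtered$units_removed), 24)
  # pool metadata untouched by filtering
  expect_identical(f$initial_pool, b$initial_pool)

  expect_equal(lengths(filter_oligomers(b, 1)$chains), lengths(b$chains))
  expect_warning(filter_oligomers(b, 100), "empty")
})

test_that("batch summary computes DP_n, DP_w, PDI and conversion", {
  b <- generate_fixture("fixed_lengths", lengths = c(50, 150), seed = 1)
  s <- batch_summary(b)
  expect_equal(s$dp_n, 100)
  expect_equal(s$dp_w, 125)   # (50^2 + 150^2) / 200
  expect_equal(s$pdi, 1.25)
  expect_equal(s$conversion, 1)  # fixtures book pool = consumed

  b$chains <- list()
  expect_error(batch_summary(b), "empty")
})
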