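test_that("binarization applies the HLB threshold per position", {
  sys <- default_system()
  ch <- match(c("MMA", "OEGMA", "EHMA", "SPMA"), sys$symbols)
  expect_equal(as.character(binarize_chain(ch, sys)),
               c("phobic", "philic", "phobic", "philic"))
  expect_equal(unique(as.character(binarize_chain(rep(1, 10), sys))),
               "phobic")
  # alternate threshold 6 splits MMA (8.45) from EHMA (5.12)
  labs <- binarize_chain(match(c("MMA", "EHMA"), sys$symbols), sys,
                         threshold = 6)
  expect_equal(as.character(labs), c("philic", "phobic"))
  expect_error(binarize_chain(c(1, 99), sys), "outside the system")
})

test_that("run extraction returns maximal runs in order", {
  r <- run_segments(c("phobic", "phobic", "philic",
                      "phobic", "phobic", "phobic"))
  expect_equal(r$phobic, c(2L, 3L))
  expect_equal(r$philic, 1L)
  expect_equal(run_segments(rep("phobic", 7))$phobic, 7L)
  expect_equal(run_segments(rep(c("phobic", "philic"), 3))$phobic,
               rep(1L, 3))
  expect_equal(run_segments(character())$phobic, integer())
})

test_that("run extraction agrees with a brute-force oracle", {
  set.seed(31)
  for (i in 1:1000) {
    labs <- sample(c("phobic", "philic"), sample(1:200, 1), replace = TRUE)
    expect_identical(run_segments(labs)[c("phobic", "philic")],
                     oracle_runs(labs))
  }
})

test_that("sequence- and batch-level distributions count runs correctly", {
  sys <- default_system()
  # chain 1 has phobic runs [1, 3]; chain 2 has [3]
  b <- generate_fixture("handcrafted", sys, sequences = list(
    c("MMA", "OEGMA", "MMA", "MMA", "MMA"),
    c("OEGMA", "MMA", "MMA", "MMA", "OEGMA")))
  seq_d <- sequence_level_distribution(b, "phobic")
  expect_equal(seq_d$length, c(1L, 3L))
  expect_equal(seq_d$value, c(0.5, 1.0))
  bat_d <- batch_level_distribution(b, "phobic")
  expect_equal(bat_d$value, c(1, 2))

  # single chain: distribution equals that chain's run histogram
  b1 <- generate_fixture("handcrafted", sys,
                         sequences = list(c("MMA", "OEGMA", "MMA")))
  d1 <- sequence_level_distribution(b1, "phobic")
  expect_equal(d1$length, 1L)
  expect_equal(d1$value, 2)

  # batch level = sequence level * NC elementwise
  b2 <- generate_fixture("bernoulli", sys, nc = 50, length = 60, seed = 8)
  s2 <- segment_distribution(b2, "philic", "sequence")
  t2 <- segment_distribution(b2, "philic", "batch")
  expect_equal(t2$value, s2$value * 50)

  # class with no runs present -> empty distribution
  b3 <- generate_fixture("handcrafted", sys,
                         sequences = list(rep("MMA", 5)))
  expect_equal(nrow(sequence_level_distribution(b3, "philic")), 0)
})

test_that("segment lengths conserve the batch's total monomer count", {
  b <- default_batch()
  ph <- segment_distribution(b, "phobic", "batch")
  pl <- segment_distribution(b, "philic", "batch")
  expect_equal(sum(ph$length * ph$value) + sum(pl$length * pl$value),
               sum(lengths(b$chains)))
})

test_that("phobic run lengths are geometric for i.i.d. draws", {
  sys <- monomer_system(c("MMA", "OEGMA"), feed = c(0.7, 0.3))
  b <- generate_fixture("bernoulli", sys, nc = 1500, length = 100,
                        seed = 33)
  # interior runs only: the first and last run of a chain are censored by
  # the chain ends and are not geometric
  interior <- unlist(lapply(b$chains, function(ch) {
    labs <- as.character(binarize_chain(ch, sys))
    r <- rle(labs)
    n <- length(r$lengths)
    if (n <= 2) return(integer())
    keep <- 2:(n - 1)
    r$lengths[keep][r$values[keep] == "phobic"]
  }))
  expect_gt(length(interior), 1e4)
  kmax <- 12
  binned <- factor(pmin(interior, kmax + 1), levels = 1:(kmax + 1))
  p <- 0.7
  probs <- c(p^(0:(kmax - 1)) * (1 - p), p^kmax)
  gof <- chisq.test(table(binned), p = probs)
  expect_gt(gof$p.value, 0.001)
})

test_that("the embedded-marker motif rule matches its worked cases", {
  sys <- default_system()
  b <- generate_fixture("handcrafted", sys, sequences = list(
    c("MMA", "MMA", "OEGMA", "MMA", "MMA"),           # match, length 5
    c("MMA", "OEGMA", "MMA", "MMA"),                  # marker 1 from end
    c("MMA", "MMA", "OEGMA", "OEGMA", "MMA", "MMA"))) # two markers
  res <- find_specific_segments(b, marker = "OEGMA", end_gap = 2)
  expect_equal(nrow(res$matches), 1)
  expect_equal(res$matches$chain, 1)
  expect_equal(res$matches$length, 5L)
  expect_equal(res$matches$start, 0L)
  expect_equal(res$matches$end, 5L)          # 0-based half-open
  expect_equal(res$distribution$value, 1 / 3)
  expect_equal(res$batch_distribution$value, 1)

  expect_error(find_specific_segments(b, marker = "XXX"), "not in system")
})

test_that("motif matches live inside single phobic-or-marker runs and never overlap", {
  sys <- default_system()
  b <- generate_fixture("bernoulli", sys, nc = 300, length = 100, seed = 12)
  res <- find_specific_segments(b)
  mi <- match("OEGMA", sys$symbols)
  phobic <- classify_monomer(sys$hlb, sys$hlb_threshold) == "phobic"
  for (r in seq_len(nrow(res$matches))) {
    m <- res$matches[r, ]
    ch <- b$chains[[m$chain]]
    span <- ch[(m$start + 1):m$end]
    expect_true(all(phobic[span] | span == mi))
    expect_equal(sum(span == mi), 1)
    # maximality: flanking positions (if any) are outside the alphabet
    if (m$start > 0) {
      left <- ch[m$start]
      expect_false(phobic[left] || left == mi)
    }
    if (m$end < length(ch)) {
      right <- ch[m$end + 1]
      expect_false(phobic[right] || right == mi)
    }
  }
  # non-overlap within each chain
  by_chain <- split(res$matches, res$matches$chain)
  for (mm in by_chain) {
    mm <- mm[order(mm$start), ]
    if (nrow(mm) > 1)
      expect_true(all(mm$start[-1] >= mm$end[-nrow(mm)]))
  }
})
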