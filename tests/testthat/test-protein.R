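test_that("FASTA records are parsed in order and uppercased", {
  path <- write_temp_fasta(c(one = "mkLv", two = "AAAA"))
  seqs <- read_fasta(path)
  expect_equal(names(seqs), c("one", "two"))
  expect_equal(unname(seqs[1]), "MKLV")

  long <- synthetic_protein(320)
  p2 <- write_temp_fasta(c(prot = long))
  expect_equal(nchar(read_fasta(p2)[["prot"]]), 320)

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("translation is a length-preserving residue substitution", {
  sys <- default_system()
  map <- default_residue_map(sys)
  expect_equal(sort(names(map)), sort(c("A", "R", "N", "D", "C", "Q", "E",
                                        "G", "H", "I", "L", "K", "M", "F",
                                        "P", "S", "T", "W", "Y", "V")))
  # charged residue -> SPMA-class monomer
  expect_equal(sys$symbols[translate_protein("K", map, sys)], "SPMA")
  expect_equal(classify_monomer(sys$hlb[translate_protein("K", map, sys)],
                                sys$hlb_threshold), "philic")

  res <- synthetic_protein(137, seed = 2)
  expect_length(translate_protein(res, map, sys), 137)

  expect_error(translate_protein("MKXLV", map, sys), "position 3")
  # five-monomer system routes aromatics to STY
  sys5 <- monomer_system(c("MMA", "OEGMA", "EHMA", "SPMA", "STY"),
                         feed = c(0.43, 0.25, 0.14, 0.05, 0.13))
  map5 <- default_residue_map(sys5)
  expect_equal(sys5$symbols[translate_protein("W", map5, sys5)], "STY")
})

test_that("segmentation produces full-length overlapping segments", {
  sys <- default_system()
  chain <- translate_protein(synthetic_protein(320), system = sys)
  b <- segment_protein(chain, sys, segment_length = 100, offset = 10)
  expect_equal(length(b$chains), 23)            # floor(220/10) + 1
  expect_true(all(lengths(b$chains) == 100))
  expect_equal(unique(diff(b$segment_starts)), 10L)
  expect_true(b$protein_derived)
  expect_null(b$initial_pool)

  b1 <- segment_protein(chain[1:100], sys)
  expect_equal(length(b1$chains), 1)
  expect_error(segment_protein(chain[1:99], sys), "too short")
})

test_that("translation and segmentation commute", {
  sys <- default_system()
  map <- default_residue_map(sys)
  res <- synthetic_protein(180, seed = 3)
  chars <- strsplit(res, "")[[1]]

  translated_then_segmented <-
    segment_protein(translate_protein(res, map, sys), sys, 100, 10)$chains

  starts <- seq(1, 180 - 100 + 1, by = 10)
  segmented_then_translated <- lapply(starts, function(s)
    translate_protein(paste(chars[s:(s + 99)], collapse = ""), map, sys))

  expect_identical(translated_then_segmented, segmented_then_translated)
})

test_that("poly-leucine becomes an all-hydrophobic batch", {
  sys <- default_system()
  chain <- translate_protein(strrep("L", 150), system = sys)
  b <- segment_protein(chain, sys)
  d <- sequence_level_distribution(b, "phobic")
  expect_equal(d$length, 100L)
  expect_equal(d$value, 1)
  expect_equal(nrow(sequence_level_distribution(b, "philic")), 0)
})

test_that("the full analysis stack runs on a protein-derived batch", {
  sys <- default_system()
  chain <- translate_protein(synthetic_protein(400, seed = 4), system = sys)
  b <- segment_protein(chain, sys)

  prof <- nfwhm_profile(b)
  expect_true(all(prof$nfwhm >= 0))
  d <- segment_distribution(b, "phobic", "batch")
  expect_gt(nrow(d), 0)
  st <- batch_position_stats(b, 9)
  expect_equal(st$per_position$n[1], length(b$chains))
  m <- find_specific_segments(b)
  expect_true(is.data.frame(m$matches))
  s <- batch_summary(b)
  expect_equal(s$dp_n, 100)
  expect_true(is.na(s$conversion))
})
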