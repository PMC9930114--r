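# Shared fixtures. Expensive batches are memoized so test files can reuse
# them within one run without re-simulating.

.batch_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.batch_cache[[key]])) assign(key, fn(), envir = .batch_cache)
  get(key, envir = .batch_cache)
}

# the reference batch: 4-monomer methacrylate system at Fig-1 feed,
# NC 15000, DP 100, 50% conversion, package-default dispersity
default_batch <- function() {
  cached("b15k", function()
    simulate_batch(default_system(), nc = 15000, dp_target = 100,
                   conversion = 0.5, pdi_target = 1.15, seed = 42))
}

# same conditions but monodisperse targets (every chain exactly DP 100),
# for oracles that assume a fixed chain length
monodisperse_batch <- function() {
  cached("b15k_mono", function()
    simulate_batch(default_system(), nc = 15000, dp_target = 100,
                   conversion = 0.5, pdi_target = 1, seed = 43))
}

# brute-force run-length oracle: position-by-position scan
oracle_runs <- function(labels) {
  out <- list(phobic = integer(), philic = integer())
  if (!length(labels)) return(out)
  start <- 1L
  for (i in seq_along(labels)) {
    end_of_run <- i == length(labels) || labels[i + 1] != labels[i]
    if (end_of_run) {
      cls <- labels[i]
      out[[cls]] <- c(out[[cls]], i - start + 1L)
      start <- i + 1L
    }
  }
  out
}

# deterministic synthetic protein sequence (standard 20-letter alphabet)
synthetic_protein <- function(n = 320, seed = 7) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
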