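#' Generate a deterministic test batch
#'
#' Seeded fixture generator used by the test suite and available to users
#' for controlled experiments. Three kinds:
#' \describe{
#'   \item{`bernoulli`}{i.i.d. monomer draws at fixed probabilities `p`
#'     (chain length `length`, `nc` chains). The run-length law is then
#'     analytically geometric, which makes this the oracle batch for
#'     segment statistics.}
#'   \item{`fixed_lengths`}{chains of a specified length multiset, monomers
#'     drawn i.i.d. from the system feed.}
#'   \item{`handcrafted`}{literal sequences given as character vectors of
#'     monomer symbols.}
#' }
#' Fixture batches set `initial_pool = consumed`, i.e. nominal full
#' conversion, so pool invariants hold trivially.
#'
#' @param kind one of `"bernoulli"`, `"fixed_lengths"`, `"handcrafted"`.
#' @param system a [monomer_system()].
#' @param nc number of chains (bernoulli).
#' @param length chain length (bernoulli).
#' @param p per-monomer draw probabilities, summing to 1 (bernoulli;
#'   defaults to the system feed).
#' @param lengths integer vector of chain lengths (fixed_lengths).
#' @param sequences list of character vectors of monomer symbols
#'   (handcrafted).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An `rhp_batch`.
#' @examples
#' b <- generate_fixture("bernoulli", default_system(), nc = 10,
#'                       length = 50, seed = 1)
#' @export
generate_fixture <- function(kind = c("bernoulli", "fixed_lengths",
                                      "handcrafted"),
                             system = default_system(), nc = 100,
                             length = 100, p = NULL, lengths = NULL,
                             sequences = NULL, seed = NULL) {
  kind <- match.arg(kind)
  system <- validate_system(system)
  if (!is.null(seed)) set.seed(seed)
  k <- base::length(system$symbols)

  chains <- switch(kind,
    bernoulli = {
      if (is.null(p)) p <- system$feed
      if (base::length(p) != k) stop("`p` must have one entry per monomer")
      if (abs(sum(p) - 1) > 1e-9) stop("`p` must sum to 1")
      lapply(seq_len(nc), function(i)
        sample.int(k, length, replace = TRUE, prob = p))
    },
    fixed_lengths = {
      if (is.null(lengths)) stop("`lengths` required for fixed_lengths")
      lapply(lengths, function(L)
        sample.int(k, L, replace = TRUE, prob = system$feed))
    },
    handcrafted = {
      if (is.null(sequences)) stop("`sequences` required for handcrafted")
      lapply(sequences, function(s) {
        idx <- match(s, system$symbols)
        if (anyNA(idx))
          stop("unknown symbol(s): ",
               paste(unique(s[is.na(idx)]), collapse = ", "))
        idx
      })
    })

  counts <- tabulate(unlist(chains, use.names = FALSE), nbins = k)
  structure(list(
    chains = chains,
    system = system,
    config = list(fixture = kind, seed = seed),
    initial_pool = setNames(as.numeric(counts), system$symbols),
    consumed = setNames(as.numeric(counts), system$symbols),
    protein_derived = FALSE
  ), class = "rhp_batch")
}
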