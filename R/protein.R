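#' Read protein sequences from a FASTA file
#'
#' Standard FASTA parsing (via Biostrings); residues are uppercased and
#' records returned in file order.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return Named character vector: names are record ids (first token of the
#'   header), values the uppercase residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(aa))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  if (any(!nzchar(seqs))) stop("empty FASTA record in ", path)
  setNames(seqs, ids)
}

#' Default residue-to-monomer map
#'
#' Maps the 20 standard amino acids onto the monomers of the active system
#' by hydrophobicity/hydrophilicity/charge class: strongly hydrophobic
#' residues (V, L, I, M, F, W) to EHMA; small/weakly hydrophobic residues
#' (A, G, P, C) to MMA; polar uncharged residues (S, T, N, Q, Y, H) to
#' OEGMA; charged residues (D, E, K, R) to SPMA. When the system contains
#' STY, the aromatic residues F, W and Y map there instead. This grouping is
#' a configurable default, not ground truth: any full 20-residue map onto
#' the system's symbols can be passed to [translate_protein()].
#'
#' @param system a [monomer_system()] containing at least MMA, OEGMA, EHMA
#'   and SPMA.
#' @return Named character vector: names are one-letter residue codes,
#'   values monomer symbols.
#' @export
default_residue_map <- function(system = default_system()) {
  map <- c(V = "EHMA", L = "EHMA", I = "EHMA", M = "EHMA",
           F = "EHMA", W = "EHMA",
           A = "MMA", G = "MMA", P = "MMA", C = "MMA",
           S = "OEGMA", T = "OEGMA", N = "OEGMA", Q = "OEGMA",
           Y = "OEGMA", H = "OEGMA",
           D = "SPMA", E = "SPMA", K = "SPMA", R = "SPMA")
  if ("STY" %in% system$symbols)
    map[c("F", "W", "Y")] <- "STY"
  missing <- setdiff(unique(map), system$symbols)
  if (length(missing))
    stop("system lacks monomer(s) required by the default map: ",
         paste(missing, collapse = ", "))
  map
}

#' Translate a protein sequence into monomer space
#'
#' Length-preserving substitution of each residue by its mapped monomer — a
#' dimensionality reduction from the 20-letter amino-acid alphabet to the
#' 2-5 synthetic monomers of the system. Non-standard residues (X, B, Z, *,
#' gaps) are errors, reported with their position.
#'
#' @param residues a single residue string or character vector of one-letter
#'   codes.
#' @param map named character vector from residues to monomer symbols (see
#'   [default_residue_map()]).
#' @param system a [monomer_system()] containing every mapped symbol.
#' @return Integer chain (monomer indices into the system).
#' @export
translate_protein <- function(residues, map = default_residue_map(system),
                              system = default_system()) {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- which(!residues %in% names(map))
  if (length(bad))
    stop("unmapped residue '", residues[bad[1]], "' at position ", bad[1],
         if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)"))
  symbols <- unname(map[residues])
  idx <- match(symbols, system$symbols)
  if (anyNA(idx))
    stop("map targets monomer(s) absent from the system: ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  idx
}

#' Segment a translated protein chain into a batch
#'
#' Splits a monomer-space chain into overlapping fixed-length segments
#' starting at positions 0, `offset`, `2 * offset`, ... (the defaults,
#' length 100 and offset 10, make segments directly comparable to simulated
#' RHPs of DP 100). Trailing residues not covered by a final full segment
#' are dropped. The result is packaged as a protein-derived `rhp_batch` with
#' no pool metadata; its system's feed fractions are set to the realized
#' composition of the full-length chain so that feed-normalized metrics
#' remain well defined.
#'
#' @param chain integer monomer-index chain (see [translate_protein()]).
#' @param system the [monomer_system()] the chain indexes into.
#' @param segment_length segment length in monomers (default 100).
#' @param offset spacing between segment start positions (default 10).
#' @return A protein-derived `rhp_batch` of
#'   `floor((L - segment_length) / offset) + 1` chains.
#' @export
segment_protein <- function(chain, system = default_system(),
                            segment_length = 100, offset = 10) {
  if (segment_length < 1) stop("`segment_length` must be >= 1")
  if (offset < 1 || offset > segment_length)
    stop("`offset` must be in [1, segment_length]")
  L <- length(chain)
  if (L < segment_length)
    stop("chain too short (", L, ") for segment length ", segment_length)
  starts <- seq(1L, L - segment_length + 1L, by = offset)
  chains <- lapply(starts, function(s) chain[s:(s + segment_length - 1L)])
  k <- length(system$symbols)
  comp <- tabulate(chain, nbins = k)
  sys <- system
  sys$feed <- comp / sum(comp)
  counts <- tabulate(unlist(chains, use.names = FALSE), nbins = k)
  structure(list(
    chains = chains,
    system = sys,
    config = list(nc = length(chains), segment_length = segment_length,
                  offset = offset, source_length = L),
    initial_pool = NULL,
    consumed = setNames(as.numeric(counts), sys$symbols),
    segment_starts = starts - 1L,
    protein_derived = TRUE
  ), class = "rhp_batch")
}
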