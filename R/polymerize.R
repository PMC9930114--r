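#' Mayo-Lewis propagation probabilities
#'
#' Probability that a radical whose terminal unit is monomer `i` adds each
#' monomer `j` next, under the terminal model:
#' `p(j | i) = (x_j / r[i, j]) / sum_k (x_k / r[i, k])`, where `x_j` is the
#' current pool mole fraction and `r[i, j] = k_ii / k_ij` the reactivity
#' ratio. With a bare chain (no terminal unit, `terminal = NA`) the draw is
#' from the raw pool fractions.
#'
#' @param terminal index (or symbol) of the chain's terminal monomer, or `NA`
#'   for the first unit of a chain.
#' @param pool numeric vector of per-monomer unit counts (or fractions) in
#'   the unreacted pool.
#' @param system a [monomer_system()].
#' @return Named numeric probability vector over the system's monomers.
#' @examples
#' sys <- default_system()
#' propagation_probs(NA, c(0.5, 0.25, 0.20, 0.05), sys)
#' @export
propagation_probs <- function(terminal, pool, system) {
  system <- validate_system(system)
  k <- length(system$symbols)
  if (length(pool) != k) stop("`pool` must have one count per monomer")
  if (any(pool < 0)) stop("pool counts must be non-negative")
  if (sum(pool) <= 0) stop("pool is depleted: no units left to propagate")
  if (is.character(terminal)) terminal <- monomer_index(system, terminal)
  x <- pool / sum(pool)
  w <- if (is.na(terminal)) x else {
    if (terminal < 1 || terminal > k) stop("invalid terminal monomer index")
    x / system$reactivity[terminal, ]
  }
  setNames(w / sum(w), system$symbols)
}

#' Sample per-chain target lengths from a Schulz-Zimm distribution
#'
#' Draws `nc` integer chain lengths whose mean approximates `dp_target` and
#' whose polydispersity index (weight- over number-average length, equal
#' monomer masses assumed) approximates `pdi_target`. Lengths are sampled
#' from the Schulz-Zimm (gamma) distribution with shape `1 / (pdi_target -
#' 1)` — the standard chain-length distribution for controlled radical
#' polymerization — rounded to integers and floored at 1. With
#' `pdi_target = 1` every length equals `dp_target` exactly.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param nc number of chains.
#' @param dp_target target number-average degree of polymerization.
#' @param pdi_target target polydispersity index, `>= 1`.
#' @return Integer vector of `nc` lengths, each `>= 1`.
#' @export
sample_chain_lengths <- function(nc, dp_target, pdi_target) {
  if (nc < 1) stop("`nc` must be at least 1")
  if (dp_target < 1) stop("`dp_target` must be at least 1")
  if (!is.finite(pdi_target) || pdi_target < 1)
    stop("`pdi_target` must be >= 1")
  if (pdi_target == 1) return(rep(as.integer(round(dp_target)), nc))
  shape <- 1 / (pdi_target - 1)
  len <- rgamma(nc, shape = shape, rate = shape / dp_target)
  pmax(1L, as.integer(round(len)))
}

#' Simulate a batch of RHP chains
#'
#' Monte Carlo simulation of RDRP copolymerization under the multicomponent
#' Mayo-Lewis terminal model. The initial monomer pool is sized so that the
#' target conversion consumes `nc * dp_target` units
#' (`pool = round(nc * dp_target / conversion)`, split by feed fractions).
#' All `nc` chains grow concurrently: each propagation step picks a living
#' chain uniformly at random and appends one monomer drawn from
#' [propagation_probs()] against the current, depleting pool. Chains retire
#' on reaching their pre-sampled Schulz-Zimm target length; the run stops
#' once the consumed fraction of the pool reaches `conversion` (within one
#' monomer addition) or no living chain remains.
#'
#' Target lengths are topped up by unit increments on randomly chosen chains
#' when their sampled sum falls short of the conversion requirement, so the
#' conversion target is always reachable; the per-chain perturbation is
#' O(1/sqrt(nc)) and immaterial at batch scale.
#'
#' @param system a [monomer_system()].
#' @param nc number of chains (NC), the Monte Carlo sample size.
#' @param dp_target target number-average degree of polymerization.
#' @param conversion target fraction of the pool consumed, in (0, 1].
#' @param pdi_target target polydispersity index (default 1.15, keeping
#'   dispersity below 1.2 as realized in well-controlled RDRP).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `rhp_batch`: list with `chains` (integer
#'   monomer-index vectors, alpha end first), `system`, `config`,
#'   `initial_pool`, `consumed` (named unit counts) and `pool_trajectory`
#'   (pool mole fractions at 50 even consumption checkpoints).
#' @examples
#' b <- simulate_batch(default_system(), nc = 50, dp_target = 30, seed = 1)
#' batch_summary(b)
#' @export
simulate_batch <- function(system, nc, dp_target = 100, conversion = 0.5,
                           pdi_target = 1.15, seed = NULL) {
  system <- validate_system(system)
  if (nc < 1) stop("`nc` must be at least 1")
  if (dp_target < 1) stop("`dp_target` must be at least 1")
  if (conversion <= 0 || conversion > 1)
    stop("`conversion` must be in (0, 1]")
  if (pdi_target < 1) stop("`pdi_target` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  pool_total <- round(nc * dp_target / conversion)
  pool <- apportion_counts(system$feed, pool_total)
  if (any(pool == 0 & system$feed > 0))
    stop("pool rounding left zero units for a monomer with nonzero feed; ",
         "increase nc or dp_target")
  needed <- round(conversion * pool_total)

  targets <- sample_chain_lengths(nc, dp_target, pdi_target)
  deficit <- needed - sum(targets)
  if (deficit > 0)
    targets <- targets + tabulate(sample.int(nc, deficit, replace = TRUE), nc)

  res <- cpp_simulate_batch(as.numeric(pool), system$reactivity,
                            as.integer(targets), needed, 50L)
  chains <- res$chains[lengths(res$chains) > 0]

  structure(list(
    chains = chains,
    system = system,
    config = list(nc = nc, dp_target = dp_target, conversion = conversion,
                  pdi_target = pdi_target, seed = seed),
    initial_pool = setNames(as.numeric(pool), system$symbols),
    consumed = setNames(res$consumed, system$symbols),
    pool_trajectory = res$pool_trajectory,
    protein_derived = FALSE
  ), class = "rhp_batch")
}

# integer apportionment by largest remainder: counts sum to `total` exactly
apportion_counts <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  short <- round(total - sum(base))
  if (short > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  base
}

#' Remove oligomers from a batch
#'
#' Drops every chain shorter than `min_dp` monomers, mirroring the
#' experimental purification step that removes oligomers from a synthesized
#' RHP batch. Pool accounting is preserved; the removed chain and unit counts
#' are recorded in the batch's `filtered` field.
#'
#' @param batch an `rhp_batch`.
#' @param min_dp minimum retained degree of polymerization (default 15).
#' @return The filtered `rhp_batch` (possibly with zero chains, with a
#'   warning).
#' @export
filter_oligomers <- function(batch, min_dp = 15) {
  stopifnot(inherits(batch, "rhp_batch"))
  keep <- lengths(batch$chains) >= min_dp
  removed <- batch$chains[!keep]
  k <- length(batch$system$symbols)
  removed_units <- setNames(
    as.numeric(tabulate(as.integer(unlist(removed, use.names = FALSE)),
                        nbins = k)),
    batch$system$symbols)
  batch$chains <- batch$chains[keep]
  batch$filtered <- list(min_dp = min_dp, chains_removed = sum(!keep),
                         units_removed = removed_units)
  if (!length(batch$chains))
    warning("all chains shorter than min_dp = ", min_dp,
            "; batch is now empty")
  batch
}

#' Summarize a batch
#'
#' Computes the batch-level quantities that NMR/GPC would report for a real
#' synthesis: number-average length `DP_n` (mean chain length),
#' weight-average `DP_w = sum(l^2) / sum(l)` (equal monomer masses assumed),
#' polydispersity `PDI = DP_w / DP_n`, realized conversion (consumed over
#' initial pool units; `NA` for protein-derived batches, which have no pool)
#' and per-monomer incorporated fractions.
#'
#' @param batch a nonempty `rhp_batch`.
#' @return A list with `nc`, `dp_n`, `dp_w`, `pdi`, `conversion` and
#'   `incorporated` (named fractions).
#' @export
batch_summary <- function(batch) {
  stopifnot(inherits(batch, "rhp_batch"))
  if (!length(batch$chains)) stop("cannot summarize an empty batch")
  len <- lengths(batch$chains)
  dp_n <- mean(len)
  dp_w <- sum(len^2) / sum(len)
  counts <- tabulate(unlist(batch$chains, use.names = FALSE),
                     nbins = length(batch$system$symbols))
  conv <- if (is.null(batch$initial_pool)) NA_real_ else
    sum(batch$consumed) / sum(batch$initial_pool)
  list(nc = length(batch$chains), dp_n = dp_n, dp_w = dp_w,
       pdi = dp_w / dp_n, conversion = conv,
       incorporated = setNames(counts / sum(counts), batch$system$symbols))
}

#' @export
print.rhp_batch <- function(x, ...) {
  cat("RHP batch: ", length(x$chains), " chains over {",
      paste(x$system$symbols, collapse = ", "), "}",
      if (isTRUE(x$protein_derived)) " (protein-derived)", "\n", sep = "")
  if (length(x$chains)) {
    s <- batch_summary(x)
    cat(sprintf("  DP_n %.2f  DP_w %.2f  PDI %.4f  conversion %s\n",
                s$dp_n, s$dp_w, s$pdi,
                ifelse(is.na(s$conversion), "NA",
                       sprintf("%.4f", s$conversion))))
  }
  invisible(x)
}

# symbols of one chain (integer indices -> character), used by IO and tests
chain_symbols <- function(chain, system) system$symbols[chain]
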