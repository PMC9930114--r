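#' Group-contribution HLB of a side chain
#'
#' Computes the hydrophile-lipophile balance of a monomer side chain from a
#' functional-group decomposition, `HLB = 7 + sum(n_i * HLB_i)`, where `n_i`
#' is the number of occurrences of the i-th chemical group and `HLB_i` its
#' tabulated group value. Lower HLB means more hydrophobic.
#'
#' @param counts integer vector of group occurrence counts (`n_i`); may be
#'   empty, in which case the base constant 7 is returned.
#' @param values numeric vector of group contribution values (`HLB_i`), same
#'   length as `counts`.
#' @return A single numeric HLB value.
#' @examples
#' hlb_side_chain()                      # 7, the base constant
#' hlb_side_chain(1, 1.45)               # 8.45
#' hlb_side_chain(c(2, 1), c(1, -0.5))   # 8.5
#' @export
hlb_side_chain <- function(counts = numeric(), values = numeric()) {
  counts <- as.numeric(counts)
  values <- as.numeric(values)
  if (length(counts) != length(values))
    stop("`counts` and `values` must have the same length")
  if (any(counts < 0))
    stop("group counts must be non-negative")
  if (length(values) && any(!is.finite(values)))
    stop("group HLB values must be finite")
  7 + sum(counts * values)
}

#' Built-in monomer registry
#'
#' The five methacrylate-system monomers used throughout, with their HLB
#' values: methyl methacrylate (MMA, 8.45), oligo(ethylene glycol)
#' methacrylate Mn 500 (OEGMA, 11.4), 2-ethylhexyl methacrylate (EHMA, 5.12),
#' 3-sulfopropyl methacrylate potassium salt (SPMA, 18.5) and styrene
#' (STY, 4.865). Molecular weights (g/mol) and densities (g/mL) are standard
#' literature values used only by the recipe solver; SPMA is a solid, so its
#' density is `NA` and no liquid volume is reported for it.
#'
#' @param symbols optional character vector selecting (and ordering) a subset
#'   of the registry.
#' @return A data.frame with columns `symbol`, `hlb`, `molecular_weight`,
#'   `density`.
#' @export
default_monomers <- function(symbols = NULL) {
  reg <- data.frame(
    symbol = c("MMA", "OEGMA", "EHMA", "SPMA", "STY"),
    hlb = c(8.45, 11.4, 5.12, 18.5, 4.865),
    molecular_weight = c(100.12, 500, 198.30, 246.32, 104.15),
    density = c(0.94, 1.08, 0.885, NA, 0.906),
    stringsAsFactors = FALSE
  )
  if (is.null(symbols)) return(reg)
  miss <- setdiff(symbols, reg$symbol)
  if (length(miss))
    stop("unknown monomer symbol(s): ", paste(miss, collapse = ", "))
  reg[match(symbols, reg$symbol), , drop = FALSE]
}

#' Classify a monomer as hydrophobic or hydrophilic
#'
#' A monomer is hydrophobic when its HLB value is strictly below the
#' threshold, hydrophilic otherwise; an HLB exactly equal to the threshold
#' classifies hydrophilic, giving a single consistent boundary rule.
#'
#' @param m a numeric HLB value (vectorized) or a one-row data.frame with an
#'   `hlb` column.
#' @param threshold hydrophilic-hydrophobic HLB cutoff (default 9).
#' @return Character vector with values `"phobic"` or `"philic"`.
#' @examples
#' classify_monomer(8.45)   # MMA -> "phobic"
#' classify_monomer(18.5)   # SPMA -> "philic"
#' classify_monomer(9)      # boundary -> "philic"
#' @export
classify_monomer <- function(m, threshold = 9) {
  if (is.data.frame(m)) m <- m$hlb
  if (!is.numeric(m)) stop("`m` must be numeric HLB or have an `hlb` column")
  if (!is.finite(threshold) && !threshold %in% c(Inf, -Inf))
    stop("`threshold` must not be NA")
  ifelse(m < threshold, "phobic", "philic")
}

#' Define a monomer system
#'
#' A monomer system is the chemistry universe of a simulation run: an ordered
#' list of monomers with HLB values, their feed mole fractions, the
#' reactivity-ratio matrix `r[i, j] = k_ii / k_ij` of the Mayo-Lewis terminal
#' model, and the HLB classification threshold. With all reactivity ratios
#' equal to 1 the propagation statistics are ideal (Bernoulli in the current
#' pool fractions).
#'
#' @param monomers either a character vector of registry symbols (see
#'   [default_monomers()]) or a data.frame with at least `symbol` and `hlb`
#'   columns (optionally `molecular_weight`, `density`).
#' @param feed numeric vector of feed mole fractions, one per monomer,
#'   summing to 1.
#' @param reactivity square numeric matrix of reactivity ratios, unit
#'   diagonal; `NULL` (default) means all ones, i.e. ideal random
#'   copolymerization.
#' @param hlb_threshold hydrophobic/hydrophilic HLB cutoff (default 9).
#' @return A validated object of class `monomer_system`.
#' @examples
#' sys <- monomer_system(c("MMA", "OEGMA", "EHMA", "SPMA"),
#'                       feed = c(0.50, 0.25, 0.20, 0.05))
#' @export
monomer_system <- function(monomers, feed, reactivity = NULL,
                           hlb_threshold = 9) {
  if (is.character(monomers)) monomers <- default_monomers(monomers)
  if (!is.data.frame(monomers) || !all(c("symbol", "hlb") %in% names(monomers)))
    stop("`monomers` must be symbols or a data.frame with `symbol` and `hlb`")
  k <- nrow(monomers)
  if (is.null(monomers$molecular_weight)) monomers$molecular_weight <- NA_real_
  if (is.null(monomers$density)) monomers$density <- NA_real_
  if (is.null(reactivity)) reactivity <- matrix(1, k, k)
  sys <- structure(list(
    symbols = as.character(monomers$symbol),
    hlb = as.numeric(monomers$hlb),
    molecular_weight = as.numeric(monomers$molecular_weight),
    density = as.numeric(monomers$density),
    feed = as.numeric(feed),
    reactivity = reactivity,
    hlb_threshold = hlb_threshold
  ), class = "monomer_system")
  validate_system(sys)
}

#' Validate a monomer system
#'
#' Checks every structural invariant of a [monomer_system()]: unique nonempty
#' symbols, finite HLB values, non-negative feed fractions summing to 1
#' (within 1e-9), a square positive reactivity-ratio matrix with unit
#' diagonal, and positive molecular weights where present.
#'
#' @param sys a `monomer_system`.
#' @return The system, unchanged, when valid; otherwise an error.
#' @export
validate_system <- function(sys) {
  if (!inherits(sys, "monomer_system")) stop("not a monomer_system")
  k <- length(sys$symbols)
  if (k < 1) stop("system must contain at least one monomer")
  if (any(!nzchar(sys$symbols)) || anyDuplicated(sys$symbols))
    stop("monomer symbols must be nonempty and unique")
  if (any(!is.finite(sys$hlb)))
    stop("all monomer HLB values must be finite")
  mw <- sys$molecular_weight
  if (any(!is.na(mw) & mw <= 0))
    stop("molecular weights must be positive")
  if (length(sys$feed) != k)
    stop("feed fractions: expected ", k, " values, got ", length(sys$feed))
  if (any(sys$feed < 0))
    stop("feed fractions must be non-negative")
  if (abs(sum(sys$feed) - 1) > 1e-9)
    stop("feed fractions must sum to 1 (got ", format(sum(sys$feed)), ")")
  rr <- sys$reactivity
  if (!is.matrix(rr) || nrow(rr) != k || ncol(rr) != k)
    stop("reactivity-ratio matrix must be ", k, "x", k)
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("all reactivity ratios must be positive and finite")
  if (any(abs(diag(rr) - 1) > 1e-12))
    stop("reactivity-ratio matrix must have unit diagonal (r_ii = 1)")
  if (!is.finite(sys$hlb_threshold)) stop("hlb_threshold must be finite")
  sys
}

#' Default four-monomer methacrylate system
#'
#' Convenience constructor for the reference system: 50% MMA, 25% OEGMA,
#' 20% EHMA, 5% SPMA, ideal reactivity ratios (all 1), HLB threshold 9.
#'
#' @param feed feed mole fractions over (MMA, OEGMA, EHMA, SPMA).
#' @param reactivity reactivity-ratio matrix; `NULL` = all ones.
#' @param hlb_threshold HLB cutoff (default 9).
#' @return A `monomer_system`.
#' @export
default_system <- function(feed = c(0.50, 0.25, 0.20, 0.05),
                           reactivity = NULL, hlb_threshold = 9) {
  monomer_system(c("MMA", "OEGMA", "EHMA", "SPMA"), feed = feed,
                 reactivity = reactivity, hlb_threshold = hlb_threshold)
}

#' @export
print.monomer_system <- function(x, ...) {
  cat("Monomer system (", length(x$symbols), " monomers, HLB threshold ",
      x$hlb_threshold, ")\n", sep = "")
  cls <- classify_monomer(x$hlb, x$hlb_threshold)
  df <- data.frame(symbol = x$symbols, hlb = x$hlb, feed = x$feed,
                   class = cls)
  print(df, row.names = FALSE)
  if (!all(x$reactivity == 1)) {
    cat("reactivity ratios:\n")
    print(x$reactivity)
  } else cat("reactivity ratios: all 1 (ideal)\n")
  invisible(x)
}

# index of a symbol within a system, with a clear error
monomer_index <- function(sys, symbol) {
  i <- match(symbol, sys$symbols)
  if (is.na(i)) stop("monomer '", symbol, "' not in system")
  i
}
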