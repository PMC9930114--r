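#' Per-chain monomer compositions
#'
#' For each chain, the mole fraction of every monomer
#' (`count / chain length`). These per-chain compositions are the raw
#' material of the chemical-heterogeneity metric: their spread across a
#' batch measures how much individual chains deviate from the batch feed.
#'
#' @param batch a nonempty `rhp_batch`.
#' @return A data.frame with one row per chain and one column per monomer
#'   symbol; the batch feed fractions are attached as attribute `"feed"`.
#' @export
chain_compositions <- function(batch) {
  stopifnot(inherits(batch, "rhp_batch"))
  if (!length(batch$chains)) stop("cannot analyze an empty batch")
  k <- length(batch$system$symbols)
  m <- t(vapply(batch$chains,
                function(ch) tabulate(ch, nbins = k) / length(ch),
                numeric(k)))
  df <- as.data.frame(m)
  names(df) <- batch$system$symbols
  attr(df, "feed") <- setNames(batch$system$feed, batch$system$symbols)
  df
}

#' Kernel density estimate and full width at half-maximum
#'
#' Gaussian-kernel density of a sample of mole fractions on a fixed grid
#' over `[from, to]` (default the unit interval, 512 points), with the full
#' width at half-maximum of the tallest peak. Bandwidth is a Scott-type
#' rule of thumb, `1.06 * min(sd, IQR/1.349) * n^(-1/5)` (falling back on
#' the sd when the IQR is degenerate). The two half-maximum crossings
#' bracketing the global maximum are located by linear interpolation; a
#' crossing that runs off the domain edge is clipped to the edge, so minor
#' secondary peaks never contaminate the width.
#'
#' @param x numeric sample (at least two distinct values).
#' @param n_grid number of grid points (default 512).
#' @param from,to grid limits (defaults 0 and 1, the mole-fraction domain).
#' @return A list with `density` (data.frame `x`, `y`), `bw`, `peak` (the
#'   mode location) and `fwhm`.
#' @export
kde_fwhm <- function(x, n_grid = 512, from = 0, to = 1) {
  x <- as.numeric(x)
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate distribution: need at least two distinct sample values")
  sig <- sd(x)
  iqr <- IQR(x) / 1.349
  s <- if (iqr > 0) min(sig, iqr) else sig
  bw <- 1.06 * s * length(x)^(-1 / 5)
  d <- density(x, bw = bw, n = n_grid, from = from, to = to)
  imax <- which.max(d$y)
  half <- d$y[imax] / 2

  cross_left <- function() {
    below <- which(d$y[seq_len(imax)] <= half)
    if (!length(below)) return(d$x[1])              # clipped at domain edge
    i <- max(below)                                  # last point <= half
    x0 <- d$x[i]; x1 <- d$x[i + 1]
    y0 <- d$y[i]; y1 <- d$y[i + 1]
    x0 + (half - y0) / (y1 - y0) * (x1 - x0)
  }
  cross_right <- function() {
    below <- which(d$y[imax:n_grid] <= half)
    if (!length(below)) return(d$x[n_grid])
    i <- imax + min(below) - 1                       # first point <= half
    x0 <- d$x[i - 1]; x1 <- d$x[i]
    y0 <- d$y[i - 1]; y1 <- d$y[i]
    x0 + (half - y0) / (y1 - y0) * (x1 - x0)
  }
  left <- cross_left()
  right <- cross_right()
  list(density = data.frame(x = d$x, y = d$y), bw = bw,
       peak = d$x[imax], fwhm = right - left)
}

#' Feed-normalized FWHM profile of a batch
#'
#' The chemical-heterogeneity statistic: for every monomer, the FWHM of the
#' kernel density of its per-chain mole fractions, normalized by that
#' monomer's feed fraction (nFWHM). Normalization makes widths comparable
#' across monomers fed at very different levels; a low-feed monomer with the
#' same absolute spread is relatively far more heterogeneous.
#'
#' @param batch a nonempty `rhp_batch` whose present monomers all have
#'   nonzero feed fractions.
#' @return A data.frame with columns `symbol`, `feed`, `fwhm`, `nfwhm`, one
#'   row per monomer with nonzero feed.
#' @export
nfwhm_profile <- function(batch) {
  comp <- chain_compositions(batch)
  feed <- attr(comp, "feed")
  present <- colSums(comp) > 0
  if (any(present & feed == 0))
    stop("monomer(s) present in chains but with zero feed fraction: ",
         paste(names(feed)[present & feed == 0], collapse = ", "))
  use <- which(feed > 0)
  recs <- lapply(use, function(i) {
    fw <- kde_fwhm(comp[[i]])$fwhm
    data.frame(symbol = names(feed)[i], feed = feed[[i]], fwhm = fw,
               nfwhm = fw / feed[[i]])
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
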