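#' Sliding-window hydropathy profile of a chain
#'
#' Assigns to each interior position the mean HLB of the odd-sized window
#' centered on it, sliding one monomer at a time from the alpha to the omega
#' end. Positions without a full window (the first and last `(w - 1) / 2`)
#' are undefined, so the profile has `length(chain) - w + 1` values. Window
#' averaging trades monomer-level noise for coarse-grained segment
#' structure; sizes 5, 9 and 15 probe small, medium and large neighbor
#' contexts.
#'
#' @param chain integer vector of monomer indices.
#' @param system a [monomer_system()].
#' @param w odd window size, `1 <= w <= length(chain)`.
#' @return Object of class `hydropathy_profile`: numeric vector of
#'   window-averaged HLB values with attributes `positions` (1-based center
#'   positions in the chain) and `w`.
#' @export
window_profile <- function(chain, system, w) {
  if (w %% 2 != 1) stop("window size `w` must be odd")
  if (w < 1) stop("window size `w` must be >= 1")
  L <- length(chain)
  if (w > L) stop("chain too short for window size ", w,
                  " (length ", L, ")")
  hlb <- system$hlb[chain]
  half <- (w - 1) / 2
  cs <- cumsum(c(0, hlb))
  vals <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  structure(vals, positions = (half + 1):(L - half), w = w,
            class = "hydropathy_profile")
}

#' Segments of a window-averaged profile
#'
#' Re-applies the hydrophobic/hydrophilic segment definition to a hydropathy
#' profile: profile values strictly below the threshold are `"phobic"`,
#' values at or above it `"philic"`, and maximal runs are extracted with
#' [run_segments()]. This is the window-robust segment definition — less
#' sensitive to the exact HLB threshold than raw per-monomer binarization.
#'
#' @param profile a [window_profile()] (or any numeric vector of HLB-scale
#'   values).
#' @param threshold HLB cutoff (default 9).
#' @return Named list of run-length vectors per class.
#' @export
windowed_segments <- function(profile, threshold = 9) {
  if (!length(profile)) stop("profile is empty")
  run_segments(classify_monomer(as.numeric(profile), threshold))
}

#' Positionwise window-HLB statistics across a batch
#'
#' Computes, for every alpha-anchored center position, the mean, variance
#' and contributing-chain count of the window-averaged HLB over all chains
#' long enough to define that position, plus position-pooled batch moments.
#' Alpha ends are synchronized by RDRP growth, so position 0 aligns across
#' chains; omega ends vary with polydispersity, which is why the contributor
#' count decays and the positional variance grows toward the omega end.
#'
#' @param batch an `rhp_batch` with at least one chain of length `>= w`.
#' @param w odd window size.
#' @return A list with `per_position` (data.frame `position`, `mean`, `var`,
#'   `n`; `position` is the 1-based window center), `pooled_mean` and
#'   `pooled_var` (moments over all window values of all chains).
#' @export
batch_position_stats <- function(batch, w) {
  stopifnot(inherits(batch, "rhp_batch"))
  long_enough <- lengths(batch$chains) >= w
  if (!any(long_enough))
    stop("no chain of length >= ", w, " in the batch")
  chains <- batch$chains[long_enough]
  half <- (w - 1) / 2
  plen <- lengths(chains) - w + 1L
  maxp <- max(plen)
  s <- s2 <- numeric(maxp)
  n <- integer(maxp)
  total_s <- 0; total_s2 <- 0; total_n <- 0
  for (ch in chains) {
    v <- as.numeric(window_profile(ch, batch$system, w))
    idx <- seq_along(v)
    s[idx] <- s[idx] + v
    s2[idx] <- s2[idx] + v^2
    n[idx] <- n[idx] + 1L
    total_s <- total_s + sum(v)
    total_s2 <- total_s2 + sum(v^2)
    total_n <- total_n + length(v)
  }
  mean_p <- s / n
  var_p <- ifelse(n > 1, (s2 - n * mean_p^2) / (n - 1), NA_real_)
  var_p[var_p < 0] <- 0  # guard tiny negative round-off
  pooled_mean <- total_s / total_n
  pooled_var <- if (total_n > 1)
    max(0, (total_s2 - total_n * pooled_mean^2) / (total_n - 1)) else NA_real_
  list(per_position = data.frame(position = (half + 1):(maxp + half),
                                 mean = mean_p, var = var_p, n = n),
       pooled_mean = pooled_mean, pooled_var = pooled_var)
}
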