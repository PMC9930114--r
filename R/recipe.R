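#' Solve a bench synthesis recipe
#'
#' Reverse design: converts a target monomer system plus batch targets into
#' reagent quantities for an RDRP synthesis. The stoichiometry is the
#' standard chain-transfer-controlled relation
#' `DP_n = conversion * [M]0 / [CTA]0`:
#' \itemize{
#'   \item total monomer moles `n_total = mass_scale / sum(f_i * MW_i)`
#'     (feed-weighted mean molecular weight);
#'   \item per monomer: `n_i = f_i * n_total`, `mass_i = n_i * MW_i`,
#'     `volume_i = mass_i / density_i` (NA for solids without density);
#'   \item chain-transfer agent `n_CTA = n_total * conversion / dp_target`,
#'     so the mean DP at the stated conversion hits the target;
#'   \item initiator `n_initiator = n_CTA / cta_initiator_ratio`;
#'   \item estimated chain count `n_CTA * N_Avogadro`;
#'   \item optional solvent volume from a target total monomer molarity.
#' }
#'
#' @param system a [monomer_system()] with molecular weights (and densities
#'   where liquid volumes are wanted).
#' @param mass_scale total monomer mass in grams (default 1).
#' @param dp_target target number-average degree of polymerization.
#' @param conversion target conversion, in (0, 1].
#' @param cta_mw chain-transfer-agent molecular weight (g/mol), optional.
#' @param initiator_mw initiator molecular weight (g/mol), optional.
#' @param cta_initiator_ratio CTA : initiator mole ratio (default 5).
#' @param monomer_molarity optional target total monomer concentration
#'   (mol/L) used to size the solvent volume.
#' @return Object of class `rhp_recipe`: list with `monomers` (data.frame
#'   `symbol`, `feed`, `moles`, `mass_g`, `volume_mL`), `cta`, `initiator`,
#'   `chains_estimate`, `solvent_volume_L` and the input targets.
#' @examples
#' solve_recipe(default_system(), mass_scale = 1, dp_target = 100,
#'              conversion = 0.5, cta_mw = 280.4, initiator_mw = 164.2)
#' @export
solve_recipe <- function(system, mass_scale = 1, dp_target = 100,
                         conversion = 0.5, cta_mw = NULL,
                         initiator_mw = NULL, cta_initiator_ratio = 5,
                         monomer_molarity = NULL) {
  system <- validate_system(system)
  if (mass_scale <= 0) stop("`mass_scale` must be positive")
  if (dp_target < 1) stop("`dp_target` must be >= 1")
  if (conversion <= 0 || conversion > 1)
    stop("`conversion` must be in (0, 1]")
  mw <- system$molecular_weight
  if (anyNA(mw)) stop("every monomer needs a molecular weight")
  if (any(mw <= 0)) stop("molecular weights must be positive")
  if (!is.null(system$density) && any(!is.na(system$density) &
                                      system$density == 0))
    stop("zero density is invalid when volumes are requested")

  f <- system$feed
  n_total <- mass_scale / sum(f * mw)
  n_i <- f * n_total
  mass_i <- n_i * mw
  vol_i <- mass_i / system$density  # NA density -> NA volume (solid)

  n_cta <- n_total * conversion / dp_target
  n_init <- n_cta / cta_initiator_ratio
  avogadro <- 6.02214076e23

  structure(list(
    monomers = data.frame(symbol = system$symbols, feed = f, moles = n_i,
                          mass_g = mass_i, volume_mL = vol_i),
    cta = list(moles = n_cta,
               mass_g = if (is.null(cta_mw)) NA_real_ else n_cta * cta_mw),
    initiator = list(moles = n_init,
                     mass_g = if (is.null(initiator_mw)) NA_real_ else
                       n_init * initiator_mw),
    chains_estimate = n_cta * avogadro,
    solvent_volume_L = if (is.null(monomer_molarity)) NA_real_ else
      n_total / monomer_molarity,
    targets = list(mass_scale = mass_scale, dp_target = dp_target,
                   conversion = conversion,
                   cta_initiator_ratio = cta_initiator_ratio)
  ), class = "rhp_recipe")
}

#' @export
print.rhp_recipe <- function(x, ...) {
  t <- x$targets
  cat(sprintf(
    "RDRP recipe: %.4g g monomer, target DP %g at %.0f%% conversion\n",
    t$mass_scale, t$dp_target, 100 * t$conversion))
  print(transform(x$monomers,
                  moles = signif(moles, 4), mass_g = signif(mass_g, 4),
                  volume_mL = signif(volume_mL, 4)), row.names = FALSE)
  cat(sprintf("CTA: %.4g mol", x$cta$moles))
  if (!is.na(x$cta$mass_g)) cat(sprintf(" (%.4g g)", x$cta$mass_g))
  cat(sprintf("; initiator: %.4g mol", x$initiator$moles))
  if (!is.na(x$initiator$mass_g))
    cat(sprintf(" (%.4g g)", x$initiator$mass_g))
  cat(sprintf("\nestimated chains: %.3g", x$chains_estimate))
  if (!is.na(x$solvent_volume_L))
    cat(sprintf("; solvent: %.4g L", x$solvent_volume_L))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.rhp_recipe <- function(x, ...) x$monomers
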