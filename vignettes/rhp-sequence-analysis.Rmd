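---
title: "Simulating and analyzing random heteropolymer sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing random heteropolymer sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhpseq)
```

## The problem

Random heteropolymers (RHPs) are statistical copolymers of two to five
monomers made by reversible-deactivation radical polymerization (RDRP).
They can mimic protein-like behavior — enzyme stabilization, membrane
transport — but, unlike proteins, individual chains cannot be sequenced.
What *is* controllable and measurable is the batch: feed mole fractions,
reactivity ratios, mean degree of polymerization (DP), conversion and
dispersity (PDI). Under good RDRP control these parameters determine the
sequence ensemble, so explicit sequences can be *simulated* and analyzed
statistically, and proteins can be translated into the same monomer space
for direct comparison.

rhpseq provides that workflow: a Monte Carlo sequence simulator, four
analysis metrics applied identically to simulated polymers and translated
proteins, and a reverse recipe solver for bench synthesis.

## The simulation model

Propagation follows the multicomponent Mayo–Lewis *terminal model*: the
probability that a radical whose last-added unit is monomer $i$ adds monomer
$j$ next is

$$ p(j \mid i) \;=\; \frac{x_j / r_{ij}}{\sum_k x_k / r_{ik}}, \qquad
   r_{ij} = k_{ii} / k_{ij}, $$

where $x_j$ is the *current* mole fraction of monomer $j$ in the unreacted
pool. With all $r_{ij} = 1$ this reduces to Bernoulli sampling from the pool
fractions (ideal random copolymerization); unequal ratios produce
compositional drift, which the simulator tracks because every addition
depletes a finite pool.

A batch simulation (`simulate_batch()`) works as follows.

1. **Pool sizing.** The pool holds `round(nc * dp_target / conversion)`
   monomer units split across types by the feed fractions (largest-remainder
   rounding), so that consuming the target conversion yields `nc` chains of
   mean length `dp_target`.
2. **Dispersity control.** Each chain is assigned a target length drawn from
   a Schulz–Zimm (gamma) distribution with mean `dp_target` and shape
   $1/(\mathrm{PDI}-1)$ — the standard chain-length distribution of
   controlled radical polymerization; two moments give direct control of
   DP$_n$ and PDI. `pdi_target = 1` is the exact monodisperse limit. When the
   sampled lengths sum to slightly less than the units the conversion target
   requires, random chains receive single-unit top-ups so that the
   conversion stop is always the binding one; the perturbation is
   $O(1/\sqrt{nc})$ per chain.
3. **Concurrent growth.** All chains are living: each step picks a living
   chain uniformly at random and appends one monomer by the rule above. The
   first unit of a chain is drawn from the raw pool fractions (no terminal
   unit exists yet). Chains retire at their target length.
4. **Stop rule.** The run stops when consumed units reach
   `round(conversion * pool)` — within one monomer addition of the target —
   or when no living chain remains (early retirement is reported through the
   realized conversion in `batch_summary()`).

The propagation loop is implemented in C++ for speed but draws from R's RNG,
so a seed makes an entire batch bit-reproducible.

Default synthesis conditions are conversion 0.5 and `pdi_target = 1.15`:
dispersity in well-controlled RDRP batches is kept *below* 1.2, so the
package default sits comfortably under that bound rather than on it. The
default chemistry is the four-monomer methacrylate system — 50% MMA, 25%
OEGMA, 20% EHMA, 5% SPMA — with all reactivity ratios 1; measured ratio
matrices can be supplied to `monomer_system()`.

```{r simulate}
sys <- default_system()
b <- simulate_batch(sys, nc = 15000, dp_target = 100, seed = 1)
batch_summary(b)[c("dp_n", "pdi", "conversion")]
```

Oligomers (chains with DP < 15) are removed experimentally during
purification; `filter_oligomers(b, 15)` reproduces that step in silico.

## HLB chemistry

Side-chain hydrophobicity is scored by the hydrophile–lipophile balance via
group contributions, $\mathrm{HLB} = 7 + \sum_i n_i \,\mathrm{HLB}_i$
(`hlb_side_chain()`). The built-in registry carries the totals for the five
stock monomers (MMA 8.45, EHMA 5.12, OEGMA 11.4, SPMA 18.5, STY 4.865); the
functional-group decompositions behind them are not part of the registry, so
new monomers take user-supplied group tables or totals. A monomer is
*hydrophobic* when its HLB is strictly below the threshold (default 9) and
*hydrophilic* otherwise; the tie goes hydrophilic so the boundary rule is
single and explicit. Under the default threshold MMA, EHMA and STY are
hydrophobic, OEGMA and SPMA hydrophilic. The threshold is a tunable analysis
parameter, not chemistry: lowering it to 6, say, splits MMA from EHMA.

## Metric 1 — chemical heterogeneity

`chain_compositions()` gives each chain's monomer mole fractions.
`kde_fwhm()` fits a Gaussian kernel density on a 512-point grid over
$[0, 1]$ with a Scott-type bandwidth ($1.06\,\min(s, \mathrm{IQR}/1.349)\,
n^{-1/5}$) and measures the full width at half-maximum of the tallest peak,
interpolating the half-maximum crossings linearly and clipping them at the
domain edges. Only the global peak is measured so that the spurious minor
peaks that appear in under-sampled batches cannot contaminate the width.
`nfwhm_profile()` normalizes each monomer's FWHM by its feed fraction
(nFWHM), making widths comparable across monomers fed at very different
levels.

```{r nfwhm}
nfwhm_profile(b)
```

For ideal (all-$r$ = 1) chains of fixed length $N$ the per-chain fraction of
a monomer fed at $f$ is $\mathrm{Binomial}(N, f)/N$, so the FWHM should be
$2\sqrt{2\ln 2}\sqrt{f(1-f)/N}$ — the oracle the test suite checks at
DP 100. The width shrinks as $1/\sqrt{\mathrm{DP}}$ and the profile
stabilizes with the number of chains; around NC = 15000 the nFWHM of even
the lowest-feed monomer (SPMA at 5%) is stable relative to its fluctuation
at NC = 100, which is the package's working definition of a converged batch
size.

## Metric 2 — segmental hydrophobicity

`binarize_chain()` labels every position phobic/philic, `run_segments()`
extracts maximal runs, and `segment_distribution()` tabulates run lengths
either *sequence-level* (mean count per chain: total runs of each length
divided by NC) or *batch-level* (summed counts; exactly the sequence level
times NC). Conventional report sets highlight lengths {1, 3, 5, 10}; the
full distribution is always computed and the highlight sets are plotting
conventions only (`plot_segment_distribution()`). For ideal chains the
phobic run-length law is geometric with continuation probability equal to
the phobic feed fraction — chain-interior runs are tested against it by
chi-square.

## Metric 3 — sliding-window hydropathy

`window_profile()` slides an odd-sized window one monomer at a time from the
alpha (first-grown) to the omega end and assigns the window-mean HLB to the
center monomer. Positions without a full window are undefined rather than
padded — the profile is `w - 1` shorter than the chain — because a
truncated window would mix segment scales. Window sizes 5, 9 and 15 probe
small, medium and large neighbor contexts. `windowed_segments()` re-applies
the metric-2 segment definition to the profile values, which makes segment
calls robust to the exact HLB threshold. `batch_position_stats()` aggregates
profiles across a batch anchored at the alpha end (alpha ends are
synchronized by RDRP growth; omega ends scatter with polydispersity, so the
contributor count decays and positional variance grows toward the omega
end — all chains alive at a position contribute, and the count is reported).
Pooled over positions, the batch mean window HLB tracks the feed-weighted
mean HLB, rises with the MMA:EHMA feed ratio at every window size, and its
variance shrinks as the window grows.

## Metric 4 — specific segment search

`find_specific_segments()` searches for the motif associated with
protein-like proton transport: a hydrophobic segment containing exactly one
embedded OEGMA unit. Concretely, a match is a maximal run over the alphabet
{hydrophobic monomers} ∪ {marker} containing exactly one marker with at
least `end_gap = 2` non-marker monomers between the marker and *each* end of
the run — the symmetric, marker-exclusive reading of "embedded, two or more
monomers from the end". Runs carrying two or more markers yield no match
rather than being split, since no splitting rule is defined for them.
Sequence-level reporting conventionally highlights lengths {5, 8, 10, 13};
batch-level comparison uses a kernel density over match lengths.

## Protein bridge

`read_fasta()` + `translate_protein()` map protein primary sequences into
monomer space via a residue dictionary grouped by
hydrophobicity/hydrophilicity/charge. The shipped default —
{V, L, I, M, F, W} → EHMA, {A, G, P, C} → MMA, {S, T, N, Q, Y, H} → OEGMA,
{D, E, K, R} → SPMA, with aromatics {F, W, Y} → STY when STY is present — is
one reasonable dictionary, prominently a *default*: any full 20-residue map
can be supplied. Non-standard residues (X, B, Z, \*) are errors with
positions, never silently dropped. `segment_protein()` splits the translated
chain into overlapping segments (length 100, offset 10 by default) so
protein segments are DP-matched to simulated RHPs of DP 100; a trailing
partial segment is dropped. The result is a protein-derived batch with no
pool metadata; its feed fractions are set to the realized composition of the
full-length chain so feed-normalized metrics stay defined, and every metric
above runs on it unchanged.

## Recipe solver

`solve_recipe()` inverts the design: given a target system, mass scale, DP,
and conversion it returns per-monomer moles/masses/volumes, chain-transfer
agent (CTA) and initiator loadings from the standard RDRP stoichiometry
$\mathrm{DP}_n = \mathrm{conversion} \cdot [\mathrm{M}]_0 /
[\mathrm{CTA}]_0$, an estimated chain count ($n_\mathrm{CTA} N_A$), and
optionally a solvent volume from a target monomer molarity (a user-supplied
concentration rule — the solver does not guess solvent chemistry). Monomer
masses close exactly to the mass scale and every output scales linearly
with it. One gram of a MW-100 monomer at DP 100 and full conversion
corresponds to about $6 \times 10^{19}$ chains — a reminder that any
simulated batch (NC ~ $10^4$–$10^5$) is a subsample many orders of
magnitude smaller than a real synthesis, the same kind of subsampling NMR
or GPC makes on ~1 mg of material.

## Numerical and design choices

* **Problem sizes.** The packaged analyses and tests use NC = 15000 at
  DP 100 as the reference batch — the point where nFWHM profiles have
  converged — with one NC = 100000 batch to demonstrate stability and
  NC = 100 batches to quantify small-sample fluctuation.
* **RNG.** One global R RNG drives everything (length sampling, then the
  propagation loop); a single seed reproduces a batch bit-for-bit.
* **Pool accounting** is exact integer bookkeeping: units in chains plus
  units remaining equal the initial pool per monomer type, and the test
  suite asserts this identity exactly.
* **Degenerate inputs.** KDE/FWHM requires two distinct values (a
  zero-variance composition sample is a degeneracy error, not a zero
  width); empty batches are errors for all summaries; an all-oligomer
  filter result is an empty batch with a warning.
* **Coordinates.** File exports (batch files, BED-like motif matches) are
  0-based half-open; positions in logs and plots are 1-based.

## What the simulator does and does not emulate

The generator reproduces the *statistical* structure RDRP synthesis
controls: feed-driven composition, terminal-model neighbor correlations,
conversion-coupled drift, Schulz–Zimm dispersity, alpha/omega asymmetry.
It does not model kinetics in time (rate constants, radical concentrations),
penultimate-unit effects, chain transfer to polymer, termination by
combination, or purification chemistry beyond the DP < 15 cut. Passing
tests therefore validate the sequence-ensemble logic, not any one wet-lab
batch; measured reactivity ratios should be supplied where available, and
conclusions about real materials inherit the terminal model's assumptions.
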