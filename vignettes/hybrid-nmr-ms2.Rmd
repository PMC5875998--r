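---
title: "Hybrid NMR/MS2 candidate ranking: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid NMR/MS2 candidate ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridrank)
```

## The problem

Untargeted metabolomics routinely detects LC-MS features that match nothing
in any spectral database. For such unknowns the only route to a structure is
*prediction*: enumerate what the molecule could be, simulate what each
candidate's spectra would look like, and keep the candidate whose
predictions best explain the measurements. `hybridrank` implements that
workflow for two orthogonal measurement types — 2D ¹³C-¹H HSQC NMR and
tandem MS — on top of accurate-mass formula inference. Each technique alone
is fallible: structurally different isomers can share near-identical
chemical shifts, and in-silico fragmenters mis-rank candidates regularly.
Their failure modes are largely independent, which is why the package keeps
both rankings and a rank-product consensus.

## Formula inference

A feature is `(m/z, adduct)`. The neutral mass is recovered through the
declared adduct — never guessed — with protonation arithmetic using the
proton mass (1.00727646 Da), not the hydrogen-atom mass. This choice is
deliberate: integer ppm-deviation columns in published feature tables
reproduce exactly under the proton convention combined with
floor-truncation of the absolute ppm error (`truncated_abs_ppm()`), and not
under H-atom arithmetic or rounding. Both conventions remain available
(`mass_constants`).

Enumeration (`enumerate_formulas()`) expands candidate counts one element
at a time, heaviest element first, pruning any partial assembly whose mass
already exceeds the window; the lightest element's count range is solved in
closed form. The search is therefore complete relative to the bounds —
there is no stochastic or heuristic component — and fast enough at
metabolite masses (< 2 s at 437 Da with CHNOPS bounds) that no
integer-decomposition machinery is needed.

Candidates are filtered by ring-plus-double-bond equivalents
(RDBE = C + 1 + (N − H − halogens)/2): negative or non-integer RDBE marks
a composition that cannot be a closed-shell neutral molecule. The filter
can be disabled (`rdbe_filter = FALSE`) since some adduct conventions
produce legitimately odd-electron species.

Isotope patterns are computed by per-element convolution aggregated at
nominal-mass (neutron-count) resolution, with bundled IUPAC masses and
abundances so results cannot drift with a library update. Nominal-mass
aggregation is the right granularity for Q-TOF instruments; isotope fine
structure is out of scope. The envelope fit statistic is a normalized L1
distance, `1 − Σ|obs − theo| / Σ theo` over the first K isotopologues
(default K = 3), clipped to [0, 1]. It is bounded, parameter-free and equals
1 only for exact agreement; it is a package design choice (no standard
exists) and is deliberately pluggable. Sulfur-rich formulas with a
phosphorus substitution can produce nearly indistinguishable envelopes, so
with noisy envelopes the top candidate occasionally swaps with such a
doppelganger — the recovery tests quantify this (≥ 18/20 at 5 %
multiplicative envelope noise).

## HSQC peak-list matching

The core NMR statistic compares a *predicted* peak list against an
*experimental* one. Each cross-peak is a (δ¹H, δ¹³C) pair; the distance
between two peaks is the weighted Euclidean form

$$ d(p,q) = \sqrt{(w_H\,\Delta\delta_H)^2 + (w_C\,\Delta\delta_C)^2},
\qquad w_H = 10,\; w_C = 1. $$

The 10:1 weighting encodes that proton shifts are measured and predicted
about an order of magnitude more precisely than carbon shifts (in ppm). A
city-block variant is available (`distance = "manhattan"`); the functional
form of the underlying distance matrix is not uniquely fixed by precedent,
so both are implemented with Euclidean as default.

Assignment is one-to-one: an experimental peak may serve at most one
predicted peak, preventing a degenerate candidate from collapsing all its
predictions onto one intense experimental signal. Only pairs with
|Δδ_H| ≤ 0.5 ppm **and** |Δδ_C| ≤ 5 ppm are eligible; these cutoffs are
package defaults chosen to be permissive relative to typical empirical
predictor errors (mean errors up to ~0.3 ppm ¹H / ~3 ppm ¹³C are common)
and are exposed in `match_config()`. Two assignment strategies exist:

* `greedy` (default): accept eligible pairs in ascending distance order.
  Fast and almost always optimal.
* `optimal`: exact maximum-cardinality, minimum-total-distance assignment,
  solved as a maximum-weight bipartite matching with weights
  `BIG − d` (`BIG` exceeding any achievable distance sum, so cardinality
  dominates). On ~1/200 random instances greedy differs from this optimum;
  the test suite checks the exact mode against a brute-force permutation
  oracle and checks greedy's invariants (never more matches, never a
  smaller total).

The **matching ratio** is the number of matched predicted peaks divided by
the number of predicted peaks — the denominator is fixed by the worked
convention that 5 matches out of 6 predictions give 0.83 (reported to two
decimals). Candidates are ranked lexicographically by (matching ratio
descending, mean weighted distance ascending, label); the reverse priority
is available (`rank_by = "distance_first"`) because "minimum shift
difference and maximum matching ratio" does not by itself fix an order.
Candidates with no eligible pair at all keep ratio 0, means `NA` and an
infinite distance key, so they are retained but sort last.

## In-silico fragmentation and MS² scoring

`generate_fragments()` enumerates every connected fragment obtainable by
removing up to `max_bond_breaks` bonds from the heavy-atom graph (default
2 — one chain cleavage plus another, or a ring opening, which needs two
cuts). Removal sets are enumerated exhaustively; since every cleavage step
removes at least one bond, the bond budget also caps the cleavage-tree
depth, and `max_tree_depth` is applied as a joint cap. Each proper fragment
carries hydrogen-rearrangement variants of ±2 H (configurable), the common
fragmenter practice; fragment mass is the fragment formula's monoisotopic
mass plus the H-shift times the hydrogen-atom mass. Fragments deduplicate
by (formula, H shift), keeping the fewest breaks.

Structures enter as SMILES. Because no R cheminformatics toolkit is
available as a dependency, the package carries a small SMILES reader
(organic subset, aromatic atoms, brackets with charge/explicit H, branches,
ring closures; stereochemistry ignored — irrelevant to constitution-level
fragment formulas). Implicit hydrogens follow the standard smallest-valence
rule; the test suite cross-checks formulas against an independent reference
toolkit via Python where available.

Spectrum annotation matches fragment ions — `[F−H]⁻` in negative mode,
`[F+H]⁺` in positive, matching the convention that a deprotonated sulfate
fragment explains a negative-mode peak — to spectrum peaks within 30 ppm
(the MS² mass accuracy used with the scoring this re-implements). Ties
resolve by smallest |ppm|, fewest bonds broken, smallest |H shift|. The
candidate raw score is

$$ \mathrm{score} = \sum_{\text{matched peaks}} I_{\mathrm{rel}}^{0.6}
\cdot (m/z)^{3}, $$

the classic peak weighting that emphasizes high-mass, reasonably intense
fragments; exponents are configurable. Scores are normalized by the best
raw score so the top candidate reports 1.0. This is a re-implementation of
the *idea* of combinatorial fragmenter scoring, not a clone of any
particular server version; score parity with historical web services is
explicitly not claimed, and the tests assert self-consistency and fixture
recovery instead.

## Mixtures

With several metabolites in one NMR tube, HSQC peaks must first be
attributed to spin systems. `group_peaks_by_connectivity()` builds a graph
on HSQC peaks, adding an edge whenever a TOCSY cross-peak's two proton
shifts match two HSQC peaks' proton shifts within 0.02 ppm (either
orientation); connected components are the groups. HMBC connectivity, when
supplied, contributes extra edges to the same graph — no separate procedure
is defined for it. Group labels are assigned by ascending minimum proton
shift, making the partition deterministic under input permutation.

`rank_mixture_candidates()` then scores *every* candidate × group pair and
orders all pairs globally — the all-pairwise design that lets a candidate
set generated for one LC-MS feature match any deconvoluted spin system.
Ties across equally good pairs break deterministically by label then group.

`combine_evidence()` aggregates the NMR and MS² rankings by rank product,
chosen because it is scale-free (the two scores live on incomparable
scales) and order-based. A candidate missing from one ranking is imputed
that ranking's worst rank + 1 rather than dropped, so the consensus never
silently loses candidates; both input rank columns are always carried in
the output for users preferring their own rule. A candidate ranked 1 in
both inputs is necessarily ranked 1 combined.

## The synthetic benchmark: what it does and does not establish

`build_scenario()` generates the package's self-contained benchmark,
mirroring a ten-metabolite model mixture: ten common metabolites (amino
acids, nicotinate, pantothenate, thymidine) with idealized HSQC spin
systems, TOCSY chains linking each metabolite's protons, accurate-mass
features with ~2 ppm mass error and 5 % multiplicative isotope-envelope
noise, predicted peak lists formed by perturbing the truth with Gaussian
predictor error (σ_H = 0.05 ppm, σ_C = 0.5 ppm — the magnitude of empirical
HSQC predictors), 20 decoy candidates per feature sampled uniformly over
physically plausible shift ranges with a minimum proton separation of
3·σ_H from the truth, and MS² spectra simulated from the true structures
with the package's own fragmenter (≥ 50 % of fragment ions retained,
plus uniform noise peaks). Everything is reproducible from one integer
seed.

Deliberate idealizations, and hence the limits of a green test:

* Library proton shifts of *different* metabolites are kept > 0.02 ppm
  apart, so TOCSY deconvolution is exact. Real mixtures overlap (methyl
  regions especially), and overlapping spin systems would merge groups.
* Decoy peak lists are random rather than chemically generated; real
  isomers' predictions cluster near the truth much more tightly. Recovery
  rates here bound the easy case, not ChemSpider-scale discrimination.
* Simulated MS² intensities are random, not physical; no collision-energy
  dependence, no J-coupling, no solvent effects, no retention-time model.
* MS² structural decoys reuse other library metabolites (the NMR decoys
  have no structures), so MS² decoys are mass-disjoint from the truth —
  again the easy direction.

## Numerical conventions

* Masses to 6 decimals in serialized output; scores and mean shift
  differences print at 4 decimals, matching ratios at 2.
* Writers emit TSV with stable ordering — reruns are byte-identical.
* Ranks are 1-based and unique (full deterministic tie-break by label).
* Degenerate inputs: empty peak lists, empty candidate sets and zero-total
  MS² scores raise errors or warnings rather than silently returning; an
  all-zero MS² score set keeps all candidates with score 0 and a warning.
* The enumeration cap (`max_candidates`) turns pathological bound choices
  into an instructive error instead of an out-of-memory condition.

## A compact mixture walk-through

```{r mixture, eval = FALSE}
sc <- build_scenario(n_features = 3, decoys_per_feature = 10, seed = 7)
grouped <- group_peaks_by_connectivity(sc$experimental_hsqc, sc$tocsy)
table(grouped$group)

cands <- subset(sc$candidates_nmr, feature_id == "F1",
                select = c(label, h_ppm, c_ppm))
res <- rank_mixture_candidates(cands, grouped)
head(res, 3)           # best pair: the true candidate in its own group

ms2 <- rank_ms2_candidates(
  subset(sc$candidates_ms2, feature_id == "F1", select = c(label, smiles)),
  sc$spectra[["F1"]]
)
nmr <- rank_hsqc_candidates(
  cands, grouped[grouped$group == sc$truth$true_group[1],
                 c("h_ppm", "c_ppm")]
)
combine_evidence(nmr, ms2)
```

## Known limitations

* Chemical-shift prediction is an input, not a capability; candidates must
  come with predicted HSQC peak lists.
* Charge states beyond |z| = 1 are supported only arithmetically.
* The SMILES subset excludes disconnected species, isotope labels'
  mass effects, and stereochemistry.
* Greedy assignment is the speed-oriented default; use
  `assignment = "optimal"` when exactness matters more than runtime.
* Rank-product consensus treats the two rankings symmetrically; no attempt
  is made to learn technique-specific reliability weights.
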