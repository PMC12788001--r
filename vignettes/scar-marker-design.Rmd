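---
title: "Designing species-specific SCAR markers from barcode panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-specific SCAR markers from barcode panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarkit)
library(dplyr)
library(purrr)
```

## The problem

Herbal raw materials sold as seeds are hard to authenticate: seeds of
related Brassicaceae species can be nearly indistinguishable by eye, and
bulk products may mix an authentic species with morphologically similar
adulterants. The motivating assay is Descurainiae Semen, the seed of
*Descurainia sophia*, whose commercial lots are frequently adulterated with
*Erysimum macilentum* and related species. Sequencing every seed is
impractical; a conventional PCR that yields a band only when a given
species is present in the bulk extract is cheap, fast, and usable by
regulatory and industrial laboratories.

`scarkit` implements the complete marker-development workflow behind such
an assay:

1. assemble a labeled panel of rDNA-ITS (or any barcode) sequences across
   the target species and its confusable relatives;
2. validate that the barcode separates the species (K2P distances,
   neighbor-joining, bootstrap, per-species monophyly);
3. find **species-specific nucleotides** (SSNs): alignment columns fixed in
   the target species and absent from every other species in the panel;
4. design **SCAR primer pairs** anchored with an SSN at the 3′ terminus
   (ARMS-style), optionally destabilized further with deliberate
   substitutions near the 3′ end, and capped at small amplicons;
5. screen the design by **in-silico PCR** across the whole panel, giving a
   pair × species specificity matrix that should be strictly diagonal;
6. model assay **sensitivity** (serial-dilution limit of detection) and
   **adulterant screening** of mixed products.

A seeded generator of ITS-like panels with known ground truth makes the
whole pipeline testable end to end without any downloads.

## Data model and conventions

Every tabular object is a tibble, and every user-facing function takes the
data frame first, so steps chain with the pipe. A *panel* is a tibble with
columns `id`, `species`, `seq`, `role` (`target_panel` or `outgroup`); an
*alignment* is the same tibble with equal-length gapped sequences. All
coordinates in this package are 1-based and inclusive — the native
convention of R and of the bp arithmetic on gels (a product spanning
positions 100–515 is 416 bp).

## Alignment

Panels are aligned with a center-star strategy over optimal pairwise
global alignments (Needleman–Wunsch with affine gaps; default scores
match +1, mismatch −1, gap open −5, gap extend −1, a gap of length $k$
costing $\mathrm{open} + k\cdot\mathrm{extend}$). The center sequence
maximizes the summed pairwise score; other sequences are merged under
"once a gap, always a gap". For barcode panels — short, closely related
sequences with occasional 1–3 nt indels — center-star alignments are
essentially identical to progressive-aligner output while remaining simple
enough to verify against enumeration oracles. Externally aligned FASTA is
accepted verbatim (equal lengths with gaps short-circuit re-alignment).
Ambiguity codes score as mismatches unless identical, a conservative
choice for diagnostic-site calling. Ties between equally optimal
alignments are broken deterministically by the alignment engine; tests
assert score-optimality rather than one canonical path.

## SSN discovery

`find_ssn_sites()` works on per-column allele tallies. A column is an SSN
for target species $t$ with allele $a$ when

* the frequency of $a$ within $t$ is at least $1 - \tau_\mathrm{intra}$, and
* the frequency of $a$ within every other species is at most $\tau_\mathrm{off}$.

The strict defaults $\tau_\mathrm{intra} = \tau_\mathrm{off} = 0$ demand
fixation in the target and absence elsewhere. $\tau_\mathrm{intra}$ exists
because real panels show occasional intraspecific variation (in the
motivating study, *Draba nemorosa*); raising it keeps such species usable
instead of discarding them. Columns where the target's allele is a gap are
never SSNs — a primer cannot anchor on absence — while off-target gaps are
allowed and flagged (`gap_context`). Columns containing any IUPAC
ambiguity code are disqualified by default, since clone-derived barcode
sequences should be unambiguous; set `exclude_ambiguous = FALSE` to relax.
`find_low_homology_windows()` complements single columns with windows in
which the target consensus differs from every other species' consensus at
`min_diff`+ columns, excluding columns where the target is polymorphic
beyond $\tau_\mathrm{intra}$.

## Primer design

Candidates are read off the target species' consensus with the 3′ terminus
exactly on an SSN column, lengths 18–28 nt (the range spanned by typical
published SCAR primers), on either strand. `introduce_mismatches()` adds
1–3 deliberate substitutions inside a window counted from the 3′ end
(default positions 2–4, configurable down to position 1 — published
assays occasionally substitute the terminus itself). The substituted base
is the transversion partner (A↔C, G↔T), the maximally destabilizing
choice; published tables do not state their substitution rule, so this is
the package's own default and every change is recorded in the candidate's
annotation rather than silently applied.

Melting temperatures come from either the Wallace rule, $2(A{+}T) +
4(G{+}C)$, or nearest-neighbor thermodynamics with the unified parameter
set (entropy-based monovalent-salt correction; defaults 25 nM strands,
50 mM Na⁺). `pair_primers()` combines forward and reverse candidates
subject to an exclusive amplicon cap (default < 500 bp — small amplicons
tolerate the partially degraded DNA of processed seed products), a Tm
balance tolerance, and a composite preference (amplicon inside 150–500 bp,
then Tm balance). The amplicon length convention includes both primer
footprints on the degapped target: 5′ end of the forward primer through
the 5′ end of the reverse primer, inclusive, which is what a gel ladder
measures. The suggested annealing temperature, min(pair Tm) − 3 °C, is a
starting point for gradient PCR, not a reproduction of empirically
optimized values.

## The in-silico PCR model

A primer binds a template site when the total number of mismatches is at
most `max_mm` (default 3) *and* no mismatch falls within `clamp_len`
positions of the 3′ end (default 2). The clamp abstracts polymerase
extension failure on 3′-mismatched templates — the mechanism that makes
ARMS-style SSN anchoring species-specific. Template ambiguity codes match
any compatible base.

One calibration subtlety: deliberate design substitutions mismatch *every*
template, including the intended target. Under a literal clamp a primer
with an engineered substitution at position 2 could never amplify
anything. The model therefore exempts annotated engineered positions from
the clamp test while still counting them against the `max_mm` budget: the
diagnostic terminus stays decisive, the engineered destabilization still
consumes mismatch budget on off-targets, and engineered primers amplify
their own targets (as they do at the bench). Unannotated primers follow
the literal rule — a single 3′-terminal mismatch kills the site.

`specificity_matrix()` runs every pair against every accession; a species
is positive for a pair when at least one of its accessions yields at least
one product. A successful design is strictly diagonal
(`specificity_is_diagonal()`). `max_mm` and `clamp_len` are declared
calibration parameters of the abstraction, not measured biophysics.

## Sensitivity and screening

Masses are carried in femtograms, which keeps the standard ten-fold series
from 10 ng (100 % of the assay) down to 100 fg (0.001 %) exact in floating
point. `simulate_dilution_series()` is deterministic by default (detected
iff mass ≥ LOD); the optional stochastic mode draws template copies as
Poisson(mass / mass-per-copy) with detection at ≥ `min_copies`, modelling
sampling noise near the limit — the copies-per-mass constant is a
configurable abstraction, not an estimated genome size. The published
limits of detection of the motivating assay are bundled as
`descurainia_lods()` (0.1 % for *D. sophia* and *E. macilentum*, 0.01 %
for *L. virginicum*, 1.0 % for the rest).

`screen_mixture()` applies per-species LOD fractions to product
compositions. A species below its LOD is reported "not detected at LOD",
never "absent" — the assay cannot distinguish absence from trace levels,
and verdicts are monotone in the adulterant fraction. The batch `glance()`
reports the adulteration percentage rounded to the nearest whole percent,
the convention of published batch surveys (15 of 17 prints as 88 %).

## Phylogenetic validation

Barcode adequacy is checked the standard way: Kimura two-parameter
distances with pairwise deletion,
$d = -\tfrac12 \ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with $P$ and $Q$ the
transition and transversion proportions over the sites retained for that
pair; ambiguity codes are treated as missing data, matching the defaults
of the distance software practitioners use. Saturated pairs (log argument
≤ 0) and empty overlaps raise errors rather than returning silently
truncated values. Trees come from a hand-implemented Saitou–Nei
neighbor-joining with deterministic lowest-index tie-breaking; negative
branch lengths are clamped to zero for display with the raw tree retained
as an attribute. Bootstrap support resamples alignment columns with
replacement, rebuilds the tree per replicate, and reports bipartition
percentages; `clade_support()` additionally reports, for any taxon set,
the fraction of replicates in which it is monophyletic on the
outgroup-rooted tree — the natural reading of "species clade support". On
a degenerate alignment with no variable columns every replicate matrix is
identical and the deterministic tie-breaking returns the same resolved
topology, so supports are 100 by construction (documented behaviour).
`ape` supplies the tree container and rooting machinery; its independent
K2P and NJ implementations serve as cross-checks in the test suite, never
as the implementation.

## The synthetic generator

`panel_spec()` defaults encode the study conditions of the motivating
assay: six species with 4/3/7/3/4/6 accessions, ~710 bp ITS-like
sequences bracketed by the universal ITS primer sites, no intraspecific
variation, and a handful of implanted diagnostic substitutions per
species. Interspecific divergence defaults to 0.04 expected root-to-tip
substitutions per site along a random coalescent species tree — pairwise
K2P distances of a few percent, typical of congeneric-to-confamilial ITS
comparisons. Mutations follow a 2:1 transition:transversion bias so K2P
estimation is well-posed on generated data. Two outgroup records descend
from a shared divergent stem (≈ 0.15 substitutions/site), mirroring a pair
of confamilial outgroup species and guaranteeing they root the tree as a
clade.

Diagnostic substitutions are implanted *after* interspecific evolution, at
columns still invariant across species (collision checking), so they are
fixed in-species and absent off-species by construction; intraspecific
noise and indels are added last and avoid the implanted columns and the
embedded primer sites. Every record carries a replayable edit log
(`replay_truth()`), which is what turns recovery tests from probabilistic
into exact. One consequence documented for test design:
terminal-branch evolution also fixes *unplanned* species-specific columns,
so the reference set for precision/recall is
`diagnostic_columns_from_truth()` — a direct recount over the truth's
species sequences — rather than the implant list alone.

What the generator does **not** emulate: concerted evolution and paralogy
of rDNA arrays, sequencing/cloning error, length heterogeneity beyond
short neutral indels, and base-composition heterogeneity across the
region. Passing tests on synthetic panels therefore demonstrate the
correctness of the algorithms under the stated model, not the wet-lab
performance of any particular primer set; the published assay quantities
that depend on chemistry (gel intensities, empirical annealing optima, the
biophysical basis of the LOD) are outside what any of this can reproduce.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the full pipeline on the
study-sized panel (29–31 records × ~710 bp), with bootstrap support at
B = 100 replicates and oracle comparisons on 100 randomized instances —
sizes chosen so the whole validation completes in about a minute on a
laptop while still exercising every code path at study scale. B = 1000
(the conventional choice, and the package default) behaves identically in
expectation and remains entirely practical interactively. Degenerate
inputs are errors, not warnings: empty panels, ragged alignments,
unlabeled records, saturated distances, non-positive masses, and
compositions that do not sum to one all abort with classed conditions.

## A worked example

```{r example, eval = FALSE}
g <- generate_panel(panel_spec(seed = 7))
aln <- center_star_align(g$panel)
prof <- column_profiles(aln)

species <- unique(g$panel$species[g$panel$role == "target_panel"])
pairs <- map_dfr(species, function(sp) {
  find_ssn_sites(prof, sp) |>
    (\(ssn) enumerate_anchored_primers(aln, ssn))() |>
    introduce_mismatches(n_subs = 1) |>
    (\(cand) pair_primers(cand[cand$strand == "forward", ],
                          cand[cand$strand == "reverse", ], aln))() |>
    head(1)
})

sm <- specificity_matrix(g$panel, pairs)
specificity_is_diagonal(sm)   # TRUE for a successful design
autoplot(sm)                  # the in-silico "gel"

bt <- bootstrap_support(aln, B = 100, seed = 1)
species_monophyly(bt, g$panel)
```

## Known limitations

* The in-silico PCR mismatch/clamp model is positional, not
  thermodynamic: it has no notion of mismatch identity, stacking context,
  or primer–dimer artifacts, and its two parameters are calibration
  choices.
* Center-star alignment has no iterative refinement; grossly divergent or
  repeat-rich panels should be aligned externally and supplied pre-aligned.
* The LOD simulator's stochastic mode is a sampling abstraction; it does
  not model inhibition or degradation.
* Quantitative PCR (Cq curves), multiplexing, and probe design are out of
  scope.
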