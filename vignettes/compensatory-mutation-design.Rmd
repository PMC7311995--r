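---
title: "Designing compensatory mutations for RNA-RNA interaction verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing compensatory mutations for RNA-RNA interaction verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Many regulatory RNAs -- bacterial sRNAs being the canonical case -- act by
base-pairing directly with a target mRNA. Computational RNA-RNA
interaction (RRI) prediction proposes such interactions in base-pair
resolution, but in vitro verification still rests on compensatory
mutation (CoM) experiments: one base pair of the putative interaction is
broken by mutating one RNA, the loss of the interaction signal is
confirmed, and the signal is restored by the complementary mutation in
the partner RNA. The experiment only discriminates if the chosen mutation
destabilizes both single-mutant combinations strongly while leaving the
wildtype-only and double-mutant interactions intact. Picking that
mutation by eye is error-prone; `comrank` turns the choice into a ranked,
reproducible candidate list.

## Model and assumptions

Two assumptions underlie the whole workflow:

1. the regulatory interaction is a *single* site, not interrupted by
   intra-molecular structure and not backed up by a second site elsewhere
   (multi-site interactions cannot be probed with a single CoM);
2. the duplex energy model identifies the relevant site and ranks its
   stability sensibly.

The built-in predictor scores only inter-molecular base pairing: an
interaction is an antiparallel set of base pairs (Watson-Crick plus GU
wobble), with free energy

    E_total = E_hybrid + ED_A + ED_B

where `E_hybrid` is a nearest-neighbor sum (duplex initiation constant,
stacking increments for adjacent pairs, an affine penalty for interior
loops/bulges) and `ED` are accessibility penalties: the energy needed to
free the interacting subsequence of each RNA from intra-molecular
structure. Only favourable interactions (`E_total < 0`) are reported.
The minimum-free-energy (MFE) interaction is computed exactly by dynamic
programming over interaction right ends (implemented in C++); an
exhaustive-enumeration oracle (`brute_force_duplex_mfe()`, sequences up
to 12 nt) independently verifies it in the test suite.

Parameters (`energy_parameters()`), all in kcal/mol at 37 °C:

* `stack`: Turner-2004-style RNA/RNA stacking increments (Watson-Crick
  values after Xia et al. 1998, GU wobble after Mathews et al. 1999),
  embedded as a versioned 6x6 table satisfying strand-exchange symmetry.
* `init_penalty` (4.09): duplex initiation; it makes isolated base pairs
  and 2-pair stacks unfavourable on their own, which is physically
  sensible and keeps candidate sites compact.
* `loop_base` (2.0) + `loop_per_nt` (0.4): affine interior-loop/bulge
  cost. This deliberately flattens the full Turner loop tables into two
  numbers; it preserves the qualitative ordering (stacks good, loops bad,
  larger loops worse) that the ranking logic needs, at the cost of
  absolute-energy fidelity.
* `max_loop_side` (16): maximal unpaired stretch between consecutive
  pairs on either sequence.

Accessibility providers: the default returns 0 (fully accessible RNAs);
`acc_constant()` charges a fixed penalty per covered nucleotide;
`acc_table()` reads user-supplied window penalties. The zero and
constant providers decompose per position, so the optimizer folds them
into the recursion and stays exact. Window tables do not decompose; for
them `duplex_mfe()` switches to exact per-boundary enumeration, which is
guarded to `nchar(A) * nchar(B) <= 4096` -- beyond that the user must
window the input or supply an additive provider. Users with
partition-function-grade energies from a dedicated RRI predictor should
use the external-predictor adapter (`parse_external_interactions()`)
instead of the built-in model.

## Candidate generation

Base pairs are collected from the wildtype MFE interaction (default) or
additionally from boundary-unique suboptimal interactions within the MFE
windows (`collection = "mfe_subopt"`); the suboptimal enumerator reports
at most one (best-energy) base-pair pattern per boundary quadruple, so
alternative patterns of the same site become visible without flooding
the list. Each pair is classified by helix context -- `stacked_both`,
`helix_end` (one stacking neighbor) or `lonely` (none) -- on the
interaction it came from, with the MFE context winning for duplicated
pairs (the MFE pattern is the better-supported annotation; this choice
was genuinely open). Filters restrict by base-pair type and context;
defaults keep all six pairable types and exclude lonely pairs, which
contribute too little stability for a robust signal, while keeping helix
ends reachable via `exclude_helix_ends = TRUE` for stricter designs.

Mutations come in two modes. `flip` swaps the two nucleotides (GC
becomes CG), which always yields incompatible wildtype-mutant pairs and
keeps wildtype-only and mutant-only stabilities similar; it is the
default because flips dominate successful published experiments. `all`
enumerates every pairable mutant pair in which neither mutated
nucleotide can still pair its wildtype counterpart, with GU wobble
counting as pairing -- each wildtype pair has exactly three such
alternatives (for U-A these are GU, GC and AU; CG is excluded because
wildtype U would wobble-pair mutant G).

## Evaluation and ranking

Every candidate is evaluated on the four sequence combinations: `ww`
(wildtype only), `wm` (target mutated), `mw` (query mutated), `mm`
(double mutant). A combination without a favourable interaction enters
the arithmetic as 0 with an explicit none-flag -- consistent with the
below-zero requirements, and it keeps the sorting statistic defined for
every candidate.

The hierarchical ranking applies a chain of classifiers, then sorts:

* **mfeCover**: the mutated base pair must be present in the `mm` MFE
  interaction. The implemented reading is the strict one -- the exact
  mutated pair, not mere window coverage of the two positions -- because
  an `mm` interaction that leaves the probed positions unpaired does not
  restore the probed contact.
* **E**: `MFE(ww) + alpha < min(MFE(mw), MFE(wm))` and
  `MFE(mm) + beta < min(MFE(mw), MFE(wm))` with strict inequalities,
  plus `MFE(ww) < 0` and `MFE(mm) < 0`. Defaults `alpha = 2`,
  `beta = 1` kcal/mol. The mixed combinations themselves are not
  required to be below zero.
* **minDeltaE** sorting:
  `min(MFE(mw), MFE(wm)) - max(MFE(ww), MFE(mm))`, descending -- larger
  values promise a cleaner experimental contrast.

Candidates are stratified by the longest *prefix* of the chain they
pass (a candidate failing the first classifier gets no credit for
passing later ones -- strata then order by decreasing constraint
satisfaction), sorted by minDeltaE within strata, and tied candidates
order by position then mutant pair so output is deterministic. The
original tie-break among equal-minDeltaE candidates was an open point;
position order is our choice and is documented in the output docs.

## Synthetic fixtures: what they do and do not show

`generate_interacting_pair()` emulates the sRNA-mRNA setup: one
complementary site of configurable length and GC content implanted in
random flanks. Defaults -- site 10 bp, GC fraction 0.7, 15 nt flanks per
side, no wobble -- reflect a typical short, GC-rich verified core
interaction inside a window around a target's start codon.

The generator must guarantee its ground truth: the implant has to be the
*single* dominant site, in the wildtype and under the single-pair flips
that evaluation applies. Random sequence does not grant this -- GC-rich
sites are self-similar, and a flip can extend a shifted self-alignment
into a competing helix. Three seeded constraints enforce it: the site is
redrawn while its shifted self-alignment has a pairable run of 3+ in
the wildtype or `max(4, L - 4)`+ in any single-interior-flip variant
(variants always admit some short complementarity, so they get the
longer bound, below which a competing helix has too few stacks to rival
the broken implant); flanks are built letter-by-letter by backtracking
search so they can never form a 3+ run with the other sequence's site or
its flip variants; and a final whole-assembly check rejects, under any
interior flip, off-register runs at least as long as the implant, which
is the shortest helix that could out-stack it. These bounds come from
stack counting: a run of `R` pairs carries `R - 1` stacking increments.

Fixtures therefore demonstrate recovery under idealized single-site
conditions. Passing tests show the machinery is correct -- they do not
show that real RRIs behave this way: real sites have intra-molecular
structure (here delegated to accessibility penalties or an external
predictor), protein chaperones, and genuinely competing near-sites, all
outside the generator's scope.

## Numerical choices

* Coordinates are 1-based inclusive everywhere, matching R indexing and
  all user-facing output.
* Favourability is strict (`E_total < 0` with a 1e-9 float guard).
* Among energy-equal optima, the interaction with the lexicographically
  smallest boundary quadruple `(start_a, end_a, start_b, end_b)` is
  reported; the DP propagates that tie-break so output is deterministic.
* Degenerate inputs: unpairable sequence pairs yield `NULL` interactions
  and empty candidate tables; an identity "mutation" (test-only) gives
  four equal energies, minDeltaE 0 and an E failure for any positive
  thresholds.
* Problem sizes in the shipped tests were chosen so the exhaustive
  oracle stays exact: oracle comparisons use sequences of 4-12 nt,
  recovery fixtures 12 nt total, benchmark tables 10 records at
  site 8/flank 8 (24 nt per sequence).
* Statistical tests in the profiling harness are `stats::t.test` (Welch
  with Satterthwaite degrees of freedom; paired one-sample on
  differences); the test suite verifies both against direct textbook
  formula evaluation. Groups with fewer than two observations or zero
  variance report `NA` rather than an invented p-value.

## Known limitations

* The simplified energy model ranks; it does not reproduce
  IntaRNA/Turner absolute energies. Threshold choices (`alpha`, `beta`)
  calibrated on another predictor's energy scale transfer only
  approximately.
* No intra-molecular structure prediction: accessibility is either
  ignored, constant, or supplied by the user.
* Single-nucleotide CoMs only; combining top candidates into multi-nt
  designs is out of scope because the current output cannot rank such
  combinations.
* Exact window-table accessibility and region-free suboptimal
  enumeration are limited to sequence-pair areas of 4096; longer inputs
  need regions or additive providers.
* Multi-site interactions violate the core assumption and will mislead
  any single-CoM design, here as in any comparable tool.
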