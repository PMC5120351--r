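---
title: "Detecting and quantifying lysyl-oxidase cross-linking sites in fibrillar collagens"
author: "colxlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying lysyl-oxidase cross-linking sites in fibrillar collagens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colxlink)
```

## The biological problem

Fibrillar collagens owe much of their tensile strength to covalent
cross-links between tropocollagen molecules. The chemistry starts when
lysyl oxidase (LOX) oxidatively deaminates one specific lysine in each
telopeptide — the short non-helical remnant left at either end of the
molecule after propeptide cleavage — to an aldehyde, which then condenses
with an acceptor (hydroxy)lysine near the end of a neighbouring molecule's
triple helix. At plain-sequence level this leaves recognisable footprints:

* **Telopeptide (substrate) sites** follow an `X-K-X'-X''` consensus, with
  `X'` mostly glycine or alanine and `X''` mostly proline (the human
  α1(I)/α1(II) C-telopeptide contexts are `QEKAH` and `REKGP`).
* **Helical (acceptor) sites** follow `Y-K-G-Y''-Y'''`, the lysine sitting
  in the third position of a Gly-X-X' triplet so the following glycine is a
  triplet anchor; `Y''` and `Y'''` are usually histidine and arginine
  (`...KGHR...`).
* The stretches connecting the helices to the cross-linking lysines are
  conspicuously **lysine-free**, which can be quantified as a probability.

This package turns that comparative analysis into a reproducible pipeline:
annotate a chain's domain architecture from sequence alone, delimit the
telopeptide analysis windows, scan for candidate sites, summarise their
conservation as position-weight matrices, and compute the lysine-depletion
statistic. A synthetic chain generator with planted ground truth makes every
stage testable without any database download.

## Domain annotation

`detect_gxy_regions()` finds collagenous regions as maximal runs of
consecutive triplets with glycine in the first position, evaluated in all
three reading registers. Two tolerances matter:

* `helix.min_triplets` (default **5**): runs shorter than this are noise.
  The literature never quantifies "short triple helix"; with real chains
  (minor helix tens of residues, main helix ~1000) any value from 3 to ~15
  gives the same classification, and 5 keeps the synthetic minor helix
  detectable.
* `helix.max_interruptions` (default **1** per run): real main helices are
  described as uninterrupted, but single substitutions and `X` residues need
  slack. Interruptions may not occupy the first or last triplet — regions
  are trimmed to glycine-anchored ends, which stabilises boundary recovery.

Overlapping runs from different registers are resolved in favour of the
longer, then the smaller start, then the smaller register — a total order,
so results are deterministic. `classify_helices()` names the longest run
the main helix (ties go C-terminal) and accepts as the minor helix the
longest strictly N-terminal run with at most `helix.minor_max_fraction`
(default 0.25) of the main helix's triplets; when two candidates tie, the
more C-terminal wins because its end anchors the N-telopeptide window.

`find_gpp_terminus()` reports the most C-terminal run of at least
`helix.gpp_min_repeats` (default **2**) exact `GPP` triplets: the motif
marks the C-terminal end of the helix, and no published count of repeats
exists, so 2 is the smallest value that is still a repeat; it is exposed
for sensitivity analysis. Only exact `G-P-P` qualifies — hydroxyproline is
indistinguishable from proline in one-letter sequence, so `P` stands for
both.

## Telopeptide windows

The N window runs from the minor-helix end (or the chain start when the
chain is N-terminally truncated and no minor helix exists) to the main
helix start. The C window runs from the main-helix end to an annotated
COLFI (C-propeptide) boundary when one is supplied; otherwise it is capped
at `telo.c_max_len` = **40** residues — vertebrate C-telopeptides are
roughly 11–26 residues, so 40 gives slack without swallowing the
C-propeptide. A user-supplied `colfi_stub` annotation always wins. Where a
chain shows no homology in the window, the rule-based window is still
reported and the scan simply returns no site.

## Site scanning and scoring

The published analysis identified sites by manual inspection of alignments;
this package makes the consensus explicit as per-offset residue weight
tables (data in the run configuration, not code constants):

| model | offset | weights |
|---|---|---|
| telopeptide | K+1 (`X'`) | G 1.0, A 0.8, S 0.5, else 0.1 |
| telopeptide | K+2 (`X''`) | P 1.0, H 0.6, G 0.6, else 0.1 |
| helical | K+2 (`Y''`) | H 1.0, else 0.2 |
| helical | K+3 (`Y'''`) | R 1.0, else 0.2 |

A candidate's score is the mean weight over the model's offsets, so it lies
in [0, 1] and is monotone in each table. The defaults are seeded from the
residues reported at each consensus position, and `sites.score_min`
(default **0.3**) is set so every reported consensus variant (KGP, KAH,
KAG, KST, KSG, KGH) passes. `X` and out-of-range positions always take the
`else` weight — ambiguity never boosts a score. Telopeptide candidates are
every lysine in the window, ranked by score with ties going to the lysine
nearest the main helix. Helical scanning covers only the first and last
`sites.end_window` = **30** residues of the main helix (the acceptor sites
sit a few triplets in from the ends), requires `K` immediately followed by
`G`, and by default enforces the register constraint
`(k - helix_start) mod 3 == 2`; no score floor applies because a bare `K-G`
at a helix end is still the best available acceptor and the published
pattern degrades gracefully (KGH with and without the arginine). The
best-scoring candidate per end is kept, ties resolved toward the end.

`check_flank_exclusion()` implements the five-residue rule: a site is
"clear" when no other lysine lies within `sites.flank` = **5** residues on
either side, clipped to the containing analysis window. A lysine exactly 5
residues away violates the rule; 6 residues away does not.

## Conservation profiles

`build_profile()` aligns site windows by their anchor lysine (offsets
−2…+4 by default) rather than by progressive multiple alignment — this is
how the published logos are centred, and it removes the alignment program
as a dependency and as a source of irreproducibility. Counts exclude `-`
pads and `X`; with `conservation.pseudocount` = **0** (raw alignments, as
in the published logos) frequencies are plain proportions, and a documented
alternative of 0.5 is available for small samples. Information content per
column is `log2(20) − H` bits with `0·log 0 = 0`; no small-sample
correction is applied by default because the published rendering settings
are unknown — the pseudocount flag is the configurable compromise.

## The lysine-depletion statistic

For lysine-free stretches of total length `N` at background lysine
frequency `f_K` (`conservation.f_k`, default **0.072**, the standard
proteome-wide lysine occurrence), the chance of that arising at random is
`(1 − f_K)^N`. The stretch for a C-telopeptide site is the open interval
from the main-helix end to the cross-linking lysine (`k − main_helix.end`),
and for an N-telopeptide site from the minor-helix end (`k −
minor_helix.end`); the landmark residue and the lysine itself are excluded.
Whether the published totals counted those terminal residues is not
recoverable from the text; the open-interval rule is one consistent,
deterministic choice and is validated on synthetic data where the truth is
known. Each measured stretch is also re-checked for actually being
lysine-free, and the flag is reported rather than assumed.

With the study-scale inputs — 19 C-telopeptide stretches totalling 275
residues and 14 N-telopeptide stretches totalling 176 — the pipeline
computes:

```{r depletion}
signif(lysine_depletion_probability(c(rep(14, 10), rep(15, 9)), 0.072)$probability, 3)
signif(lysine_depletion_probability(c(rep(11, 3), rep(13, 11)), 0.072)$probability, 3)
```

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` plants a full clade A-like architecture (propeptide
filler, 5-triplet minor helix, 15-residue N-telopeptide, 100-triplet main
helix ending in (GPP)3, 20-residue C-telopeptide, COLFI stub) with the
cross-link lysines in their canonical contexts and background lysines at
7.2%. Chains are deterministic given `(seed, index)` via a per-chain
substream, so families are reproducible even if generated in any order.
Three deliberate simplifications keep the ground truth exact:

* background filler excludes glycine, so no spurious Gly-X-X' register can
  arise by chance and planted helix boundaries are identifiable;
* telopeptides are lysine-free apart from the planted (and optional decoy)
  lysines, so depletion lengths are exact by construction;
* main-helix background lysines occur only at third-triplet positions
  strictly between the two planted acceptor motifs, so the planted site is
  always the end-proximal lysine of its terminus and zero-noise recovery is
  well-posed under the "tie toward the end" rule.

Substitution noise (`substitution_rate`) is applied i.i.d. after planting
and by default spares planted lysine anchors and triplet glycines, so
recall measurements isolate scanner behaviour from helix-detection
degradation (a flag lifts the protection). Consequently, passing tests on
synthetic chains demonstrate correct recovery of the planted architecture
under controlled divergence; they do not demonstrate robustness to real
evolutionary features the generator omits — indels, genuine helix
interruptions, compositional drift beyond lysine frequency, or telopeptides
with no homology at all. One emergent interaction is worth knowing: if a
planted telopeptide glycine happens to sit exactly one triplet before the
main helix and in its register, the detector (correctly) absorbs that
triplet into the helix; family gap vectors in the bundled analyses are
chosen so planted and detected boundaries coincide.

## Problem sizes and numerical choices

The bundled analyses and tests use families of 14–19 chains of ~400–460
residues (100-triplet main helices) — large enough that every landmark is
unambiguous, small enough that the full suite runs in a few minutes. The
oracle-equivalence property for helix detection is checked against an
exhaustive window enumeration on hundreds of random sequences up to 200
residues; information content is checked against a direct entropy
computation to 1e-9. All coordinates are 0-based half-open everywhere —
in memory and in every TSV/JSON — eliminating off-by-one drift between
modules; selenocysteine/pyrrolysine codes are rejected rather than silently
remapped; `X` is permitted but never matches a motif position and never
counts as lysine.

## Known limitations

* Detection is purely positional: no triple-helix propensity or thermal
  stability scoring.
* No propeptide-processing biology (ADAMTS/BMP1 cleavage prediction) and no
  COLFI HMM detection — the COLFI boundary is user-supplied or the
  C-window cap applies.
* The numeric site score is this package's operationalisation of a
  consensus that was originally curated by eye; it is configuration data
  and should be reported alongside any result.
* Hydroxylysine and lysine are indistinguishable in sequence, as are
  proline and hydroxyproline.
* Clade B fibrillar collagens are out of scope.
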