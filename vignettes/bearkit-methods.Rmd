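---
title: "Models and methods behind bearkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bearkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearkit)
```

`bearkit` has three layers: design rules for splice-donor base-editing
reporters, quantification of editing outcomes from amplicon deep
sequencing, and a seeded simulator that generates both layers' inputs
with known truth. This vignette records the models, the tunable
parameters and the design choices that were genuinely open, so a reader
can judge what a passing test does and does not establish.

## The splice-donor activity rule

A 5' splice site is summarised by three parts: the donor dinucleotide
(intron positions +1/+2, canonically `GT`), the last exonic base
(canonically `G`) and intron positions +3..+6 (canonically `RAGT`,
`R ∈ {A, G}`). Intron sequence beyond +6 is treated as free: the assay
tolerates arbitrary downstream sequence, which is what lets the PAM and
editing window be repositioned relative to the edited base.

The binary activity rule, with `d` the Hamming distance of the donor to
`GT` and `f` the number of non-canonical flanks:

> active iff (`d = 0` and `f ≤ 1`) or (`d = 1` and `f = 0`).

Three of its four clauses restate direct observations from mutational
scans of this junction: single-base donor variants with intact flanks
splice; double donor variants do not; one donor change plus one altered
flank does not; and `GT` with both flanks altered does not. The remaining
cell — canonical `GT` with exactly one altered flank — is not directly
reported anywhere we know of; `bearkit` classifies it **active** because
that is the weakest rule consistent with all reported observations (an
active pair selection would otherwise have been impossible for some of
the published constructs). This is an inference, so the rule takes the
flanks as arguments and the classification is exercised by exhaustive
enumeration in the tests rather than asserted case by case. Because only
the canonical/non-canonical *status* of a flank enters the rule, the
enumeration works over that status, not over specific altered flank
sequences.

Under this rule, with canonical flanks, exactly 7 of the 16 donors are
active (`GT` and its six single-base variants) and `AC` is the unique
donor rescuable to an active donor both by a single A→G (position 1,
giving `GC`) and independently by a single C→T (position 2, giving
`AT`) — the basis of a reporter usable with both editor classes.

There is deliberately no splicing-strength scoring beyond this binary
rule: the package enumerates designs, it does not rank them.

## Coordinates, PAM and cut site

All reference coordinates are 0-based with half-open intervals;
protospacer *positions* are 1-based counted from the PAM-distal end, the
convention of the base-editing literature. The PAM is fixed to NGG. The
editing window defaults to protospacer positions 4–8 inclusive — the
usual window quoted for the editors this assay targets; it is not derived
from data in this package and is configurable everywhere it appears. The
cut site is pinned to the blunt SpCas9 cut between protospacer positions
17 and 18; `bearkit` stores the coordinate of the position-17 base and
defines the indel window as that coordinate ± the half-width (closed, in
bases). The half-width default is 2 bp.

## Alignment

Reads are aligned semi-globally: the read end to end, reference overhangs
free. Scoring is affine — match +2, mismatch −2, gap open −6, gap extend
−1, with the opening penalty covering the first gapped base (a 1-bp indel
costs 6). `N` never matches anything and scores as a mismatch. Ties are
broken by preferring substitutions over gaps; afterwards every gap run is
canonicalised by shifting it as far toward the reference 5' end as
possible without changing the aligned base content, so indel placement is
deterministic and comparable across reads. The implementation is a Gotoh
dynamic program in C++; the test suite checks it against an independent
score-only dynamic program written in R, exhaustively on all sequence
pairs up to length 8 over a two-letter alphabet.

Reverse-orientation reads are handled by aligning the reverse complement
as well and keeping it only when it wins by at least the gap-open
penalty, so orientation is never decided by alignment noise.

## Read filtering and outcome calling

A read is retained when at least 75% of the first 20 reference positions
are aligned as exact matches; deletions, substitutions, `N` and positions
the alignment never reaches all count against the read. Both constants
are arguments (`identity_threshold`, `prefix_len`).

Retained reads are classified, mutually exclusively:

* **indel** — some gap run's reference footprint intersects the cut-site
  window (deletions by overlap, insertions by their anchoring
  coordinate), any gap size. Under the default `strict_flanks = TRUE`,
  a gap-bearing read qualifies only if it has *no* substitutions outside
  the designated editable positions. The source phrasing ("indels
  without mismatches") is ambiguous about whether a substitution near
  the gap should disqualify the call; the strict reading is the default
  and the permissive one is a switch, because both are defensible.
* **edited** — every designated editable position shows its expected
  product base.
* **byproduct** — some editable position shows an unexpected conversion
  (the C→G minority outcome of cytosine editing is the motivating case).
* **partially_edited** — some but not all expected conversions present.
* **unedited** — otherwise. `N` never counts as a conversion.

Frequencies: `indel_frequency = indel reads / retained reads`. The
denominator is *post-filter* — the order of operations in the source
method description runs filter first, count second; the pre-filter
alternative would only differ by the filtered fraction and is not
exposed. `intended_edit_frequency` divides by retained reads covering all
editable positions, so partially mapped reads cannot deflate it. Any
zero denominator yields `NA`, never 0 — downstream ratios (specificity,
enrichment) must see "undefined", not "clean".

## Derived statistics

`specificity = editing % / max(indel %, 0.05%)`. The floor is the
resolution limit of amplicon sequencing; it applies to the denominator
only and the result records whether it engaged. Specificity is therefore
constant for indel levels in [0, 0.05%] and non-increasing beyond.

`enrichment_fold` is a ratio of intended-edit frequencies with `NA` for
zero or undefined baselines. `normalize_profile` divides an activity
profile by a reference signal (active-control plasmid, or matched
on-target sgRNA); values above 1 are flagged and above 1.05 warned, since
a normalised activity materially above the control usually indicates a
mismatched reference. `profile_correlation` is plain Pearson on paired
values (≥ 3 pairs, `NA` on zero variance) — affine-invariant, so raw and
normalised profiles correlate identically.

Mismatch panels substitute blocks of 1–5 consecutive spacer positions.
The default substitution is the Watson–Crick complement — maximally
disruptive and guaranteed to be a true mismatch at every block position;
published panels mark their mismatched bases only graphically, so the
default block layout (ten evenly spaced starts per block length, 50
variants) is a configurable stand-in, not a reproduction of any specific
published set.

## What the simulator emulates — and what it does not

`simulate_reads` draws, independently per read: a cut-site indel with
probability `indel_rate` (signed size from a configurable distribution,
default mostly 1–3 bp deletions and 1–2 bp insertions; anchor uniform
over placements whose *canonical, left-aligned* footprint intersects the
±2 bp window, resampled otherwise so the caller's truth is unambiguous);
otherwise the intended conversion with probability `editing_rate`, each
edited C redirected to G with `byproduct_fraction`; bystander conversions
independently per position; then uniform substitution errors at
`error_rate` over every read. Defaults — editing 0.3, indel 0.01,
byproduct 0.1, error 0.001 — are realistic mid-range values for
unenriched editing, nickase-editor indel background, the reported
minority C→G share, and Illumina substitution error; the bystander rates
used in tests (0.66 and 0.16 at the two flank adenines) mirror reported
bystander levels of a hyperactive adenine editor. The simulator does not
model read quality, platform error profiles, sequencing indels, PCR
duplicates or paired ends; a green recovery test therefore establishes
estimator correctness under clean single-end substitution noise, nothing
more.

One estimator/simulator interaction is worth recording: the simulator
applies sequencing errors to indel reads too, so under the strict
"indels without mismatches" rule a fraction ≈ `1 − (1 − ε)^L` of true
indel reads is deliberately not counted. That is the published rule, not
an estimator of the simulator's indel rate — so the parameter-recovery
tests quantify with `strict_flanks = FALSE`, and the strict rule is
tested separately with constructed reads.

`simulate_enrichment` uses the simplest generative structure that yields
reporter-based enrichment: within transfected cells a latent competent
fraction π edits reporter (probability `q_r`) and genome (`q_g`)
independently *given competence*. The expected unsorted genomic edit
rate is `transfected · π · q_g`, and with `q_r = 1` the reporter-gated
over transfection-gated fold is exactly `1/π` — the closed form the
acceptance tests check at π ∈ {0.25, 0.5, 0.8}. This is a fixture with a
checkable answer, not a biological claim about how competence is
distributed.

All randomness is seeded explicitly (`seed` is a mandatory argument, no
hidden global RNG state), and identical truth gives byte-identical
output.

## Numerical and degenerate-input choices

* Scoring constants are fixed in the result's recorded parameters, so a
  quantification is reproducible bit for bit from its `run_config.json`.
* Undefined frequencies are `NA` markers end to end; `specificity`
  propagates them and `enrichment_fold` maps zero baselines to `NA`.
* Gap canonicalisation is idempotent; the tests assert that no gap run
  in any produced alignment can shift one base 5' without changing
  aligned content.
* Degenerate inputs (empty read sets, all reads filtered, sites without
  editable positions) return well-formed results with `NA` frequencies
  rather than erroring, because sample sheets routinely contain empty
  samples.

## Known limitations

* The activity rule is binary and flank-status-based; it cannot rank two
  active designs or score unusual flank sequences.
* Only NGG PAMs are enumerated.
* The aligner is for amplicon-length references (hundreds of bases), not
  genomes; there is no paired-end merging, UMI handling or
  quality-aware base calling (qualities are read and written, not used).
* Fluorescence enters as already-gated percent-positive values; there is
  no flow-cytometry file parsing or gating.
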