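---
title: "Methods: deciding whether an intronic hairpin is a processable miRNA"
author: "mirexapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding whether an intronic hairpin is a processable miRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Many microRNAs are born inside introns of protein-coding genes: a stretch of
already-transcribed sequence drifts into a fold that the Drosha/Dicer
machinery can process, and selection then refines it — intronic exaptation.
`mirexapt` implements the computational side of a case study of this
process for a hairpin in a Hox-gene intron: decide whether a candidate
precursor is structurally processable, survey its presence across a clade,
quantify which mature arm dominates in small-RNA data, ask whether the
miRNA can be transcribed independently of its host gene, nominate an
intragenic promoter from chromatin and CAGE evidence, and score candidate
targets. Every stage runs on synthetic data with planted ground truth, so
the whole analysis is testable without downloads.

## The functional-precursor classifier

A candidate is called a functional precursor when all four criteria hold:

* **Energy**: folding free energy strictly below the threshold
  (default −18 kcal/mol). The literature convention "< −18" is ambiguous at
  equality; we implement it strictly, so −18.00 exactly fails.
* **Stem**: at least 18 paired bases on the main stem, the unique helix
  chain from the outermost pair to the hairpin loop. Multibranch folds are
  an automatic failure of the separate hairpin-topology criterion: real
  annotated precursors are simple hairpins.
* **Mature arms**: no large internal loop or bulge inside either mature
  arm. "Large" is not quantified in the annotation literature; the default
  is > 5 nt per loop side or bulge, configurable. A mismatch is
  represented as a 1×1 internal loop — reportable, but below the default
  threshold, matching how mismatches are usually listed separately from
  large loops.
* **Topology**: a single simple hairpin.

If arms are not supplied they default to the 22 nt abutting each side of
the hairpin loop, the typical mature-duplex register.

## Energy models and folding

Two models are provided. The **unit-pair model** assigns −1 kcal/mol per
allowed pair (Watson–Crick plus GU wobble) and nothing to loops. It is
deliberately simple: its optimum is a maximum-pairing structure, which
makes exhaustive verification cheap and lets the synthetic generator plant
provably unique optima (below). The **nearest-neighbor model** sums
stacking energies over helices plus length-dependent penalties for
hairpin, bulge and internal loops and an affine multibranch cost, with
parameters read from a plain-text table. The shipped table is a documented
simplified set (36 stack contexts, loop initiations with a
Jacobson–Stockmayer log extrapolation, no dangling ends, no helix-end or
special-loop terms, 37 °C); a complete published parameter set in the same
format can be supplied for parity work, and externally computed folds can
be imported as Vienna text (`read_vienna()`), which is the supported route
when exact agreement with reference folding tools is required.

`fold_mfe()` is a dynamic program over nested structures (pseudoknots
excluded, hairpin loops ≥ 3 nt, bulge/internal loops bounded at 30 nt
total by default). Traceback is deterministic: among equal-energy
alternatives the 5′-most pairing is preferred, then the partner that
extends the current helix. `enumerate_structures()` generates every legal
structure of a short sequence (guarded at 25 nt) and is the independent
oracle: for hundreds of random sequences the DP optimum equals the
enumeration minimum exactly, in both models.

## Homolog scanning and locus composition

`locate_precursor()` runs Smith–Waterman local alignment with affine gaps
(match +2, mismatch −3, open 5, extend 2 — megablast-like scoring, since
the original searches used BLASTN without printed parameters). A species
is scored **present** when percent identity ≥ 60 over coverage ≥ 85 % of
the reference. The coverage requirement carries the discriminative load:
random local alignments in unrelated sequence can reach high identity
over short spans but do not extend over most of the reference.
Per-species statuses combine into a distribution matrix with precedence
database-confirmed > structure-supported (present hit + functional
verdict) > sequence-predicted > absent.

Conservation profiles are per-column modal-residue frequencies over
non-gap rows, optionally smoothed. CpG islands use the classic
sliding-window rule (200 bp windows, GC ≥ 0.5, observed/expected CpG ≥
0.6, merged maximal runs ≥ 200 bp) — the convention behind standard
genome-browser CpG tracks; island bounds are trimmed to unambiguous bases
so flanking `N` padding cannot shift a call. All coordinates package-wide
are 0-based half-open.

## Arm counts, expression calls and the co-expression rule

Reads (16–30 nt) are aligned ungapped at every offset of the precursor;
a read is assigned to the arm covering ≥ 16 nt of its best placement
(≤ 1 mismatch by default). Reads whose best placements split across the
two arms are excluded to an `other` tally rather than fractionally
assigned — conservative, and it keeps the dominance estimate a clean
binomial. Dominance is `count3p / (count5p + count3p)`.

Expression calls: microarray present/absent flags pass through, else a
detection p-value < 0.05 means present; RNA-seq uses a presence floor of
FPKM ≥ 1.0, the conventional detection threshold (the source analyses
state only the microarray rule), configurable.

The transcription-mode rule reduces jointly assayed samples to a 2×2
table. miRNA-without-host samples, with zero host-without-miRNA samples,
*support* an independent intragenic promoter; any host-without-miRNA
sample is reported as `expectation_violated` rather than suppressed,
because the model being tested predicts the host transcript always
delivers the miRNA. This is categorical evidence, never proof.

## Promoter candidates

CAGE 5′ tag starts are clustered by single linkage (gap ≤ 20 bp, ≥ 2 tags
to keep a cluster). Clusters overlapping the precursor or within 1000 bp
upstream are retained: the window must cover both the literature's "most
miRNA promoters lie within 500 bp upstream" and the specific candidate
around 550 bp upstream that motivates this analysis. Evidence flags are
any-overlap (≥ 1 bp) with DNase and H3K4me3 peaks (ENCODE-style peak
widths dwarf CAGE clusters; fractional-overlap rules add parameters
without signal); EST 5′ support is an optional third track with identical
semantics, and a missing track yields an `NA` flag, never a fabricated
one. Ranking is by evidence count, then total tags, then distance.
Cluster width is reported rather than clusters being merged, so broad
CpG-island-type initiation stays visible.

## Targets and GO enrichment

Site discovery uses the canonical seed rules (6mer core at miRNA
positions 2–7; 7mer-m8, 7mer-A1 and 8mer upgrades). The score is the
minimum duplex energy over sites in the seed register — a documented
stand-in for accessibility-based predictors whose ΔΔG internals are out
of scope here. The −20 retention cutoff used by such predictors is
carried over as an inclusive (≤) configurable default, with the caveat
that the scales differ. Over-representation of GO terms in the retained
set versus the background is an exact hypergeometric upper tail with
Benjamini–Hochberg correction — the standard choice where the original
comparison method is unstated.

## The synthetic generator

Generators define the study conditions and are fully deterministic under
(arguments, seed); one run seed fans out to per-stage subseeds by a fixed
counter scheme.

* **Precursors**: the stem is built as G:C pairs with the whole 5′ side G
  and the whole 3′ side C, and every unpaired region (hairpin loop,
  planted bulges and internal loops) is A. The sequence then contains no
  U, so G:C pairs are the only pairs possible, and the unique non-crossing
  perfect matching between the G block and the C block is the planted
  one: the unit-model MFE structure *provably equals* the planted layout.
  This trades base-composition realism for exact, assumption-free ground
  truth.
* **Degradation** models the unselected state: seeded substitutions,
  optionally "loop-opening" (toward A, the least pairing-prone base) and
  optionally spread one-per-bin so mutations cannot cluster. The clade
  generator uses loop-opening spread mutations (14 across the interior)
  so degraded copies stay recognisable by alignment (~71 % identity, full
  coverage) while reliably failing the structural criteria.
* **Introns** have exact-count GC backgrounds (so composition is within
  any stated tolerance by construction) with the precursor inserted
  verbatim at a seeded position.
* **Reads**: arm of origin Bernoulli(dominance), lengths uniform 20–24,
  substitution-only errors (indels would complicate the deliberately
  ungapped arm counter).
* **Tracks**: Poisson tag counts per planted TSS with ±5 bp jitter,
  uniform single-count noise tags, evidence peaks over planted TSSs.
* **Expression**: host on with probability `p_host_on`; miRNA whenever
  the host is on, plus `p_mirna_only` otherwise — zero host-only samples
  by construction.

What the generator does **not** emulate: realistic base composition and
repeat structure, indels and alignment uncertainty, paralogous hits,
sequencing quality, batch structure in expression data, or genome-scale
track noise. Passing tests therefore demonstrate correctness of the
operations and recoverability under the stated statistical conditions,
not performance on real genomes.

## Problem sizes and numerical choices

The default test and acceptance runs use: 200 random sequences of 8–18 nt
for the folding oracle (both models); a 9-species clade (6 intact, 2
degraded, 1 empty) in 2 kb introns; 100 repetitions for promoter recovery
(one planted TSS, 50-tag depth, 200 noise tags over 10 kb), co-expression
(40 samples), and dominance (depths 200–1000). Energy comparisons use a
1e-9 tolerance; the classifier's energy criterion is strict at the
threshold; target-score retention is inclusive at the cutoff; ranking
tie-breaks are documented total orders so every output is reproducible
byte-for-byte.

## Known limitations

The simplified nearest-neighbor table does not reproduce published
reference free energies — exact parity requires importing a full
parameter set or externally computed folds, and the external-record
parity check ships red until those inputs are supplied. The duplex target
score is not comparable to accessibility-based predictor scores despite
the shared cutoff convention. The promoter inference is evidence
integration, not TSS mapping; and the co-expression rule is sensitive to
the presence thresholds feeding it, which is why those thresholds are
exposed rather than fixed.
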