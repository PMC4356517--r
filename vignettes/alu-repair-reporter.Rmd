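---
title: "Modelling an Alu/Alu recombination reporter: simulation, junction calling, and junction statistics"
author: "aluRepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an Alu/Alu recombination reporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluRepair)
```

## The system being modelled

Alu elements are ~300-bp primate SINE retrotransposons, present in roughly a
million copies per human genome. Any two copies are similar but rarely
identical ("homeologous"), and recombination between non-allelic copies is a
recurrent source of pathogenic deletions. Selectable reporter constructs are
the standard way to quantify this in cells: two Alu elements in direct
orientation flank a selectable marker and a single I-SceI endonuclease cut
site, so that a double-strand break between the repeats can be repaired
either by homology-directed single-strand annealing (SSA) — deleting the
intervening sequence and fusing the two Alus into one chimeric element — or
by end joining (NHEJ), which deletes a variable segment and leaves a
junction with or without short microhomology. Only deletion products inside
a bounded size window reconnect the promoter to the downstream resistance
gene and survive selection.

`aluRepair` implements this whole measurement chain in software:

1. **cassette model** — the diverged Alu pair, its diagnostic sites, the
   homology-interval map, and the reporter construct geometry;
2. **repair simulator** — selectable repair products of every class the
   assay recovers, with known truth;
3. **junction caller** — recovery of the repair event from a product
   sequence alone;
4. **statistics** — interval-based expected junction counts, chi-square
   goodness of fit, pathway proportions, fold-decrease arithmetic.

## The cassette model

Coordinates are 0-based half-open on a single strand throughout; the
constructs are direct repeats, so no reverse-strand handling exists.

The default geometry is: promoter (1200 bp), Alu1 (300 bp), a ~1100-bp
spacer holding a neoR marker, a 50-bp polyA signal and the 18-bp I-SceI
recognition site (plus a 10-bp unannotated linker so the cut site does not
abut Alu2), then Alu2 (300 bp) and a promoterless puroR gene (600 bp) —
3500 bp in total. Filler and marker sequence is seeded-random synthetic
DNA; only the Alu spans, the polyA hexamer and the I-SceI site have defined
sequence. A 300-bp default element divides evenly into three 100-bp
reporting segments; a real consensus of a different length (for example a
~281-bp Ya5 element read from FASTA) simply truncates the final segment,
since segments are defined as ceiling(L/segment_length) spans.

**Diagnostic sites and homology intervals.** Where the two parental Alus
differ, a chimeric repair product can be genotyped for parent of origin;
where they agree, it cannot. The crossover of a single-crossover chimera is
therefore only mappable to the span between consecutive diagnostic sites.
With k sites the element carries k + 1 homology intervals, tiled with
boundaries at the sites; each interval reports to the 100-bp segment
containing its midpoint.

**Divergence patterns.** `generate_diverged_alu()` supports three modes.
`evenly_spaced` places k = round(L·pct/100) substitutions at 0-based
positions round(i·L/k) − 1, which at whole spacings reduces to
s − 1, 2s − 1, … (5% on 300 bp is one substitution every 20 bp; 0.7% is
realised as 2 substitutions, i.e. 0.67%). We use the rank-based formula
rather than a fixed rounded spacing because a fixed spacing
s = round(100/pct) overflows the element at divergences whose spacing does
not divide the length evenly (e.g. 15% on 300 bp), while the rank formula
spreads any representable k evenly. `random` samples k distinct positions
uniformly; `scrambled` permutes the consensus, giving the ~75% positional
divergence expected of unrelated sequence of identical composition.
Substituted bases are drawn seeded-uniformly from the three non-reference
bases: the exact substitution identities of published constructs are not
available in machine-readable form, so synthetic patterns stand in for
them, and constructs with bespoke site layouts can be supplied as FASTA.

**Alignment and the divergence convention.** Unequal-length pairs (e.g.
genomic Alus from different subfamilies) are aligned end-to-end with
Needleman–Wunsch (`Biostrings::pairwiseAlignment`; match +1, mismatch −1,
gap open 4, gap extend 1 — reasonable for repeats of 70–100% identity, and
configurable). Each maximal indel run is collapsed to a single diagnostic
site, because a run of inserted/deleted bases bounds junction mappability
exactly like one diagnostic substitution; divergence is
100 × (mismatch columns + collapsed indel runs) / alignment columns.
Equal-length pairs are compared positionally by default: reporter
constructs are built by substitution, and for unrelated equal-length
sequences a global aligner finds spurious gapped alignments that understate
the divergence of a scrambled element by ~25 percentage points.
`force_alignment = TRUE` restores the aligner for equal-length pairs that
genuinely contain balanced indels.

## The repair simulator

The simulator is the package's synthetic-data generator: its defaults are
the study conditions, not tuning knobs.

* **Single-crossover products** fuse parent-1 alleles 5′ of a chosen
  homology interval to parent-2 alleles 3′ of it; the deletion is one
  Alu-to-Alu distance (1400 bp under default geometry).
* **Complex chimeras** carry an arbitrary per-site parent-of-origin patch
  vector with ≥ 2 switches (1 or 0 switches *is* a single crossover and is
  rejected), emulating heteroduplex mismatch processing.
* **NHEJ deletions** join two cut positions drawn uniformly over pairs of
  positions between promoter end and puroR start. Junction microhomology is
  never imposed — it emerges from the flanking sequence and is measured by
  shift equivalence. An optional microhomology-seeking mode resamples
  candidate junctions with weight 2^microhomology, emulating the 5–25-nt
  microhomology preference of MMEJ; it is off by default.
* **Selection filter**: a product is selectable iff the deletion removes
  the whole polyA and I-SceI site, leaves promoter and puroR intact, and is
  897–1881 bp long. (One supplementary description of the same experiments
  gives 1901 bp as the upper bound; the window follows the main-text figure
  of 1881 bp and is configurable.)
* **Mixtures**: `mixture_preset()` fixes class probabilities (e.g. the
  44/56 recombination/NHEJ split observed at 10% divergence) and the
  crossover-position distribution — a two-component mixture of a uniform
  draw over intervals and a draw restricted to first-segment intervals,
  with `bias_weight_for_segment1()` solving the weight for a target 5′
  junction share. The default weight is 0 (the uniform null).

`simulate_colony_set()` emits exactly n selectable colonies. The class is
drawn once per colony and non-detectable *position* draws are rejected
within the class, so the emitted class mixture is unbiased even though NHEJ
draws are rejected far more often than recombination draws; the rejection
count is reported (it is the analogue of repair the assay cannot see). A
single seeded RNG stream is used with a fixed per-event draw order (class,
then positions, then bases), so outputs are byte-identical across runs and
platforms. Untemplated insertions default to length zero.

**Classification is by junction content.** A rare NHEJ draw can be
"in-register": a deletion of exactly one Alu-to-Alu distance whose junction
falls within the element produces a sequence byte-identical to an SSA
product. Such events are stored as `RECOMB_SINGLE_CROSSOVER`, matching the
operational definition used with sequenced junctions (a junction containing
an intact Alu counts as Alu/Alu recombination) — no sequence-based caller
could do otherwise.

**What the simulator does not model:** resection kinetics, Rad52 binding,
heteroduplex rejection or mismatch-repair cleavage mechanics (pathway
biology enters only through the class mixture); PCR artefacts, chromatogram
noise or multi-copy integrations. Passing round-trip tests therefore show
that the caller inverts *this* generative model exactly, not that it is
robust to raw Sanger data.

## The junction caller

`call_junction()` anchors a product to the cassette by its longest exact
prefix and suffix match. Products anchoring under 30 bp on either side are
`UNRESOLVED` (an unmodified cassette has no deletion and is likewise
unresolved — such cells are never selected in the real assay). The
unmatched middle defines the deletion; when the prefix and suffix overlap,
the overlap is the junction microhomology and the breakpoints are reported
at the leftmost equivalent placement (the same normalisation VCF uses for
indels), with the ambiguity reported explicitly rather than
midpoint-assigned.

The **intact-Alu test** decides the pathway: the product must carry, at the
Alu1 locus, a full-length span matching a parental allele at every readable
diagnostic site, matching the shared sequence at ≥ 99% of non-diagnostic
positions (head-room for optional simulated sequencing noise), and running
directly into the cassette sequence downstream of Alu2. If it passes, the
genotype vector is mapped by `locate_crossover()`: all-parent-2 → interval
0, all-parent-1 → the last interval, exactly one 1→2 switch at site i →
interval i; any 2→1 transition or ≥ 2 switches → complex chimera; > 10%
missing genotypes → unresolved (irrelevant for clean reads). For complex
chimeras the caller reports per-site genotypes only — when microhomology
makes a switch position ambiguous there is no canonical conversion-tract
boundary to infer. Otherwise the product is an NHEJ deletion, annotated
with microhomology and a topology class (`both_Alus` / `one_Alu` /
`no_Alu`) computed from the leftmost-aligned breakpoints against the Alu
spans; an `any_placement` mode instead counts a breakpoint as in-Alu if any
equivalent placement is, since published junction tables do not state their
convention.

## The statistics layer

* `expected_counts()` defaults to **per-interval weighting** (expected
  share of segment i = intervals assigned to i / total intervals): junction
  positions are only observable at interval resolution, so a "random"
  junction is naturally a random interval. Because "random throughout the
  element" could equally mean uniform per bp, `per_bp` weighting is also
  provided; for evenly spaced divergence the two nearly coincide, and
  neither is asserted to be the convention used with any published table.
* `chi_square_gof()` computes Σ(obs − exp)²/exp on segments − 1 df with an
  upper-tail p-value, cross-checked in the test suite against
  `stats::chisq.test`. Per-segment significance marks use a post-hoc
  one-segment-vs-rest chi-square at α = 0.05 with no multiple-testing
  correction, mirroring how such segment asterisks are usually reported.
* `fold_decrease()` rounds the quotient to the nearest integer, or to one
  decimal below 2 — the rule inferred from published colony-count tables,
  stated here explicitly. ANOVA/t-tests on colony counts are deliberately
  out of scope; colony tables pass through for reporting only.
* `adjusted_colony_counts()` splits a colony count by pathway percentages
  and always conserves the total.

## Worked example

```{r example}
cons <- synthetic_alu_consensus(300, seed = 101)
div <- generate_diverged_alu(cons, 5, "evenly_spaced", seed = 102)
pair <- align_pair(div, cons)
pair
cassette <- build_cassette(pair, seed = 103)

set <- simulate_colony_set(cassette, pair, 200,
                           mixture_preset(0.55, 0, 0.45,
                                          crossover_bias =
                                            bias_weight_for_segment1(
                                              build_interval_map(pair), 0.6)),
                           seed = 7)
calls <- call_colony_set(set, cassette)
rep <- repair_report(calls, build_interval_map(pair))
rep
```

## Numerical choices and test problem sizes

Degenerate inputs: a pair with zero diagnostic sites yields a single
homology interval spanning the element (junctions unmappable, and an empty
genotype vector maps to interval 0); divergences whose rounded substitution
count is zero are rejected as unrepresentable rather than silently returned
as 0%. Ties in the indel-run genotyping walk prefer parent 1 after an
8-column look-ahead. All text outputs are TSV/JSON with LF endings, `NA`
for absent values and 6-significant-digit formatting, so `simulate → call →
stats` is byte-identical across runs.

The test suite verifies the caller against brute-force oracles
(positional Hamming scans, shift-enumeration microhomology, consistency
enumeration for the crossover locator on all 3^k genotype vectors up to
length 8), and runs the pipeline end to end: 1,000 noise-free events per
class for round-trip recovery, 1,000 random junctions for the microhomology
oracle, 2,000 null simulations at 169 junctions for chi-square calibration
and 500 biased simulations for power. These sizes give the binomial checks
~3-SD resolution while keeping the suite comfortably interactive.

## Known limitations

* Sequencing noise is supported only as a tolerance in the intact-Alu test;
  no basecalling or chromatogram handling exists.
* In-register MMEJ/SSA products are inherently indistinguishable; class
  labels are junction-content labels, not mechanism labels.
* The genotyping walk for gapped (genomic) pairs resolves indel diagnostic
  sites greedily with a short look-ahead; adversarial tandem-repeat
  structures around an indel site could defeat it.
* No modelling of RNA-polymerase-III promoter boxes, Alu subfamily
  phylogeny, genome-wide Alu scanning, or multi-copy cassette
  deconvolution.
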