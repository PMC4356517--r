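# aluRepair

Simulation and junction analysis of Alu-mediated deletion repair, built
around a selectable Alu/Alu recombination reporter.

## The problem

Alu elements — ~300-bp SINE retrotransposons present in ~10⁶ copies per
human genome — are the dominant substrate for non-allelic homologous
recombination, a recurrent cause of pathogenic deletions. The standard way
to quantify this in cells is a reporter cassette: two (deliberately
diverged) Alu elements in direct orientation flank a selectable marker and
an 18-bp I-SceI cut site; a double-strand break between the repeats is
resolved either by single-strand annealing between the Alus (deleting the
marker and fusing the repeats into one chimeric element) or by NHEJ with a
large deletion, and only deletion products of roughly 0.9–1.9 kb restore
expression of a downstream resistance gene.

`aluRepair` is for people who build, analyse or teach with such reporters:
it models the cassette, simulates selectable repair products of every
recoverable class with known truth, calls the repair event back from a
product sequence alone, and implements the junction statistics used with
such assays.

## The core quantities

For a diverged Alu pair with diagnostic sites $d_1 < \dots < d_k$ (alignment
columns where the parents differ, indel runs collapsed), a crossover
junction is mappable only to a *homology interval* — one of the $k+1$ spans
between consecutive sites. The caller genotypes each diagnostic site of the
product's Alu span as parent 1 or parent 2 and maps a monotone genotype
vector with first parent-2 site $i$ to interval $i$; ≥ 2 switches is a
complex chimera. NHEJ junction microhomology is the maximal $m$ such that
shifting both breakpoints together by any offset in $[0, m]$ leaves the
product identical; breakpoints are reported leftmost-aligned.

Observed junction counts per 100-bp segment are tested against a random
distribution with $X^2 = \sum_i (O_i - E_i)^2 / E_i$ on segments − 1 df,
with $E_i = n \cdot (\text{intervals in segment } i)/(k+1)$ (per-interval
weighting; per-bp weighting is also available). Colony-count fold decreases
are reference/test rounded to the nearest integer (one decimal below 2).

## Worked example

```r
library(aluRepair)

cons <- synthetic_alu_consensus(300, seed = 101)     # 300-bp consensus
div  <- generate_diverged_alu(cons, 5, "evenly_spaced", seed = 102)
pair <- align_pair(div, cons)                        # 15 sites, 16 intervals
cassette <- build_cassette(pair, seed = 103)         # 3500-bp reporter
imap <- build_interval_map(pair)

# 55/45 recombination/NHEJ mixture with a 60% 5'-segment junction bias
set <- simulate_colony_set(cassette, pair, 200,
         mixture_preset(0.55, 0, 0.45,
           crossover_bias = bias_weight_for_segment1(imap, 0.6)), seed = 7)
calls <- call_colony_set(set, cassette)
render_report(repair_report(calls, imap))
```

```
Repair junction report (200 calls, 0 unresolved)
  Alu/Alu recombination:  52.0 %
  NHEJ:                   48.0 %

Junction distribution (observed | expected):
  segment_1   66 |   32.5 ######################################## *
  segment_2   20 |   32.5 ############ *
  segment_3   18 |   39.0 ########### *
  chi-square = 50.646, df = 2, p = 1.005e-11
```

200 selectable colonies were simulated from a mixture that is 55%
recombination by draw (52.0% realised in this sample) with junctions
enriched in the first 100 bp of the element; the caller resolved every
product, and the goodness-of-fit test rejects the uniform-junction null
decisively, flagging all three segments in the post-hoc one-vs-rest test
(`*`). The same stages are scriptable from a shell via the thin CLI in
`inst/cli/alurepair` (`simulate`, `call`, `stats`, `report` subcommands,
JSON run configs, deterministic given seeds).

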