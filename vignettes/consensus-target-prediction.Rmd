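---
title: "Consensus sRNA target prediction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus sRNA target prediction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnacons)
```

## The problem and the model

Bacterial small regulatory RNAs act by short antiparallel base pairing with
mRNAs, most often within a window around the translation start. Individual
prediction algorithms model this interaction differently (hybridisation
energy, accessibility, machine-learned classifiers, comparative
conservation) and their outputs overlap only partially. The premise of this
package is that *agreement between independent channels is itself the most
informative signal*: predictions supported by two or more algorithms at the
same site are far more likely to be genuine than any single algorithm's
list, and predictions that contradict an experimentally mapped site should
be surfaced, not hidden.

The package therefore separates three concerns:

1. **Channels** produce per-gene interaction records. Any external
   algorithm can be ingested through the canonical eight-column table
   (`read_prediction_table()`); a built-in duplex scanner provides a fully
   offline baseline channel.
2. **Collation** (`collate()`) clusters overlapping target intervals per
   gene, classifies each record against known sites, and assigns the gene a
   rank from 1 (multiply-confirmed known site) to 7 (single-channel novel
   call by the lowest-precedence channel).
3. **Filters and evaluation** restrict report membership (gene lists,
   differential-expression evidence) and quantify performance (sensitivity,
   false-positive rate, consensus-threshold ROC, seed sweeps).

## Coordinates

All interaction intervals are *translation-relative*: +1 is the first base
of the start codon, −1 the base immediately upstream, and position 0 does
not exist. For a minus-strand gene, +1 is the rightmost CDS base and
windows are reported in coding-strand orientation. Intervals are stored
ascending; an interval crossing the origin such as −3..+2 spans five
positions (`rel_span(-3, 2)`). Genomic coordinates are 1-based inclusive.
Replicons are treated as linear: windows running off an end are clipped
silently with the clipped base counts recorded (`clipped_up`,
`clipped_down`). Circular-genome wrap-around and the anchoring of
leaderless or boundary genes are out of scope; for such genes the clipped
window is simply shorter.

## The baseline duplex scanner

The scanner is deliberately transparent rather than thermodynamically
elaborate: channels are treated as black boxes by the consensus layer, so
the built-in channel favours desk-verifiable arithmetic over nearest-
neighbour energy models.

* **Pairing**: Watson–Crick plus G:U wobble (`allow_GU`, default TRUE).
* **Duplexes**: ungapped antiparallel runs. A candidate needs `seed_size`
  (default 6 nt) contiguous pairs; maximal runs are found by a small C++
  kernel and scored additively with weights GC −3, AU −2, GU −1 (arbitrary
  energy units, configurable, all ≤ 0).
* **Window presets**: stringent = 80 nt upstream / 20 nt downstream of the
  start codon with p ≤ 0.05; relaxed = 150/100 with p ≤ 0.5. The relaxed
  regime exists because genuine sites can sit well upstream of the
  stringent window; the cost is more background, which the consensus layer
  absorbs.
* **Significance**: per gene, the best duplex energy is compared with the
  best energies on `n_shuffles` (default 200) mononucleotide shuffles of
  the same window — composition-preserving, so the null respects local GC
  content. The add-one estimator p = (1 + #{null ≤ obs}) / (1 + n) never
  returns 0 and counts ties conservatively. A rank-based alternative
  (`top_n`) keeps the best N records genome-wide instead of thresholding.
* **One record per gene per channel**: the per-gene result-table convention
  of the published algorithms. Secondary sites on the same gene are not
  enumerated; ties are broken toward the most-upstream target position,
  then the longest duplex, so output is deterministic.
* **Determinism**: each gene's shuffle null is seeded as
  `rng_seed + gene_index`, making scans byte-reproducible and independent
  of execution order — concurrency is a contract on the output, not a
  mechanism the code depends on.

## Collation rules

* **"Same site"** means target-interval overlap of at least `min_overlap`
  nucleotides (default 1), closed under single linkage. The most
  permissive defensible reading was chosen because no stricter criterion is
  canonical; the parameter makes the choice explicit and adjustable.
  Correctness is judged on the mRNA interval only — the sRNA-side interval
  is reported but not required to match, since classifications in practice
  are made on target sites.
* **Ranks** take the best applicable tier. A gene with three correct
  channels and one inconsistent channel is rank 1, not rank 3: a
  contradicting channel should not bury a multiply-confirmed site. A gene
  with no known site and several channels at mutually disjoint sites falls
  through to the best single-channel tier among its channels — the tier
  list does not cover this case, and crediting the most trusted channel
  present is the conservative generalisation.
* **Channel precedence** for tiers 5–7 defaults to C > {T, S} > I but is an
  arbitrary-length user-supplied list, so any channel set gets a total
  ranking. Unknown channels fall in the last tier.
* **Filters never change ranks.** Ranks are computed on the full collation;
  gene-list and DE filters then restrict membership. Recollation from saved
  raw channel tables is therefore exactly equivalent to a fresh collation
  under the same filters (reports are byte-identical; numeric columns are
  written as `%.10g`, which round-trips).

## Filters

The differential-expression filter keeps genes with fold change ≥ `fc_up`
(default 1.5) or ≤ `fc_down` (default 0.5) and q ≤ `q_max` (default 0.005).
Bounds are inclusive by default — the boundary convention differs between
reasonable readings ("≥ 1.5" vs "> 1.5"), so it is a flag (`inclusive`).
Genes absent from a supplied DE table are dropped: providing the table
declares expression evidence a requirement, not a bonus. The degenerate
spec `fc_up = 1, fc_down = 1, q_max = 1` is accepted and acts as the
identity on genes present in the table.

## Evaluation

Sensitivity is correct known targets over all known targets; the
false-positive rate divides by the supplied validated non-target list only,
never by the genome — genome-wide denominators would dilute the rate
meaninglessly. Integer percent display rounds half away from zero (10/18 →
55.6 → 56). In the consensus ROC, a known target counts as hit at threshold
k only through a *correct* prediction in a ≥ k-channel cluster
(inconsistent-only genes are misses), while a non-target is called at k if
it has any ≥ k-channel cluster regardless of classification — an incorrect
site on a non-target is still a false call. Both curves are non-increasing
in k by construction, which every fixture asserts.

## The synthetic-data generator

`synth_genome()` emulates the *shape* of the real inputs: a single-replicon
genome with genes on alternating strands, a random sRNA, and planted
binding sites — the reverse complement of a designated sRNA stretch
embedded at a stated translation-relative position, on either strand.
Planted sites are guaranteed recoverable at exact coordinates by
construction:

* flanking positions are set non-pairing, so seed-and-extend stops exactly
  at the planted boundary;
* the declared search window of every planted gene is *sanitised*: a
  single left-to-right pass tracks, for every query position, the length of
  the contiguous pair run ending at the current window base, and replaces
  any free base that would let a background run reach `sanitize_min_run`
  (default 5) pairs. This is constructive, O(window × query), and avoids
  the instability of break-and-rescan repair (a point mutation that breaks
  one run tends to seed a fresh run on another diagonal, since each window
  base faces every query position);
* degraded sites cap their longest contiguous run via interior mismatches
  (`max_run`), exercising seed-size sensitivity;
* default intergenic spacing is `2 * window_up + 10`, keeping adjacent
  genes' windows disjoint so per-window sanitisation cannot conflict.

Background composition is uniform by default with a configurable GC
fraction, since sensitivity to GC content is an open question worth
exploring. What the generator does **not** emulate: real promoter/RBS
sequence structure, RNA secondary structure and accessibility, operon
organisation, overlapping genes, or realistic RNA-seq noise (DE tables are
designed directly). Passing tests on these fixtures therefore demonstrate
the correctness of the machinery — coordinate bookkeeping, scanning,
clustering, ranking, filtering — not biological accuracy on real genomes.

`synth_prediction_tables()` realises a per-gene/per-channel design
(correct / inconsistent / novel, with site groups laid out as overlap
chains that exercise single-linkage transitivity) and returns an **answer
key** derived by an independent naive re-implementation of the collation
rules (pairwise-overlap transitive closure by repeated sweeps, literal tier
rules). The optimised collation path is tested against this key on
thousands of randomised designs.

## Problem sizes and numerical choices

The bundled checks use genomes of up to 50 genes (~16 kb), 60-nt sRNAs,
25–50 shuffles per null and 1,000 randomised ranking designs — sizes chosen
so the whole suite re-derives every expected value from scratch in well
under a minute per property while still covering both strands, both window
regimes, degenerate compositions and origin-crossing intervals. Shuffle
counts in examples are below the 200-shuffle default because recovery
properties do not depend on p-value resolution; the add-one estimator's
floor 1/(n+1) is the only quantity affected. All randomness flows from
explicit seeds; identical inputs and seeds give byte-identical outputs
everywhere.

## Known limitations

* Ungapped additive scoring is a baseline, not a thermodynamic model;
  bulges, loops and accessibility are invisible to it.
* One record per gene per channel means a genuine second site on the same
  gene is never reported.
* Multi-replicon assemblies, GFF3 ingestion and network retrieval are out
  of scope; inputs are local FASTA + PTT (or the internal constructors).
* Reverse mode requires the sRNA catalogue to reference genomic intervals,
  matching the custom-annotation mechanism it models.
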