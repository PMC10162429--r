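---
title: "Integrating promoter and enhancer evidence at a gene locus"
author: "regulocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating promoter and enhancer evidence at a gene locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulocus)
```

## The problem

For most disease genes we know the coding sequence intimately and the
regulatory landscape hardly at all. SCN1A — the major epilepsy gene, with
three alternative promoters attached to the untranslated first exons h1a,
h1b and h1c — is the motivating case: promoter boundaries in routine use
date from reporter assays on an obsolete genome build, enhancers were
uncharacterized, and the evidence needed to revise both is scattered across
genome-wide resources (CAGE/RAMPAGE TSS atlases, candidate cis-regulatory
element registries, sequence-constraint maps, brain enhancer catalogues,
cell-type-resolved chromatin interactomes). regulocus implements that
integration as a reusable, tested pipeline: any gene locus with the same
evidence-track inputs can be analysed.

The package is organised around an `EvidenceCatalogue`, an S4 bundle of
everything the integration consumes: a `GeneModel` (transcripts, named
untranslated exons, CDS span), TSS records, promoter-like-signature (PLS)
elements, experimental promoter constructs, a binned `ConstraintTrack`,
per-source enhancer call sets, and interaction loops. All intervals are
`GRanges`; BED/bedGraph files are read and written through rtracklayer, and
loops through a small BEDPE reader returning `S4Vectors::Pairs`.

## Promoter derivation

The central algorithm turns a prose integration rule into a deterministic
procedure. The constraint track follows CDTS semantics — a score per 10 bp
bin, lower meaning less tolerant to variation in the population, negative
flagging highly constrained, likely functional sequence. The rule gives
priority to constrained sequence: constrained regions around the direct
promoter evidence are included; unconstrained sequence is included only when
it is sandwiched inside constrained context *and* covered by experimental
promoter evidence.

Formally, for one untranslated exon (UE):

1. Partition the track into maximal **sign runs** (consecutive bins all
   negative, or all non-negative).
2. Build the **evidence seed**: the coordinate hull of the UE, positioned
   TSSs padded by `seed_pad` (default 50 bp), PLS elements, experimental
   construct intervals, and the UE extended downstream by `downstream_ext`.
3. Include every negative run overlapping the seed. Include a non-negative
   run iff it is abutted on both sides by currently included negative runs
   and overlaps experimental evidence; each bridged run lets step 3 pull in
   the negative runs beyond it. Iterate to a fixpoint (bounded by the
   number of runs).
4. Report the hull of everything included, snapped outward to bin
   boundaries, with full provenance (every seed component and run).

Design choices that the prose left open, decided here and tested as part of
the package's definition:

* **"Encompassed" means strict abutment.** A non-negative run counts as
  inside constrained context only when the flanking negative runs touch it
  exactly (no gap). A `bridge_gap` parameter relaxes this if a user wants
  gap-tolerant bridging; the default is 0.
* **Downstream extension is a parameter.** Regulatory sites are known to
  sit downstream of the UEs, but no extent is established; the seed extends
  the UE downstream (strand-aware: for a minus-strand gene, downstream is
  towards lower coordinates) by 500 bp by default.
* **Absent TSS evidence merely removes a seed component.** The h1c UE has
  no TSS in either TSS atlas; its seed is built from the remaining
  components rather than being penalised.
* **Ties and degenerate inputs are errors, not silent fixes** — inverted
  coordinates, a seed not covered by the track, or an unknown UE all stop
  with a message naming the offender.

The packaged SCN1A catalogue ships the *published* revised boundaries
(P1a\*: chr2:166,148,180–166,151,550; P1b\*: 166,127,360–166,129,030;
P1c\*: 166,077,140–166,079,490) as a reference annotation. The underlying
genome-wide CDTS values are not redistributable at desk scale, so the
pipeline does not pretend to re-derive these coordinates: on the fixture it
reports the annotation and logs that derivation was skipped. The
algorithm's correctness is instead established on an enumerated worked
example (a 20-bin toy locus exercising both the bridge-and-grow and the
exclusion branches) and on simulated loci with known truth.

## TSS activity

Tag counts are normalized to tags per million: `tpm = count / total * 1e6`.
Library totals default to column sums — appropriate when the matrix is
genome-wide — and can be supplied explicitly when the matrix covers only a
locus (the simulator does this, passing the true library depths). The
published activity values were additionally processed with a
relative-log-expression step; since that computation is not reproducible
from the published summaries, plain per-million scaling is the core
definition here, with an optional median-of-ratios size-factor adjustment
(`method = "rle"`) whose factors are cross-checked against edgeR in the
test suite. Group summaries use the arithmetic mean and the n−1 standard
error (0 when n = 1); ranking is by descending mean with deterministic
tie-breaks (genomic position, then identifier).

## Enhancer corroboration and linking

Enhancer calls from an origin source (for SCN1A, the PsychENCODE GRN brain
enhancers) are corroborated against every configured source by any-bp
overlap — presence/absence, not reciprocal fraction, because the underlying
catalogues report presence; a `min_overlap` parameter is exposed (default
1 bp). Mouse-derived calls participate as an ordinary source carrying a
`mouse-lifted` species flag; no liftover is performed in-package. A
high-confidence label is attached at a configurable support threshold
(default: supported by all human sources) — reporting metadata, not a
filter. Proximity to the gene is the minimum gap to the CDS span (0 when
overlapping), classed near/intermediate/far at 300 kb and 700 kb defaults,
matching the published description of seven enhancers at ~250 kb and two
beyond 700 kb.

Promoter–enhancer links require at least one cis loop with one anchor on
the promoter and the other on the enhancer, in either orientation; links
are tabulated per cell type over a complete, zero-filled (cell type ×
promoter) table.

## The simulator and what passing tests mean

`simulateLocus()` generates a locus with known truth so every stage is
testable without downloads. Defaults were fixed once as the study
conditions:

* geometry: a 400 kb locus, minus-strand gene, CDS spanning the 62–80%
  band, three UEs spaced 25 kb apart, true promoters 1.5–3.7 kb wide and
  bin-aligned, five true enhancers 30–240 kb downstream of the CDS;
* constraint: N(0.5, 0.3) baseline vs N(−1.5, 0.3) over functional
  elements, 10 bp bins — at these levels ~5% of baseline bins dip negative
  while functional bins essentially never flip sign, which is the regime
  the rule assumes (clear troughs on a noisy tolerant background);
* counts: negative binomial (dispersion 10), the standard overdispersed
  model for CAGE tags, with groups of 3/3/3/24 samples matching the
  published cell-type inventory and two active groups;
* enhancer calls: per-source sensitivity 0.9, one false positive per Mb,
  30 bp edge jitter; six sources, the last mouse-lifted;
* loops: each (cell type, promoter, enhancer) triple is a true link with
  probability 0.3, represented by a loop with probability 0.95, plus two
  background loops per cell type.

One seed governs all stages (stage k reseeds from `seed + k`), so runs are
bit-reproducible and stages can be regenerated independently.

`recoveryReport()` scores derived outputs against truth: per-promoter
base-pair Jaccard; enhancer precision/recall of corroborated candidates at
a support threshold (default 2 — the point of corroboration being that a
region seen by at least two independent sources is trusted), computed on
the pooled, merged calls of all sources; link precision/recall of detected
triples. The repository's standing bar, checked in the acceptance tests
over 50 simulated loci: mean promoter Jaccard ≥ 0.8 and enhancer and link
precision/recall ≥ 0.9 at default noise, and exact recovery (all metrics
1.0) under noiseless parameters. Fifty 400 kb loci keep the experiment at
a few minutes on one CPU.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: sequence content and alignment artefacts; constraint
scores that drift rather than switch cleanly between regimes; spatially
correlated noise in constraint and in enhancer calls; TSS positions mislabelled
across promoters (the packaged catalogue carries one such published
discordance, stored verbatim with a flag); and interaction loops with
resolution-limited, offset anchors.

## Worked example

```{r example, eval = FALSE}
cat <- loadScn1aCatalogue()
report <- runPipeline(cat, out_dir = "scn1a_out")

toExternal(report$promoters)     # the three revised promoter regions
head(report$rankings[["brain"]]) # TSS:166128014 first at 44.1533 TPM
report$enhancers                 # 9 candidates: 7 near (support 6/6), 2 far (4/6)
```

On a simulated locus the same call derives promoters from the constraint
track, and `recoveryReport()` scores the run against truth:

```{r simulated, eval = FALSE}
sim <- simulateLocus(simulationParams(), seed = 1)
rep <- runPipeline(sim$catalogue, verbose = FALSE)
recoveryReport(rep$promoters, sim$truth,
               candidates = rep$enhancers, links = rep$links)
```

## Known limitations

* The derivation rule is a formalization; published boundaries are carried
  as annotation, not re-derived, because the genome-wide inputs are not
  shipped.
* Corroboration is binary per source; no weighting by source quality.
* Distances are gap-based; the package takes no position on the published
  near-distance ambiguity (~250 kb from the CDS in one section, ~125 kb in
  another) beyond computing the stated min-gap definition.
* No liftover, no binary track formats (bigWig/tabix), no QTL integration,
  no de novo TSS calling or loop calling.
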