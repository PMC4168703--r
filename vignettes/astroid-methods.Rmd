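---
title: "Assembling effective transcript copies: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling effective transcript copies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(astroid)
```

This vignette explains the statistical model behind `astroid`, the
parameters that matter in practice, what the bundled simulator does and
does not emulate, and the design decisions taken where the method left
genuine latitude.

## 1. The copy model

An RNA-seq library is a sample of fragments cut from individual transcript
molecules. `astroid` reconstructs those molecules ("effective transcript
copies") directly: a copy is an ordered chain of non-overlapping aligned
mate pairs, together with the gaps between them and the two terminal gaps
to the transcription start (TSS) and termination (TES) sites.

All sizes — fragment lengths, inter-fragment gaps, terminal gaps — are
modeled by one Weibull distribution `d(x) = P_W(x | δ, η)`. Under a
uniformly random fragmentation process the fragment-size distribution is
approximately Weibull; the scale `η` is the fragmentation intensity of the
experiment and the shape `δ` is fitted globally by default (an optional
rule makes it proportional to the log molecule length; with a single global
shape the two parameterizations are practically indistinguishable on
pooled data, so the global fit is the identifiable default).

The likelihood of a copy is the geometric mean of the `d` values of all its
fragments and gaps, so copies with different fragment counts are
comparable. A copy is **effective** when `p = ∫_{d(x) ≤ L} d(x) dx > τ`:
this is a highest-density-region test, and for a size drawn from the model
itself `p` is uniform, so `τ` (default 0.05) is exactly the probability of
falsely discarding a typical copy. (The opposite inequality direction,
which a literal reading of the defining set suggests but which would
discard *typical* copies, is available as `paper_literal = TRUE`.)
Ineffective copies are kept in the diagnostics output but contribute
nothing to the effective-copy count `eT`, from which
`eTPM = eT·10⁶/ΣeT` is computed; FPKM and TPM are produced alongside from
fragment counts.

## 2. Fitting the size model: truncation matters

Sequencing libraries are size-selected. The observed spliced fragment
sizes are therefore a *windowed* sample of the fragmentation distribution,
and an unconditioned Weibull MLE on them badly inflates the shape (a
[150, 350] bp window of an exponential-like process fits as `δ ≈ 4`), which
in turn floors the probability of every long gap and distorts both edge
weights and the effectiveness test. `astroid_assemble()` therefore fits by
truncated maximum likelihood on the selection window — supplied as
`size_selection = c(lo, hi)` when the library prep is known (recommended),
or estimated from the data (left edge at the mode of the 10 bp-binned size
histogram, below which only path-measurement artifacts live; right edge at
the 99.9th percentile). `fit_size_model()` without a `truncation` argument
is the plain MLE.

Because sizes are integer base counts, `size_density()` evaluates the pdf
at `max(x, 0.5)`: the half-base continuity correction gives a zero-length
gap (abutting fragments — a real and common feature of size-selected
libraries) a finite probability instead of the 0 (shape > 1) or ∞
(shape < 1) of the continuous density at the origin. All probabilities are
clamped to `[prob_floor, 1]` with `prob_floor = 1e-12` so that `−log`
weights stay finite and non-negative.

## 3. The read flow network

Per locus (weakly connected component of the splice graph, with mate pairs
also linking components), every read is a vertex of capacity 1. Edges:

* **in-fragment** — one per mate pair per unique splice-graph path
  connecting the mates, weight `−log d(spliced fragment size)`;
* **between-fragment** — from each fragment's 3′ read to every downstream
  5′ read whose transcript-coordinate gap lies in `[0, max_gap]`, one per
  connecting path, weight `−log d(gap)`. `max_gap` defaults to the length
  at which the Weibull survival drops below 10⁻⁶ — longer connections
  cannot pay for themselves and only grow the network quadratically;
* **TSS→5′ read** and **3′ read→TES** edges, weighted the same way but with
  unbounded gap (the floor keeps the weight finite), so every read is
  always reachable;
* zero-weight virtual edges source→TSS, TES→sink, and one source→sink
  bypass that absorbs surplus flow.

Read vertices carry a cost `−log P(v)` with `P(v) = 1 − 10^(−MAPQ/10)`.
Without annotation, TSS/TES are the outer boundaries of source/sink exons
of the splice graph; with a GTF, annotated transcript ends are used
(clamped into covered exons).

Every read must belong to exactly one copy, so read vertices carry a lower
bound equal to their capacity. The solver realizes vertex capacities by
node splitting and the lower bounds by the standard reduction to node
demands with a super source/sink and a sink→source return arc — this keeps
all arc costs non-negative, which matters because the *compressed* network
can contain directed cycles and any negative-cost formulation (e.g. a
per-read routing bonus) would create negative cycles there. Costs are
scaled to integers at 10⁶ for the successive-shortest-path solver and the
objective is re-reported from the unscaled weights.

## 4. Compression and MultiSplice penalties

Reads with the same exon chain and mate role whose boundaries differ by at
most γ collapse into one cluster vertex (capacity = cluster size);
duplicated edges between cluster pairs that represent the same
splice-graph path collapse to one edge (weight = minimum of the
duplicates, capacity = their count). γ defaults to half the expected
fragment size; γ = 0 clusters exact duplicates only and is lossless, but
multiplies runtime by an order of magnitude at depth, so the default is
the practical choice for the depth study (the γ = 0 lossless identity is
verified on duplicate-only fixtures). The compressed network is built
directly — reads are clustered first and the quadratic between-fragment
edge set is collapsed group by group during construction — which is what
keeps memory linear at high coverage; the result is identical to
compressing an explicitly built network.

Edges whose exon path contains internal exons, and which no observed read
confirms by spanning all exons of the corresponding MultiSplice feature
`b`, are penalized by `−log(1 − ψ(b)/len(e))^{c_e}`, where the sampling
window `ψ(b)` counts the read start positions from which a read could span
`b`. When `ψ(b) = 0` no read *could* span the feature, non-observation is
uninformative and the penalty is zero — which means the penalty is inert
for features whose internal exons exceed the read length, a structural
limitation discussed below.

## 5. Flow decomposition

The optimal flow is decomposed into copies by repeatedly stripping the
maximum-bottleneck source→sink path with all its units at once
(deterministic; ties prefer the smaller vertex and cheaper edge). This
parsimony heuristic concentrates units on few distinct exon chains, so
upstream and downstream alternative-splicing choices stay paired the way
the bulk of the flow pairs them; stripping single units along
lowest-weight edges (available as `strategy = "cheapest"`) measurably
fabricates more rare combination chains. Cluster vertices are expanded
into member fragments in deterministic start order, a used-set guarantees
each fragment appears in at most one copy, and fragment sizes and gaps are
recomputed in transcript coordinates along the stitched chain (the ≤ 2γ
distortion of cluster-level lengths is accepted). Copies with identical
chains are grouped into isoform records whose terminal coordinates are the
outermost TSS/TES used by the chain's copies; `eT` counts only effective
copies, and chains with `eT = 0` are excluded from GTF output but kept in
the tables.

## 6. What the simulator does (and does not) emulate

The bundled simulator follows the three-step protocol: (1) assign each
isoform an independent copy number uniform on `{0..max_copies}` (default
20, giving a realistic dynamic range at desk scale); (2) cut copies —
drawn with replacement, weighted by copy number — by a uniform (Poisson)
breakpoint process with mean spacing `η` (default 200 bp) and retain
fragments inside the size window (default [150, 350] bp hard window; a
triangular acceptance is available); (3) emit perfect 2×75 bp mate pairs
from the fragment ends as coordinate-sorted SAM with N-gapped CIGARs, plus
a truth GTF carrying copy numbers. The random-annotation fixture generates
genes of 1–10 exons (80–500 bp, introns 200–2000 bp) with 1–4 isoforms by
skipping random internal-exon subsets.

Not emulated: sequencing errors and quality strings, multi-mapping,
positional/sequence bias, PCR duplicates, intron signal, or real gene
structures. Passing tests on these simulations therefore demonstrates the
correctness of the machinery and the behavior of the model under its own
assumptions — not performance on real libraries, where bias and mapping
noise will lower all metrics.

## 7. Numerical choices and degenerate inputs

Integer cost scaling at 10⁶ bounds the solver's rounding error per edge at
5·10⁻⁷; objectives are re-reported from unscaled weights. Path
enumeration between exon pairs is capped at 64 (deterministic order:
shortest spliced length, then lexicographic). Root-finding for the
effectiveness test brackets the upper density crossing by doubling.
Degenerate cases: fewer than 30 (or zero-variance) fragment sizes fall
back to a default model (η = 200, δ = 1.8) with a warning; loci whose
fragments cannot be embedded in any splice-graph path drop them with a
warning; an infeasible flow (impossible with the bypass and unbounded
terminal edges, but guarded) degrades to best-effort decomposition rather
than failing.

## 8. Known limitations

* **Combination chains.** Where several alternative-splicing events share
  a locus, copy identity across shared exons is unobservable; the flow can
  pair choices into junction combinations that no single molecule
  supports. The MultiSplice penalty only guards features short enough for
  one read to span, so with 75 bp reads and typical exon sizes most
  features are unguarded. On the depth-study simulations this caps
  precision around 0.6–0.7 and the eT-to-truth correlation around 0.75–0.8
  at 50-gene scale, whereas single-event loci (the two-isoform scenario)
  reconstruct exactly.
* **Short transcripts.** Copies of transcripts shorter than about twice
  the size-selection window consist of one fragment, so their `eT` scales
  with length where longer transcripts' does not; eTPM comparisons across
  that boundary inherit the distortion.
* **Gap model.** Gaps between retained fragments are sums of unretained
  pieces (with an atom at zero), which a single Weibull can only
  approximate; the half-base correction and truncated fit mitigate but do
  not remove this.
* **Strand.** Loci are processed in genomic orientation; minus-strand
  annotation only affects output labeling.
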