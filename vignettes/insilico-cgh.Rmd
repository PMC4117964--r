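---
title: "In silico CGH: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico CGH: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

In silico comparative genome hybridization (CGH) asks, for every annotated
region of a finished reference genome, whether a related query strain —
known only through short sequencing reads — still carries it. Reads are
mapped to the reference; a region that attracts essentially no reads is
inferred absent from the query. The unit of inference is the *segment*: the
reference is dissected into its annotated genes (protein-coding and RNA,
including tRNAs) and the intergenic regions (IGRs) between them. Each
segment is scored by its **coverage rate**, the percentage of its bases
covered by one or more mapped reads. Coverage *breadth* is the right
statistic here because presence/absence, not copy number, is the question:
a present gene at any reasonable depth is covered nearly end to end, an
absent one attracts almost nothing, and the resulting rate distribution is
sharply bimodal. Segments with a rate strictly below 20% are called
low-coverage-rate (**LCR**) and inferred absent.

Downstream, absent genes are characterized three ways: their clustering
(maximal runs of consecutive LCR segments containing at least two LCR genes
are candidate genomic islands; single LCR genes in a run are "independent"),
the mobile elements flanking each cluster (tRNA direct repeats, generic
direct repeats, same-family IS pairs — the classical signatures of
integration and excision), and their codon usage (GC3 and CAI, which run
low in horizontally acquired DNA relative to a high-GC host chromosome).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lcr_threshold` | 20 (%) | strict upper bound on the coverage rate of an absent segment; the published operating point, comfortably inside the bimodal gap |
| `seed_k` | 18 (bp) | exact seed anchoring a read before ungapped extension |
| `max_mismatches` | 3 (per 50 bp read) | full-read mismatch budget; tolerates ~1% sequencing error plus true strain divergence |
| `count_multimappers` | TRUE | multi-mapped reads count toward coverage; excluding them would spuriously flag multicopy genes (transposases!) as absent |
| `window` | 2000 (bp) | how far beyond each cluster end flank detectors look |
| `min_len`, `min_identity` | 15 bp, 0.85 | direct-repeat acceptance thresholds |
| `depth` | 20× | simulated fold-coverage; P(base uncovered) ≈ e^(−20) |
| `sub_error_rate` | 0.01 | per-base substitution error of simulated reads |

The mapper defines a hit as: some `seed_k`-mer of the read matches the
reference exactly, and the full-length ungapped comparison has at most
`max_mismatches` mismatches (both strands; `N` never matches). The seed
condition is part of the definition, not merely an optimization; the test
suite checks the implementation against a naive all-positions scan of the
same definition, and separately — where the pigeonhole guarantee applies
(one mismatch in a 50-mer leaves an exact run ≥ 25) — against the pure
mismatch-threshold scan. Gapped alignment is deliberately out of scope for
the built-in mapper; alignments from external aligners can be ingested via
SAM/BAM, where a base is covered iff a non-secondary, non-unmapped
alignment's reference-consuming blocks overlap it.

Coordinates are 0-based half-open internally; GFF3 and SAM are converted at
the boundary, and exported tables print 1-based starts.

## The local aligner and the direct-repeat detector

Flank classification needs a local aligner (the classical tool for this job
implements Smith–Waterman). The built-in aligner uses affine gaps with a
gap of length *L* costing `gap_open + L·gap_extend` (defaults +2/−3/−5/−2);
ties for the optimum break toward the smallest end coordinates. It is
verified against a plain-R dynamic program, against an exhaustive
substring-pair oracle, and against Biostrings' independent implementation.

A subtlety dictated the direct-repeat detector's design: the best local
alignment of two multi-kilobase windows reaches 15 columns at 85% identity
*by chance alone* — short micro-homologies are ubiquitous, and measured
false-positive rates under a naive length+identity rule exceeded 25% even
on uniform random sequence. The detector therefore also requires the
alignment score to reach the equivalent of `min_len` exact matches
(`score ≥ match · min_len`). A 15 bp exact repeat, or an 18 bp repeat with
one mismatch, passes; chance micro-homology does not (measured
false-positive rate ~1–3% on both random and simulated-genome windows).
tRNA-repeat hits and annotated IS features are masked out of the windows
before the generic search, so a tRNA- or IS-flanked cluster is not
double-counted as direct-repeat-flanked — the tabulation convention for
the flank-class table, and the reason planted flank styles are recovered
*exclusively* in the tests.

The tRNA detector flags a cluster when an annotated tRNA gene, or a copy at
≥90% identity over ≥70% of its length, lies within the window at **both**
ends in the same orientation. The IS detector requires annotated IS
features at both ends sharing a family label. Enlarging the window can only
add evidence, so true tRNA/IS flags are monotone in `window`.

## CAI construction

Relative adaptedness is computed from a designated reference gene set:
`w(codon) = count(codon) / count(most frequent synonymous codon)`, stop
codons excluded, zero counts floored at 0.01 so geometric means stay
finite. In real annotations the natural reference set is the ribosomal
proteins; the synthetic generator designates a "highly expressed" subset
for the same role. CAI is the geometric mean of `w` over a gene's codons,
excluding Met, Trp and stops (single-codon families carry no information).
When synonymous counts tie at the family maximum, all tied codons keep
`w = 1` (uniform usage gives all-1 weights) and the lexicographically first
is merely *designated* preferred in the weights table.

## What the synthetic generator emulates — and what it does not

The generator builds an alternating gene/IGR chromosome (geometric lengths,
minimums 90 bp and 30 bp; gene lengths rounded to codons), genes drawn from
a codon model with two knobs: a GC3 preference (default 0.80, realized GC3
≈ 0.9 as in high-GC actinobacteria) and a preferred-codon bias (default 2).
Foreign DNA uses the same machinery with the GC3 preference lowered by 15
percentage points and the bias removed, so the low-GC3/low-CAI signature of
acquired genes is recoverable by construction. Chromosomes are generated
linear but flagged circular by default (bacterial chromosomes are; the
wrap-around IGR is merged and coverage counts wrap accordingly). Reads are
emitted in nucleotide space with uniform starts, both strands, constant
quality, and independent per-base substitutions; read names record the
source position for provenance checks.

Query genomes are derived by excising runs of consecutive gene-kind
features (clusters of 2–12 genes, or isolated genes) and splicing foreign
gene blocks into IGRs; a truth manifest records every edit, the deleted
gene ids and the expected query size (`reference − deletions +
insertions`, asserted identically equal to the assembled length). Because
flank classification reads the *reference* around cluster ends, flank
elements for decorated deletions are installed into the reference's
flanking IGRs before queries are derived (`install_flank_elements()`): a
20 bp repeat, an unannotated copy of a real tRNA gene, or two annotated
same-family IS copies.

The default study (`make_demo()`) is a 200-gene reference with four
queries — no loss, 5%, 15% (clusters of 5/8/12 plus isolated genes, one
cluster per flank style) and 30% loss plus three 5-gene foreign
insertions — at depth 20 and 1% error. These sizes were chosen as the
smallest study at which every phenomenon of interest (bimodality, cluster
statistics, flank classes, codon contrast, size compensation) is present
and crisply measurable; plans scale proportionally for smaller demo
genomes. What the generator does *not* emulate: real repeat families and
paralogy (genes are unique sequences, so mapping ambiguity is limited to
the planted elements), indel sequencing errors, paired ends, plasmids,
compositional heterogeneity along the chromosome, and true inter-strain
divergence of *retained* genes (queries differ from the reference only by
the planted edits). Passing parameter-recovery tests therefore shows the
pipeline's logic is correct under its stated model, not that a 20%
threshold or a 3-mismatch budget is optimal for any particular pair of
real strains — on real data the bimodal gap should be inspected (the rate
histogram is produced for exactly this purpose).

## Numerical and degenerate-input choices

* Coverage counts are exact integers; rates are stored unrounded and only
  the exports round (4 decimals).
* The LCR comparison is strict (`rate < threshold`); a segment at exactly
  the threshold is present.
* Histogram bins are `[0,10) … [90,100]`, last bin closed.
* Reported percentages round to the nearest integer, ties away from zero
  (configurable to banker's rounding); values below 1 print two decimals so
  that tiny fractions stay visible. One published row (912/6774 printed as
  14) is consistent with no single rounding rule and is not reproduced.
* Overlapping genes are both kept as full segments; the gap between them
  yields no IGR. Zero-length gaps yield no segment.
* A non-LCR segment of any kind breaks a cluster run (strictest reading of
  "consecutive"); `igr_gap_tolerance` optionally bridges short covered
  IGRs for robustness studies. IGR-only LCR runs are recorded but form no
  cluster. On circular genomes runs joining across the origin are merged.
* Nonredundant clusters across queries are deduplicated by identical
  reference span; near-identical spans can optionally be merged at Jaccard
  ≥ 0.9.
* Venn partitions are computed over genes only, not IGRs.

## Known limitations

The built-in mapper is for desk-scale validation and moderately sized
genomes (k-mer index in memory); production mapping of tens of millions of
reads belongs to a dedicated aligner, ingested via SAM/BAM. Mapping
stringency of the original instrument software is unknown, so neither
multi-mapper behaviour (configurable) nor the mismatch budget claims to
replicate it. Flank detection inspects only the best-scoring local
alignment per window pair; multiple distinct repeats at one cluster end are
not enumerated. Expected genome size ignores partial segment loss by
construction (it subtracts whole LCR segments), which is also why
truth-recovery tests bound its error by the total length of
partially-covered boundary segments.
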