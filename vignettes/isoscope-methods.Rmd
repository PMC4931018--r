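---
title: "Methods: full-length transcript characterization with isoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length transcript characterization with isoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`isoscope` characterizes full-length transcript isoforms from long-read
genome alignments: redundancy collapse, structural classification against a
reference annotation, alternative-splicing mode calling, fusion detection,
a lncRNA filtering cascade, junction support scoring, splice-site and
metagene methylation profiles, and rarefaction. This vignette explains the
models and rules behind each stage, the parameters that matter, the design
choices made where the field's conventions are genuinely open, and what the
synthetic fixture does and does not establish about real data.

## Data model and coordinates

A transcript model is one row of a tibble with list-columns of exon starts
and ends. All internal coordinates are 0-based half-open; GFF3/GTF (1-based
inclusive) and the STAR junction dialect are converted at the I/O boundary,
so only one convention exists inside the package. A junction is the intron
`(chrom, strand, intron_start, intron_end)`; the donor is the transcript-5′
intron boundary (`intron_start` on `+`, `intron_end − 1` on `−`). Junction
identity for set operations is strand-agnostic by default because
short-read junction evidence often has unknown strand; a strict-strand mode
is available in the support scorer.

## Collapse

Reads are first filtered on alignment quality — kept iff coverage ≥ 0.85
and identity ≥ 0.90, both inclusive; missing values default to 1 so that
curated inputs pass unchanged and the filter stays orthogonal to parsing.
Multi-exon reads are then grouped by their intron chain. Because incomplete
reverse transcription truncates molecules from the 5′ end, the 5′ outer
boundary is never part of the identity key; the 3′ outer boundary is also
excluded by default (polyA-priming artifacts are the symmetric failure
mode), with `collapse_3prime = FALSE` available to keep it. Each group is
represented by its longest member (sum of exon lengths), ties broken by the
lexicographically smallest id, which makes the operation deterministic,
idempotent and independent of input order. Mono-exon reads have no chain,
so they merge by single-linkage reciprocal overlap of at least 50% of the
shorter read (configurable); a representative-longest rule applies there
too.

## Structural classification

Every collapsed isoform receives exactly one of eight categories by a
precedence ladder evaluated top-down:

1. **multi_gene (h)** — same-strand exon or splice-site sharing with ≥ 2
   distinct genes;
2. **full_match (c)** — intron chain identical to a reference transcript;
3. **partial_match (g)** — chain is a contiguous proper sub-chain of a
   reference transcript (internal boundaries equal, terminal outer
   boundaries free, mirroring the collapse tolerance);
4. **novel_isoform (b)** — shares ≥ 1 splice site (a single donor or
   acceptor coordinate, same strand) with an annotated gene;
5. **intronic (e)** — the read lies entirely inside an annotated intron, or
   an annotated transcript lies entirely inside one of the read's introns
   (the two subtypes are reported);
6. **exonic_no_ss (d)** — same-strand exonic overlap, zero shared sites;
7. **antisense (f)** — opposite-strand exonic overlap only;
8. **novel_locus (a)** — everything else.

The ladder settles the overlaps among the definitions: a full chain match
always also shares sites, so c must outrank b; a read merging two genes
matches chains of both, so h must outrank c or merged genes would be hidden.
The ladder is a total function — a read overlapping a gene's extent without
touching exons or sitting in a single intron falls through to novel_locus
with the extent overlap noted in its rationale string. Classification is
invariant under permutation of annotation records.

Split-gene candidates (tuples of adjacent gene ids suspected to be one true
gene) are `confirmed` when a multi_gene read spans all genes of the tuple,
and `partially_correct` when the annotation additionally contains a
transcript whose chain is a sub-chain of the merged read *and* whose extent
reaches across ≥ 2 of the candidate genes — the extra extent condition is
needed because each constituent gene's own chain is trivially a sub-chain
of the merged read.

Novel loci are grouped for gene counting by single-linkage same-strand exon
overlap. Feature-density tracks count midpoints in a 1-Mb window sliding at
20-kb steps; the window anchored at position *s* covers `(s − window, s]`.

## Alternative-splicing modes

Events are defined pairwise. The differing junctions of two isoforms are
clustered by genomic overlap within the shared extent, and each cluster is
matched against one template: IR (an intron of one isoform inside an exon
of the other), ES (two junctions vs their merged junction, skipped exon
internal), A5/A3 (one junction each, sharing exactly one boundary; which
mode applies follows from the strand), MXE (two junctions each, outer
boundaries shared, the two middle exons disjoint). A cluster matching no
template is reported as `OTHER` and excluded from the five-mode frequency
table, which keeps the table comparable across datasets. Terminal-exon
differences are not events, consistent with the collapse tolerance. Events
are deduplicated across pairs by `(mode, chrom, strand, detail)`.

Two dualities follow from the definitions and are enforced by tests:
flipping the strand of both isoforms (same coordinates) swaps A5↔A3 and
preserves IR/ES/MXE; mirroring all coordinates *and* flipping the strand is
the identity on transcript geometry and preserves every mode.

## Junction support and motifs

A junction is supported in a tissue iff the evidence holds the identical
intron (exact coordinates, no tolerance window — both aligner dialects
report exact introns, and a fuzzy match would inflate support) in the same
tissue with at least `min_reads` (default 1) reads. The headline rate is
the macro-average over tissues, matching the convention of averaging
per-tissue rates rather than pooling junctions. Splice motifs are the two
intronic bases at each boundary read 5′→3′ on the transcript strand;
anything outside the six named classes (GT/AG, GC/AG, CT/AC, CT/GC, GT/AT,
AT/AC) counts as `other`.

## Fusion transcripts

Multi-locus alignments of one read are first merged into loci: same
chromosome, same strand, genomic gap < 100 kb. Four criteria are then
evaluated — ≥ 2 loci; every locus ≥ 10% of the read; the union of the
loci's read intervals ≥ 99% of the read (union, so overlapping segments
cannot inflate coverage); all locus pairs on different chromosomes or
≥ 100 kb apart, measured as the extent gap between closest edges, applied
to all pairs. A candidate passes iff all four hold. For passing candidates
the breakpoint-adjacent genomic boundaries (exon-end edges against known
intron starts, exon-start edges against known intron ends) are compared
with the splice sites of the non-fused transcript set: exact agreement at
every breakpoint is the signature of splicing-mediated fusion. Validation
requires at least one uniquely-mapping evidence record — a discordant read
pair or a split junction-spanning read — whose two segments fall in two
different loci of the candidate.

## lncRNA cascade

Candidates pass four stages in a fixed order, each stage seeing only the
survivors of the previous one: length ≥ 200 nt; longest ORF ≤ 100 codons
(an ORF is `ATG … stop` in any of six frames, a stop is required, and the
reported length is the translated amino-acid count — ATG included, stop
excluded, so exactly 100 codons passes and 101 fails); no hit to a grass
proteome at e ≤ 1e−10; no hit to a known-lncRNA set at e ≤ 1e−10 with
identity ≥ 0.90 and coverage ≥ 0.85. An external coding-potential
classifier is deliberately not re-implemented; a pre-computed candidate
set can simply be supplied as the input. Survivors are positioned relative
to the annotation with precedence sense → antisense → intronic →
intergenic; "intronic" accepts either strand. A transcript overlapping a
gene extent without exon overlap or single-intron containment falls
through to intergenic with an `extent_overlap` flag, since the four-class
scheme has no residual label.

## Methylation profiles

The level at a cytosine is `C/(C+T)`; zero-depth sites are undefined and
excluded. Deduplicated junctions are stacked in transcript orientation
(`−` junctions coordinate-mirrored): donor positions −50…−1 are exonic and
+1…+50 intronic, acceptor positions mirrored. Pooling is count-weighted
(`ΣC / Σ(C+T)`), not a mean of per-site ratios, so low-depth sites cannot
dominate; a minimum per-site depth is configurable (default 1). Cytosine
strand is recorded relative to the transcript (sense/antisense) and a
combined track carries exactly the summed counts. Positions whose base is
fixed by the splice motif (e.g. donor +2 is always T) can hold no cytosine
and are reported as `NA` cells. Gene-level strata are 1, 2–10 and ≥ 20
isoforms; genes with 11–19 isoforms belong to no stratum and are reported
aside. Metagene profiles map 1-kb flanks and the transcript body to 100
bins each in transcript orientation with fractional bin edges, so bodies
shorter than 100 bases are assigned proportionally rather than skipped.

## Rarefaction

Rarefaction samples reads without replacement (true rarefaction semantics)
at each depth and counts distinct units, averaged over replicates. The
closed form
`E[distinct] = Σ_i (1 − C(N − n_i, k)/C(N, k))`
is implemented separately (`rarefaction_expectation()`) and used as an
analytic check; computation uses `lchoose` for numerical stability.

## The synthetic fixture

`simulate_dataset()` emulates the structure of a multi-tissue long-read
isoform survey at desk scale and carries complete planted truth. Defaults:
3 chromosomes × 600 kb of i.i.d. uniform sequence; 60 genes with 4–7 exons
(exons and introns ≥ 110 bp so the 50-bp methylation windows stay
disjoint; one intron ≥ 360 bp per gene to host containment plantings) plus
a few short mono-exon genes; isoform counts drawn from strata 1 / 2–10 /
≥ 20 with weights 0.44/0.46/0.10 (roughly the observed split between
single- and multi-isoform genes in large isoform surveys); extra isoforms
built only from exon-skipping and intron-retention edits of the primary
isoform so every annotated junction reuses a motif-bearing splice site;
GT..AG written into every intron (GC..AG for a configurable fraction of
donors, decided per donor site so isoforms stay consistent). Twenty-five
reads are planted per structural category, each constructed to satisfy
only its category under the ladder; intron-containment plantings use
introns that no isoform covers with an exon (intron-retention variants
otherwise turn "intronic" into "exonic overlap"). The AS mode mix defaults
to IR 0.40, A3 0.19, A5 0.18, MXE 0.152, ES 0.078 — IR predominating and
exon skipping rare, as in plant transcriptomes; the A5/MXE split is the
package's own choice where only IR, A3 and ES shares are commonly quoted.
Fusion plantings pair transcript halves cut at annotated splice sites
(24 true; 9 decoys per violated criterion; 6 breakpoint-shifted decoys
that pass all four criteria); separation decoys use opposite-strand
neighbours because same-strand loci under the merge gap would merge and
violate criterion (a) instead of (d). Fusion validation truth is computed
by a post-pass over the emitted paired evidence, since fusions sharing a
gene pair legitimately validate each other. Junction evidence covers each
(tissue, junction) with probability 0.9 and `1 + Poisson(5)` reads.
Methylation covers every genomic cytosine on both strands at depth 20 with
background 0.2 in all contexts, donor-window CG 0.5 and acceptor-window
CHG 0.6 planted on the intron side of the windows. lncRNAs are planted in
the four positional classes (12/5/4/2 — intergenic-dominant, as observed
for plant lncRNAs) with decoys failing exactly one cascade stage each;
non-coding sequences are engineered by iterative stop-codon injection,
verified by an independent translate-and-scan check and avoiding splice
motif bases.

What passing on this fixture shows: the rules are implemented exactly as
specified, recover planted structure perfectly in the absence of noise,
and are deterministic, order-independent and correctly calibrated where
the planting is stochastic (support fraction, methylation levels,
rarefaction). What it does not show: robustness to alignment errors around
splice sites, non-uniform base composition, overlapping genes, soft-clip
artifacts, or annotation errors other than split genes — real data contain
all of these, and the quality filter plus exact-match contracts are the
only defenses the pipeline provides.

## Problem sizes and determinism

The test suite and the acceptance script run the full fixture (≈ 390
annotated transcripts, ≈ 310 reads, ≈ 1,000 distinct junctions, ≈ 0.9 M
cytosines) in a few minutes on one CPU; the methylation recovery check
uses a denser 150-gene fixture so that each profile cell pools enough
counts for a ±0.02 comparison. Every stochastic step draws from a stream
seeded from the single master seed (per-stage offsets), so identical
configurations produce byte-identical files and `run_pipeline()` reruns
are byte-identical including the JSON summary.

## Known limitations

* Classification compares coordinates only; sequence similarity plays no
  role, so paralogous loci are distinguished purely by position.
* Pairwise event calling underreports genes whose isoform differences
  compose several modes in one region (reported as `OTHER`); a splice-graph
  model would resolve these.
* The fusion criteria are rule-based and have no statistical error model;
  the short-read validation counts records but does not test significance.
* The lncRNA cascade implements the length/ORF/homology filters only; a
  machine-learned coding-potential score, if desired, must be applied
  upstream and its survivors supplied as the candidate set.
* Methylation profiles are descriptive; no test of differential
  methylation between strata or groups is provided.
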