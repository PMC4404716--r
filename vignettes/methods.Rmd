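---
title: "Methods: haplotype-aware SNP mining and array design in polymine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-aware SNP mining and array design in polymine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polymine re-creates, at desk scale, the computational path from pooled
RNA-Seq reads of highly heterozygous polyploid individuals to a
genotyping-array manifest, together with an orthology-guided assembly of a
non-redundant transcriptome against the proteome of a related sequenced
species. This vignette records the models and conventions behind each
stage, the parameters that matter, what the synthetic data generator does
and does not emulate, and the design choices made where the procedure left
room.

## The problem setting

Commercial roses are tetraploid and highly heterozygous: each individual
carries up to four haplotypes per gene, and a mapping population of two
parents pools up to eight. SNPs mined from expressed sequences are
attractive array content (they sit in genes and transfer across
germplasm), but three artifacts corrupt naive variant calling in this
setting: paralogous genes collapse into one reference contig and their
fixed differences masquerade as alleles; chloroplast transcripts
contaminate the hybridisation; and probes spanning exon-exon junctions
fail on genomic DNA. The pipeline addresses each with an explicit,
testable filter.

## Read preparation

`prep_reads()` applies, in order: a 10-nt 5' head trim (random-hexamer
priming bias), ends-in quality trimming at phred 25 (the maximal interval
whose boundary bases pass; interior bases are never masked), poly-A/T
tail removal (minimum run 5 — short genuine A/T runs are left alone; the
length is not part of the published procedure, so it is a package
default), DUST low-complexity removal (classic triplet score, window 64,
threshold 7), a minimum length of 50 nt (100 for long single-end reads),
at most one ambiguous base, and duplicate removal by exact sequence
identity. Pairs are then overlap-merged (minimum overlap 10, mismatch
rate at most 0.1, conflicting bases resolved by quality); merged pairs
and orphaned mates continue as single-end reads, intact pairs as pairs.
All filters after the head trim are idempotent, which the test suite
checks on random reads.

Quality trimming is offered 3'-only as well (`quality_trim_mode`); the
default trims both ends, matching tools that remove terminal low-quality
bases.

## Alignment kernels

All stages share one seeded affine-gap local aligner (match 2, mismatch
-3, gap open 5, gap extend 2; BLOSUM62 in protein mode; a gap of length L
costs open + L·extend). Database search seeds on shared k-mers (k = 12
nucleotide, 4 protein), clusters seed diagonals, and runs banded dynamic
programming around each cluster; the test suite proves score equality
with an independent exhaustive-DP implementation on short sequences.
E-value cut-offs are replaced by presets — `loose` (identity ≥ 0.80 over
≥ 50 columns), `standard` (0.85/60), `strict` (0.90/100) — because
e-values depend on database size and scoring-statistics parameters this
artifact does not model.

Read mapping reports a mapping-quality surrogate
`min(60, round(-10·log10 p))` with `p = 10^(-0.3 (s1 - s2))` from the
best and second-best candidate scores: a unique exact hit scores 60, a
perfect tie 0, and two diagnostic bases against an 85%-identity paralog
clear the downstream `mapq > 25` filter. A unique but poorly scoring
alignment is not trusted: when the best alignment has identity below
0.97 (about where an end-to-end aligner's unique-hit confidence falls
through the `> 25` filter, at 3-4 mismatches per 100 bp) or covers less
than 90% of the read, the mapq is capped at 20. This matters in one
concrete scenario: when a paralog's 5'
end is missing from the assembly, its reads would otherwise cross-map
onto the partner contig at ~92% identity with no competing location and
manufacture a dense block of false SNPs.

The assembler is a greedy overlap-layout-consensus: dovetail or
containment overlaps on either strand of length ≥ 40 at identity ≥ 0.97
(the 97% mirrors the reference-assembly overlap setting) are merged
best-overlap-first; the consensus takes the per-column majority with ties
to the lexicographically smaller base. The layout is ungapped — offsets
come from the overlap alignments — which is exact for the
substitution-level divergence the generator plants and approximate in the
presence of indels.

## Transcript selection

Reads are mapped to the individual's own transcripts; a read counts as
mapped to a transcript only when it aligns near-end-to-end (≥ 90% of the
read) at identity ≥ 0.95, as an end-to-end transcript mapper would
report. Transcripts sharing a tied multi-mapped read form a component;
within each component, transcripts attracting strictly less than 1% of
the component's reads (IsoPct < 1, multi-mapped reads split equally) are
dropped, and of the remainder only the most abundant survives (ties to
the longer transcript, then the smaller id). Both steps are separately
switchable because the published wording leaves open whether the
most-abundant rule was applied universally. The end-to-end condition is
load-bearing: clipped local alignments of a read that crosses a fragment
boundary tie exactly between two overlapping partial transcripts and
would otherwise weld fragments of one gene into a single "isoform
component".

Retained transcripts are screened against contaminant proteins in
translated mode at the `standard` preset; flagged transcripts are removed
and their mean identity reported.

## Reliable SNPs

Per sample set, the individuals' retained transcripts are assembled into
a reference at 97% overlap identity, all reads of the set are mapped, and
alignments with mapq ≤ 25 are discarded. A position is a candidate when
two distinct unambiguous bases each carry ≥ 5 reads. Reads are collapsed
to their allele profiles over candidate positions and clustered
agglomeratively; two clusters may merge while their consensus alleles
agree on at least 80% of shared covered positions (`sim_min = 0.8`), and
clusters with fewer than two reads are discarded as noise.

Two conventions here are the package's own and deserve emphasis:

* **Comparability.** Profiles sharing at least one covered candidate
  position are comparable (`min_shared_sites = 1`). Requiring two shared
  sites would leave every transcript with a single polymorphic site — and
  any pair of sites further apart than a read — unclusterable, which
  contradicts the expectation that an ordinary heterozygous SNP at 30×
  on two haplotypes is called reliable.
* **The haplotype ceiling is counted per site.** With ~0.5 SNPs per
  100 bp and 100-nt reads, candidate sites frequently cannot be phased
  against each other: summing clusters across a transcript counts
  regional fragments of the *same* haplotype several times and pushes
  perfectly normal tetraploid transcripts past the ceiling. The
  transcript's observable haplotype count is therefore the maximum number
  of strong clusters (at least `min_reads_per_allele` reads - the same
  confidence floor the allele rule uses; smaller clusters are treated as
  noise, not as evidence of an extra haplotype) covering any single
  candidate site. Fragments of one haplotype never co-cover a site, so
  they cannot double-count; a paralog-collapsed contig stacks the cluster
  sets of both genes on the same dense divergent sites and still exceeds
  the ceiling. Transcripts whose count exceeds `ploidy × n_individuals`
  (8 for two tetraploid parents; pooled panels default to the same
  product, configurable) lose all their SNPs.

A candidate is reliable when each of its two most frequent alleles has
≥ 5 reads and is the consensus allele of at least one surviving cluster.
Density (SNPs × 100 / length), transition fractions and the
SNPs-per-transcript histogram are reported per set.

## Marker design

The cascade runs in a fixed order and logs every SNP into exactly one of
the manifest or the rejection log: context extraction (35-nt flanks free
of other candidate SNPs, deletion columns with ≥ 5 supporting reads, and
ambiguous bases; SNPs within 35 nt of a transcript end are rejected);
removal of strand-ambiguous A/T and C/G SNPs (identical on both strands,
they would need twice the probes); the paralog filter (the source
transcript searched against its own reference; the self-hit counts, so
any second hit — "two or more" — discards the marker, with a flag to
ignore the self-hit; the default gate is the `standard` preset because
the e-value criterion this surrogate replaces flags a 92%-identity
paralog sharing even a few hundred bases with enormous margin, whereas a
0.90 identity cut sits within sampling noise of such a pair); the chloroplast screen (71-mer context vs
the chloroplast genome at `loose`; any hit fails); the splice screen
(context vs the genome at `loose`; a best hit aligning fewer than
`ceil(0.95 × 71) = 68` contiguous bases indicates an exon junction; no
hit passes; a flag sums across hits instead); cross-set redundancy
removal (identical context — on either strand — and alleles; priority
follows the configured set order, mirroring the listing order of the
sample sets); and the probe-similarity screen (non-identical contexts
aligning at ≥ 0.90 identity over ≥ 60 columns interfere during
hybridisation; the lower-priority marker is dropped). Insertion evidence
inside reads is not tracked as a variant class — only substitution
candidates and deletion columns disqualify flanks — a limitation that is
immaterial for substitution-dominated short-read data.

The manifest assigns `{set}_{transcript number}_{SNP number}` identifiers
and two probes per SNP, one per strand, so the probe count is exactly
twice the marker count.

## Orthology-guided assembly

All retained transcripts are searched against the guide proteome in six
translated frames (stops split frames into segments, so alignments never
cross a stop) and grouped under their best-scoring guide (`loose`;
grouping and the reciprocal check are deliberately on different presets —
the published procedure used a permissive search to collect candidates
and a stricter criterion to accept them — both configurable). Groups with
one member are discarded as singletons. Each group assembles at the
default overlap parameters; each contig is kept only when its top hit
against the whole proteome is the original guide (ties drop the contig
as ambiguous). The longest ATG-to-stop ORF over six frames (a stop-to-stop
mode is available; "full-length coding region" implies a start codon, so
ATG is the default) defines the coding sequence; UTRs are trimmed and the
trimmed sequences reassembled into finals named `{guide}.m{k}` by
descending length. A final is full-length when it starts with ATG, ends
with an in-frame stop, and its translation covers ≥ 90% of the guide
protein (`flcov`, the package's quantification of "appeared to contain
the full-length coding region"). External annotation joins by guide
protein id; duplicate keys are an integrity error.

## The synthetic truth set

`make_truth()` builds, under one seed: gene models with UTRs, a coding
sequence and 1-4 exons on a toy genome (introns 80-250 bp); planted SNPs
at density 0.005/bp with 60% transitions, assigned to the pooled
haplotypes by rejection-sampled presence patterns (never monomorphic);
per-individual consensus transcripts and their *presentation* — one full
transcript, 2-3 overlapping fragments ("tiled"), or fragments missing the
5' start including the ATG ("truncated", never full-length); paralog
partner genes at 92% identity with coding frames preserved; exon-skipping
isoforms at 10% of a gene's reads; chloroplast decoy windows with
between-individual variants; fungal contaminant proteins with
back-translated, 2%-diverged decoy transcripts; a guide proteome at 5%
amino-acid divergence; and singleton genes expressed in one individual
only. `simulate_reads()` draws uniform-start fragments per haplotype
(Gaussian insert 200 ± 40, per-base substitution errors, a 3'-decaying
quality profile) or long indel-biased single-end reads for the 454-like
regime.

Several generator choices keep the planted truth interpretable rather
than adversarial: fragment overlaps are 40-45 bp (at the assembler
minimum but below the shortest read surviving the length filter, so
fragments of one gene never tie-multimap and are not spuriously treated
as isoforms); isoform decoys are planted only on genes whose main
transcript is present in one piece (so the most-abundant rule has a
well-defined intended winner); chloroplast windows do not overlap
(distinct plastid loci are not isoforms of each other); paralog partners
carry exactly `round((1 - identity) × L)` substitutions, rejection-sampled
so no conserved run exceeds 80 bp (a fixed count keeps the planted
divergence at its declared value, and an identical stretch longer than a
read would let reads tie-multimap across two *genes*, which the
shared-read component rule - a surrogate for graph-based assembler
components - cannot tell apart from isoforms); and truncated
presentations remove 60-200 nt of coding sequence, not just the start
codon, so the not-full-length truth label is unambiguous. The generator does *not* emulate
realistic expression-level variation, fragmentation or GC bias, quality
mis-calibration beyond a flat error rate with 3' decay, or
allele-specific expression — so passing recovery tests demonstrates the
correctness of the pipeline's logic under its stated assumptions, not
robustness to every artifact of real libraries.

Default scale: 100 genes of ~1 kb, two tetraploid individuals, 30× per
haplotype coverage (about 130 thousand read pairs), 0.5% error. A full
pipeline run on this configuration takes a few minutes on one CPU; the
test suite uses 6-12 gene configurations for everything except the
end-to-end recovery check.

## Numerical conventions

Coordinates are 0-based half-open everywhere internally; 1-based appears
only in SAM POS and VCF POS on output. Sorting and tie-breaking use C
(radix) collation throughout so that runs are byte-identical across
locales; consensus ties go to the lexicographically smaller base; hit
ties to the lexicographically smaller subject id; agglomeration merges
the highest-similarity pair with ties to the smaller cluster index. All
randomness flows from R's RNG under the configured seed, including inside
the compiled kernels, so a fixed seed reproduces every output byte for
byte.

## Known limitations

The ungapped assembly layout and the absence of an insertion variant
class make the pipeline approximate for indel-rich long-read data (the
454-like regime is supported for read preparation and mapping, but indel
calling is out of scope by design — indels only disqualify marker
flanks). The haplotype ceiling is a per-transcript, per-linkage-block
count and cannot detect paralogy when the collapsed copies differ at
fewer than two phaseable sites; such markers are instead caught by the
self-search paralog filter downstream. Probe thermodynamics,
array-manufacturing constraints and genotype dosage calling are outside
the package's scope.
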