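---
title: "Methods: comparative plastome analysis and heteroplasmy quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis and heteroplasmy quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastotyper)
```

# The problem

Some plant species carry two distinct chloroplast genome types (cytotypes)
segregating among individuals. The two types differ at a set of fixed
point mutations and small indels — the *diagnostic loci* — and sometimes
at short structural rearrangements such as an inversion of a few hundred
base pairs. Deep whole-genome sequencing reads the plastome at thousands
of fold coverage, which makes two analyses possible that shallow data
cannot support:

1. assembling and comparing the *major* plastome of each individual
   (SNPs, indels, inversions, haplotype groups, nucleotide diversity), and
2. detecting a *minor* cytotype hiding inside an individual at a few
   percent frequency — heteroplasmy — by reading allele fractions at the
   diagnostic loci from filtered base counts.

plastotyper implements both layers plus a seeded synthetic-data generator
that reproduces the statistical structure of such a study, so that every
stage is testable without any external download.

# Genome comparison

## Quadripartite structure

A plastome is circular with a large and a small single-copy region (LSC,
SSC) separated by two inverted repeats (IRa, IRb) that are reverse
complements of each other. `detect_quadripartite()` finds the maximal
pair of disjoint exact reverse-complement repeats by k-mer seeding of the
genome against its own reverse complement: a repeat pair forms a run of
seed matches at constant diagonal offset, so maximal exact repeats fall
out in near-linear time. Candidate arms are then extended base-by-base
across the linearization origin (the molecule is circular), and ties
between maximal pairs are broken by minimizing the SSC, which matches the
conventional naming of the regions. Exactness (`max_mismatch = 0`) is the
default because IR copies are essentially invariant within a species; a
small substitution tolerance can be allowed, implemented by merging
same-diagonal seed runs.

## Anchors, variants, inversions

`anchor_align()` aligns two assemblies by k-mers (default `k = 31`) that
occur exactly once in *each* genome, counting both strands. Counting both
strands automatically removes the IR interior from the anchor set (each
IR k-mer occurs twice per genome), so chaining never places an anchor
inconsistently between the two IR copies; the IR interiors are instead
compared copy-to-copy by position as big anchor gaps. Runs of collinear
anchors (same orientation, consistent spacing) become forward or inverted
blocks; the default `max_gap = 35000` is chosen to span a full plastome
IR.

`call_variants()` compares the unanchored gap between each pair of
consecutive anchors in a forward block: identical gap pairs are skipped
(this silently disposes of the identical IR interiors), pure
insertions/deletions are emitted directly, and differing pairs are
realigned with an affine-gap Needleman–Wunsch (match +1, mismatch −2, gap
open 4, gap extend 1 — values chosen so that indel placement is canonical
after left-normalization). Two subtleties matter for exactness:

* an anchor can reach *into* an indel when the event's first bases
  coincide with the reference continuation; the flanking anchors then
  overlap on one genome, and the overlap is un-claimed from the left
  anchor before alignment so that no position is lost;
* all indels are left-aligned against the reference within their
  homopolymer/repeat context, giving a unique representation and
  deterministic counting.

Runs of adjacent substitutions are counted as separate SNPs (one
reporting flag merges them into MNPs). Equal-length gap pairs longer than
the alignment bound are compared position-by-position; unequal long pairs
raise an error naming the interval.

Inverted blocks are excluded from variant calling and become inversion
calls (`detect_inversions()`), each with its interval on both genomes.
Because plastome inversions are typically mediated by short inverted
repeats (often paired tRNA genes) at their boundaries, the flanks of each
call are searched by locally aligning the upstream window against the
reverse complement of the downstream window, and the repeat is reported
with its percent identity. One representational caveat: if the bases
immediately flanking an inversion are complementary, the inverted
interval is not unique (shifting both ends by one gives the same
sequence); the detector reports the maximal representation, and the
synthetic generator avoids placing inversions at such ambiguous
boundaries.

## Coding effects

`annotate_effect()` rebuilds the affected codon in transcription
direction — strand-aware, exon-joined, honoring `codon_start` — and
translates reference and alternate codon. Genes flagged as using an
alternative ACG/GTG initiation translate codon 1 as Met, as plastid
C-to-U editing and non-AUG initiation imply. Effects are reported as
`synonymous` or `XnY` (residue `n` changes from `X` to `Y`). A CDS whose
length is not divisible by three errors unless flagged as a pseudogene.
The test suite checks every position of toy genes on both strands against
an independent oracle that translates the whole protein before and after
the substitution and diffs the result.

`classify_region()` assigns `CDS` to positions in protein-coding exons
and `intron` to positions inside a gene's span but outside its exons.
Positions inside tRNA/rRNA exons are neither protein-coding sequence nor
intron, and are deliberately reported as `intergenic`; surveys of
plastome variation conventionally count "coding" as protein-coding.

# Microsatellites

`find_ssrs()` reports maximal perfect tandem repeats with a primitive
(minimal-period) unit of 1–6 bp, at the conventional plastome thresholds
of 10, 6, 5, 5, 5, 5 complete units for mono- through hexanucleotide
motifs. A repeat qualifying under two unit lengths (a poly-A run also
matches period 2) is reported only at its minimal period. Runs separated
by at most 100 bp merge into a compound SSR that counts once in totals.
The reported end covers complete units only. The scanner is
property-tested against an explicit O(n²·6) enumerator on random strings.

# Population summaries

Nucleotide diversity per site (π) between two aligned sequences is the
proportion of differing sites among sites where both carry an unambiguous
base (pairwise deletion: gaps and N drop out of numerator and
denominator). `sliding_window_pi()` averages this over all unordered
sample pairs in windows of 1200 bp advanced by 400 bp — the conventional
window layout for plastome diversity scans — with windows laid out from
position 1 and a trailing partial window dropped. Structural differences
are masked, not realigned: an inversion region contributes mismatches
that are not point mutations, so it is listed as an excluded interval.

Distances use the Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)p)`
(valid for `p < 0.75`; larger p errors, naming the pair), and the tree is
neighbor-joining via ape with taxa sorted lexicographically so ties break
deterministically. NJ on additive distances recovers the generating tree
exactly, which the tests assert; only topology-level claims (the
two-cytotype bipartition) should be read from such a tree.
`build_haplotype_table()` collapses samples with identical allele vectors
over the union of variant loci into haplotypes and can flag alleles
private to one cytotype group.

# Heteroplasmy

A mixed-cytotype individual shows the alternate cytotype's alleles at a
roughly constant low frequency across *all* diagnostic loci, while two
artifacts mimic that signal locally: sequencing/alignment error, and
reads from nuclear or mitochondrial copies of plastid DNA (NUMT/mtpt
inserts) that diverged from the plastome. The estimator defends against
each in turn:

* **Quality and strand filtering** (`filter_basecounts()`): reads at or
  below Phred 20 are discarded ("above 20" is read strictly), and at each
  locus an allele seen on only one strand has both its strand counts
  zeroed — strand bias is the signature of a local alignment artifact.
* **Per-locus minor frequency** = minor-type allele count / filtered
  depth. The summary statistic is the **median** across loci, robust to
  the few loci disturbed by insert homology; the mean is reported
  alongside.
* **Consistency**: heteroplasmy is called only when the summary reaches
  the 2% screening cutoff *and* the minor allele is visible at ≥ 90% of
  loci. Visibility is judged at half the cutoff: a mixture sitting
  exactly at the cutoff leaves ~half its loci below the cutoff by
  binomial noise alone, so requiring the full cutoff at 90% of loci would
  reject genuine 2% mixtures by construction. The reported
  `fraction_of_loci_supporting` still counts loci at the full cutoff.
* **Depth-ratio guard** (`numt_guard()`): a genuine minor plastome is
  sequenced at plastid depth (hundreds-fold), an insert at its host
  compartment's depth (tens-fold). Calls whose minor-allele mean depth is
  below 3× the nuclear depth are downgraded to `ambiguous`. Known insert
  intervals can also be masked outright.

With 0.2% per-base error spread over three off-target bases, the error
floor at a locus is ~0.07% — forty times below the 2% cutoff — which is
why the false-positive control in the test suite observes zero calls in
200 error-only replicates at 8000× depth.

# The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs: a
161,537 bp genome at 36% GC with 30,896 bp IRs and a 13,632 bp SSC; 105
diagnostic SNPs and 36 diagnostic indels (1–10 bp, outside exons — coding
indels would frameshift and are not observed between cytotypes) plus one
230 bp inversion in the LSC; 25 intra-type subgroup variants; 8,175×
plastid depth with 0.2% error and ~45× nuclear depth. Implanted events
keep 40 bp mutual spacing, sit only in single-copy regions (the IR pair
must stay an exact repeat in both genomes), and indel/inversion
placements are rejected when their left-normalized/boundary-canonical
representation would differ from the implanted one, so implant-and-
recover tests can demand exact equality.

The default population specification realizes 43 samples in 15
haplotypes: 7 identical second-cytotype individuals, and 36 first-
cytotype individuals in 14 subgroups (one reference-identical; an
18-sample clade sharing three SNPs with nested subgroups; several
singletons), drawing on 17 subgroup SNPs and 8 subgroup indels. The
subgroup sizes were chosen once to emulate geographically structured
intra-type variation; with the inversion masked, the closed-form expected
genome-wide π of this design is ≈ 2.0 × 10⁻⁴ (each locus contributes
`c(N−c)/(N choose 2)/L` with `c` carriers among `N = 43` samples), and
the simulated population is asserted to match that closed form — the
generator emits the alignment directly from its truth set, so agreement
is essentially exact.

Base-count profiles draw allele counts from a multinomial with
probabilities `(1−f)(1−e)`, `f(1−e)` and `e/3` leakage per off-allele,
split counts binomially between strands, and thin a configured fraction
(default 5%) below the Phred filter so the quality filter has something
to do. An optional insert background adds nuclear-depth reads of the
minor allele at chosen loci for testing the guard.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mapping bias and soft-clipping artifacts around
indels, coverage heterogeneity along the genome, PCR duplicates,
within-read error correlation, heteroplasmy varying across loci, and any
real phylogeographic signal beyond the programmed subgroup structure.
Deposited-genome checks (running the pipeline on real accession records)
are wired into the acceptance test and run whenever the records are
placed under `inst/extdata/deposited/`; they are not distributable with
the package.

# Numerical and interface choices

* Coordinates are 1-based inclusive everywhere a user sees them (GenBank
  convention); conversions are confined to the IO layer.
* Ambiguity codes other than N are rejected at parse time — none occur in
  scope, and failing loudly beats silent miscounting.
* On-disk formats are plain TSV/FASTA/GenBank/newick; the base-count
  dialect stores quality-passing counts only, with sub-threshold counts
  carried in memory by the simulator.
* All generators are seeded and bit-reproducible; the pipeline writes no
  timestamps, so re-running a config reproduces outputs byte-for-byte.
* Problem sizes in the test suite: most module tests run on a 24 kb
  genome (5 kb IRs) with 15+6 implanted events, which exercises every
  code path; the acceptance tests run one full-size (161.5 kb, 105+36
  events) pair and population, where the implant-recover, haplotype,
  bipartition and closed-form-π checks take well under a minute each.

# Known limitations

* The anchor chainer targets near-identical genomes of the same species;
  it is not a general whole-genome aligner and does not model nested or
  overlapping rearrangements.
* Only the maximal IR pair is reported; IR expansion/contraction analysis
  across species is out of scope.
* The NJ tree is a distance-based stand-in suitable for topology-level
  statements; branch supports and model-based estimates are not provided.
* Heteroplasmy estimation requires cytotype-diagnostic SNP loci; indel
  frequencies are deliberately excluded (their base-count representation
  is unreliable).
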