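---
title: "Curating full-length cDNA collections: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating full-length cDNA collections: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A full-length cDNA collection starts as tens of thousands of clone reads
and ends, after curation, as a non-redundant set of transcripts that each
carry a complete coding sequence (an "nrFLcDNA" set). Between those two
points sit a series of decisions that are individually simple but easy to
get subtly wrong: which reads are vector or junk, which clones are
5'-truncated copies of one another, which inserts are chimeric ligation
artifacts or contaminant transcripts (non-coding RNAs, pathogen mRNAs from
infected source tissue), which apparent isoforms merely retain an unspliced
intron, where the true CDS and UTRs sit, and — once a draft genome exists —
what the collection says about exon/intron structure, alternative splicing
and cultivar-level sequence divergence.

`flcdna` implements that pipeline end to end, and pairs it with a seeded
synthetic-data generator that emits a toy genome, gene models, isoforms and
clone libraries **with complete truth tables**, so that every stage can be
verified exactly without any external data. The package's test-suite is
organized around that idea: planted artifacts must be recovered with
precision and recall 1 on noiseless data, and planted rates must be
recovered within their sampling bands on noisy data.

## The alignment layer

All similarity decisions go through one scoring model: Smith–Waterman local
alignment with affine gaps (default +1/−3, gap open 5, extend 2 for
nucleotides; BLOSUM62 with 11/1 for proteins), with E-values from
Karlin–Altschul theory. `ka_calibrate()` solves
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ for $\lambda$ and approximates
$K$ by the classical ungapped series over partial-sum distributions,
truncated at 60 terms (the terms decay geometrically; the truncation error
is far below the precision any threshold here needs). For the default
nucleotide scheme this yields $\lambda = 1.374$, $K = 0.711$. E-values use
raw sequence lengths $m \cdot n$, one best alignment per sequence pair. They
are internally consistent rather than identical to any particular BLAST
build; every threshold taken from them (1e-180 for redundancy and ncRNA,
1e-50 for grouping and chimera hits, 1e-30 for pathogens, 1e-10 for protein
homology) is a configuration knob with those defaults.

Quadratic alignment of every pair would dominate the run time, so a
shared-word prescreen (exact k-words, k = 12–14 for DNA and 5 for protein)
gates which pairs are aligned, with an occupancy cap that drops
uninformative words — poly(A) words in particular. This plays the role that
seeding plays in BLAST; the thresholds are set low enough that any pair that
could satisfy a downstream rule shares dozens of words.

## The spliced aligner

Transcript-to-genome alignment uses a local dynamic program with three
affine-gap states plus an intron transition: a genomic jump of at least
`min_intron` (default 60 nt) between two aligned columns, charged a flat
penalty of 40, plus 20 more unless the jump starts `GT` and ends `AG`.
Intron transitions are only available between aligned exon columns, so
introns exactly fill the genomic gaps between exon blocks. Equal-scoring
donor placements resolve to the leftmost donor, making the output
deterministic. With the intron transition disabled the recurrence reduces
exactly to the local aligner — a reduction the tests exercise — and on small
instances both programs are checked cell-for-cell against naive
enumeration oracles written independently in R.

Two consequences of the *local* semantics are worth spelling out:

* A terminal exon is only included when its match gain exceeds the intron
  penalty, so terminal exons shorter than ~41 nt are provably truncated by
  any score-optimal local alignment. The generator therefore draws terminal
  exons of at least 60 nt (internal exons at least 30 nt).
* A retained intron aligns as one long exon; a short (< `min_intron`)
  insertion is absorbed as an affine gap. This is exactly the asymmetry the
  retained-intron filter relies on: the bidirectional scan reports an
  intron *in the sequence playing the genome role* only.

## The curation cascade

Filters run in a fixed order — redundancy, ncRNA, pathogen, chimera,
retained intron — and a sequence removed early is never tested later, so
stage counts are order-dependent by design. The audit ledger records
`in = removed + kept` per stage, and `pipeline_accounting()` re-checks the
identities exactly.

Redundancy links pairs with E < 1e-180, identity ≥ 97% over non-gap
columns, and aligned length ≥ 80% of *both* sequences; components collapse
to their longest member. One refinement was necessary: a full
Smith–Waterman bridges an intron-sized gap whenever enough matching
sequence follows it, which would merge retained-intron isoform pairs that a
single-HSP search (whose extensions stop at such gaps) keeps apart. A
linked pair must therefore contain no single alignment gap of 30 nt or
more. This restores single-HSP semantics without re-implementing X-dropoff
heuristics.

The chimera rule follows the classical two-step confirmation: a candidate
must hit two transcripts with *different* functional descriptions on
essentially disjoint query regions (overlap < 20% of the shorter region);
descriptions are compared as normalized token sets (case-folded,
punctuation and the generic tokens putative/predicted/like/family/protein
removed) and differ only when neither set contains the other — this keeps
isoform-vs-fragment hits from looking chimeric. Confirmation comes either
from hits on two distinct genome scaffolds or from a BamHI/XhoI site
(`GGATCC`/`CTCGAG`, the ligation sites) strictly between the two matched
regions.

The pathogen filter has a rescue rule: a pathogen hit below 1e-30 is
overridden when a host transcript hits with a strictly smaller E-value, so
conserved genes are not discarded as contamination.

## CDS selection and UTRs

External gene-finders are deliberately not part of the cascade. ORFs are
enumerated exhaustively in the three sense frames (every ATG of each
stop-delimited segment, plus the open-ended candidates needed to classify
5'- or 3'-truncated CDSs), and candidates with proteins of at least 10
amino acids are ranked by homology: the full-length candidate with the
smallest E-value against the protein database wins; if the best-E candidate
is not full length, selection falls through the E-ranked order; when
everything ties, or nothing hits, the longest ORF wins. Completeness is
`full_length` exactly when both ATG and stop codon are present. The stop
codon is counted inside the CDS interval and excluded from the protein, so
a 938 bp mean CDS corresponds to a 313 aa mean polypeptide.

The poly(A) tail is the maximal suffix of length ≥ 10 that is ≥ 90%
adenine **and begins with an adenine**. The last condition is a necessary
refinement: without it the 90% rule always absorbs the final non-A base of
the 3'-UTR (a pure tail of length $t$ gives $t/(t+1) \ge 0.9$ for every
$t \ge 9$), so no tail boundary could ever be pinned down. With it, the
5'-UTR / CDS / 3'-UTR / poly(A) intervals partition the cDNA exactly — an
identity asserted on every annotated sequence.

Base composition counts A, T, G, C with N and X tallied separately and
excluded from the four-way denominator, so composition rows always sum to
100% up to rounding.

## Genome mapping, splice events and SNP rate

A cDNA (poly(A) stripped) is located on the scaffolds by the shared-word
scan in both orientations, then splice-aligned against the located region
extended by a margin (default 12 kb; the pipeline driver uses 2 kb because
the word scan already spans every exon longer than the word size, so the
margin only absorbs span-end truncation). A model is *full-length mapped*
when exon-column identity and est coverage are both ≥ 90% and the alignment
starts within the first and ends within the last 20 nt of the cDNA; failures
report which criterion broke. Exons are typed initial/internal/terminal
(single for one-exon models) in transcript order, and the positions of the
translation start and stop map through the exon blocks, giving the
frequency of start/stop codons in internal exons — the signature of
UTR-located introns.

Splice events between two models at one locus are classified per
structural difference, so one pair can yield several events: an exon of one
model spanning the other's intron is a retained intron; exon skips are
detected *before* alternative sites because a skip's merged intron shares
its donor with one flanking intron and would otherwise masquerade as an
alternative acceptor; intron pairs sharing a donor but not an acceptor (in
transcription sense) are alternative acceptors and vice versa; anything
left is `other`.

The SNP estimator counts substitution columns inside exon blocks over
aligned non-gap exon columns, for pairs with identity ≥ 99.5%; indel
columns enter neither numerator nor denominator. On a variant genome
planted at rate 0.00061 the estimate is unbiased up to edge effects of
order one mismatch per thousand (a substitution in the last couple of
bases of a transcript is trimmed by the local alignment).

## The generator and what passing tests mean

Length families are log-normal with hard bounds — the simplest family with
the right heavy right tail, parameterised to the target medians (exon 154,
intron 264, 5'-UTR 106, 3'-UTR 220 nt, CDS 292 codons) with dispersions
chosen so the bounded draws keep those medians (e.g. intron
`sdlog = 0.55` with a 70 nt floor; a heavier tail would let the floor
shift the realized median). Exon counts are 1 + Poisson(3.9), matching a
mean of 4.9 exons per gene; 20 genes per scaffold with 2 kb spacers;
strands random. Base composition is AT-rich (59.7% AT), stop codons drawn
at 40.6/35.6/23.8% (TGA/TAA/TAG). The variant-genome substitution rate
defaults to 0.00061. Artifact rates (redundancy mean 2 clones per
transcript, 2% chimeras, 1% ncRNA, 1% pathogen contaminants) are far above
the per-ten-thousand rates seen in real curated collections, deliberately:
a desk-scale library of a few hundred clones must contain every artifact
class for recall to be measurable at all.

Several rejection-sampling guards make the planted truth *exactly*
recoverable, and they are the most instructive part of the design:

* 3'-UTRs are resampled until the poly(A) rule recovers exactly the
  planted tail.
* 5'-UTRs are resampled until every in-frame upstream ATG is followed by
  an in-frame stop before the true start (otherwise a nested ORF ties the
  true CDS's homology score and selection becomes ambiguous).
* Intron junctions (including the planted alternative-site junctions and
  every skip-merged junction) are resampled while any slid canonical
  placement scores equally — the classic "intron wobble" degeneracy.
* Alternative donor/acceptor sites are planted 9–50 nt into the intron;
  at 60 nt the shifted block would itself reach the intron-detection
  threshold and the planted classes would contradict each other.
* Genes whose drawn event is infeasible (any event on a single-exon gene,
  exon skip without an internal exon) skip the event and log it; the
  logged draws are what the rate-recovery checks compare against.

The library generator emits two synchronized views: finished clone inserts
(error-free, as after full-length sequencing) and single-pass 5' reads with
a vector flank and a Phred model N(38, 4) clipped to [2, 60] decaying by
0.04/nt after position 500 — enough structure to exercise the Q30 sliding
window trimming rule. Genes carrying an alternative-site or exon-skip event
are represented in the library by the event isoform only (their reference
stays in the unigene database), because such near-identical pairs satisfy
the redundancy rule and would otherwise make the planted classes
inconsistent; retained-intron genes contribute both isoforms, since
detection requires the spliced sibling to be present.

What the passing tests do **not** show: the generator has no sequencing
errors in finished inserts, no paralogous gene families, no repeats, no
alternative transcription starts, and descriptions in its unigene database
are synthetic. Real collections stress the thresholds (97% identity, 20%
overlap, the description heuristic) in ways uniform random sequence cannot;
the exactness results here validate the machinery, not the thresholds'
field performance.

## Problem sizes and coordinates

The shipped checks use 200 genes (about 400 clones) for the noiseless
truth-recovery study, 380 genes for SNP-rate recovery (about 550 kb of
aligned exon bases), and 2000 genes for distributional recovery (intron
median, stop-codon mixture, ~1900 splice-event draws); the dynamic programs
are verified against enumeration oracles on a thousand instances of up to
30 x 60 nt. All coordinates, internal and emitted, are 1-based inclusive
(the Bioconductor convention); GFF3 output follows the gene/mRNA/exon/CDS
hierarchy with ID/Parent attributes.

## Known limitations

* E-values are calibrated for ungapped statistics and raw lengths; they
  are comparable across this package's runs, not across BLAST builds.
* The chimera description heuristic is token-based; curated annotation
  vocabularies with systematic synonyms would need a mapping layer.
* The spliced aligner has no splice-site model beyond the GT..AG bonus
  (no position weight matrices), and does not handle trans-splicing.
* Clustering uses a fixed overlap rule (100 nt at 95%), not an
  overlap-quality model; it reproduces cluster membership, not contigs.
* `select_cds` searches the 20 longest ORF candidates; a cDNA whose true
  CDS is shorter than 20 spurious ORFs would need the cap raised.
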