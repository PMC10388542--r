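---
title: "Methods: chloroplast InDel markers for cytoplasm typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast InDel markers for cytoplasm typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cytoplasmic male sterility (CMS) is the workhorse of F1 hybrid breeding in
*Sorghum*: a sterile (S) cytoplasm combined with non-restoring nuclear
alleles gives a male-sterile seed parent, while the fertile (N) cytoplasm
of a near-isogenic maintainer line propagates it. Because the chloroplast
genome is maternally inherited and structurally stable, fixed differences
between the S and N chloroplast genomes make clean diagnostic markers.
Two intergenic tandem-repeat copy-number differences — a 28-bp unit in the
*rpoC2*–*rps2* spacer and a 22-bp unit in the *cemA*–*petA* spacer —
separate the cytotypes by a PCR product-size shift that capillary
electrophoresis resolves easily.

chlorotype re-implements the full comparative pipeline behind such
markers: quadripartite structure detection, pairwise whole-genome
alignment with left-normalized variant calling, tandem-repeat CNV
characterisation and primer design, in-silico PCR cytotyping of cohorts,
and distance-based phylogenetics, plus a deterministic synthetic-genome
generator so that every stage is testable offline.

## Quadripartite structure detection

A chloroplast genome is modelled as a circular string partitioned as
LSC + IRb + SSC + IRa with IRa = revcomp(IRb). `detect_structure()` finds
the *maximal pair of disjoint exact reverse-complement repeats* at least
`min_ir_len` (default 1,000) bp long. Seed k-mers (k = 31) of the
sequence are joined against k-mers of its reverse complement; runs of
consecutive seeds on one diagonal are maximal exact matches, because
every k-mer inside a maximal match is itself a matching seed. The search
is circular (k-mers are taken over the doubled sequence), so the result
is invariant to rotation and strand of the input. Ties between equally
long repeat pairs are broken by smaller SSC, then by lower start
coordinate. Exact repeats are the default because the IR arms of the
genomes this pipeline targets have identical printed lengths within each
genome; a mismatch-tolerant extension exists (`find_inverted_repeats()`
internals) but is not used by the tests.

The canonical linearization puts position 0 at the first LSC base with
order LSC–IRb–SSC–IRa, where *IRb is defined as the arm adjacent to the
LSC's right end*. Both strands admit such a linearization;
`canonical_rotation()` picks the lexicographically smaller of the two, so
the canonical form is a strand- and rotation-invariant fingerprint. This
is an arbitrary but deterministic convention; it may flip a genome
relative to its database orientation, which is irrelevant to every
downstream computation (all of which are strand-paired).

GC content is reported rounded half-up to two decimals, matching the
precision the field prints.

## Pairwise alignment and variant calling

`align_genomes()` is an anchored global aligner for near-identical
genomes. Shared 21-mers that are unique in both sequences become anchors;
the longest strictly increasing chain (by query position) is kept, chained
anchors merge into exact-match runs, and the gaps between runs are closed
with affine-gap global alignment (match +1, mismatch −2, gap open −4, gap
extend −1 per gapped base, i.e. a gap of length L costs 4 + L). The window
closure is delegated to `Biostrings::pairwiseAlignment()`; the test suite
validates the whole path against an independently written full-matrix
Needleman–Wunsch with the same scoring on pairs up to 2 kb — both the
optimum score and the event set after normalization must agree. Genomes
whose anchor chain covers less than half the reference are rejected as too
divergent rather than force-aligned.

`call_variants()` merges adjacent gap columns into single InDel events and
left-normalizes every InDel VCF-style: the event is shifted to the lowest
reference position that preserves the haplotype and reported with an
anchor base. Left-normalization is what makes InDel *counting*
reproducible in repeat contexts, where the same haplotype difference has
many equivalent alignments. Runs of two or more adjacent mismatches form
an MNP by default; `mnp = FALSE` decomposes them to SNPs, and both
conventions are reported by `variant_summary()`, because published counts
rarely say which convention they used. An insertion and a deletion
separated by fewer than three matched bases are *not* merged into a
complex event — the simplest deterministic rule, stated here because it
affects counts. Two invariants are tested: calls are symmetric under
swapping the genomes (up to allele exchange), and the signed sum of InDel
lengths equals the genome length difference exactly.

The alignment is computed on the canonical linearizations; an event
touching the linearization ends is flagged `origin_spanning`.

## Tandem-repeat CNV markers

`detect_tandem_unit()` explains a large InDel as a copy-number change: the
smallest primitive unit u such that the inserted/deleted sequence is an
integer number of exact copies of u *and* u occurs tandemly at least once
more in the flanking reference context. Copy numbers are maximal exact
tandem runs at the locus in each genome, so
|copies difference| × unit length = InDel length by construction. Because
left-normalization parks the event at the run start, copy counting always
scans rightward from the event position; the test suite checks the
operation against an exhaustive unit-length/phase search.

`select_marker_candidates()` keeps InDels strictly longer than 20 bp
(a literal reading of the "more than 20 bp" rule — a 20-bp InDel is
excluded; the threshold is a parameter), intergenic by default, ordered by
length. `design_primers()` searches 200-bp flanks for pairs with length
18–25 nt, Tm 55–62 °C, GC 40–60%, a *unique* exact site in both genomes
and a product ≤ 400 bp, scoring pairs by Tm balance and closeness to a
250-bp product. Published primer pairs can be injected verbatim — the only
way to reproduce published amplicon sizes exactly, since primer design is
massively underdetermined.

Tm uses unified nearest-neighbor thermodynamics (SantaLucia-style
parameters) with terminal initiation terms, a 0.368·(N−1)·ln[Na⁺]
entropic salt correction at 50 mM monovalent salt, and CT/4 = 0.125 µM
effective strand concentration (0.5 µM primer). Published Tm values are
*not* asserted anywhere: the upstream Tm model behind them is unstated,
and nearest-neighbor Tm predictions legitimately differ by several
degrees across parameter sets.

## In-silico PCR and cytotyping

`insilico_pcr()` reports every primer-site pair on either strand with at
most `max_mismatch` mismatches per site (the three 3'-terminal bases must
match exactly — a primer-extension chemistry rule that is vacuous at the
default 0 mismatches), product ≤ 2,000 bp, scanning across the circular
origin via a bounded doubled template. Product length is inclusive of both
primer footprints, which is what makes published amplicon sizes
reproducible. A brute-force all-position scan serves as the oracle in
tests, including origin-spanning products.

`classify_cytotype()` compares each marker's product to its expected S and
N sizes within a ±2 bp tolerance (mimicking capillary sizing error). The
consensus rule is fail-safe: S only if *every* amplifying marker matches
S; mixed or unmatched evidence is `ambiguous`; no product anywhere is
`no_amplification`. `summarize_cohort()` tallies calls per cultivar with a
grand total and refuses silently unmapped samples.

## Distances, NJ and bootstrap

`distance_matrix()` builds a *star alignment*: every genome is aligned
pairwise to a designated reference and projected onto reference
coordinates; insertions relative to the reference are not columns. This is
justified at the >99.9% identities this pipeline targets and is the
documented limitation of the phylogenetics module — for divergent taxa a
true progressive MSA would be needed. Gap and N columns are excluded
pairwise (pairwise deletion), maximizing usable sites.

Distances are either p-distances or Tamura–Nei (TN93) with base
frequencies pooled across the whole genome set — the composite element of
"maximum composite likelihood" as implemented here. Full MCL also pools
the two transition-rate parameters; at the divergences involved
(p < 10⁻⁴) the difference is far below the printed precision, and the
suite tests |tn93 − p| < 10⁻⁶ in that regime plus a cross-check of the
TN93 closed form against `ape::dist.dna()`.

`neighbor_joining()` is a hand-written Saitou–Nei implementation with the
standard Q-criterion, deterministic tie-break (smallest node-index pair),
and an optional clamp that zeroes negative branch lengths while moving the
deficit to the sibling (off by default so additivity tests stay exact).
`ape::nj()` is used only as an independent cross-check in tests.
`bootstrap_support()` resamples alignment columns via compressed site
patterns (a multinomial draw over pattern counts — equivalent to
resampling columns, and fast), rebuilds the tree per replicate with seed
`seed + r`, and reports bipartition frequencies. Site patterns are
indexed by first occurrence along the genome, which makes supports
invariant to taxon input order. A set of identical sequences is flagged
degenerate and reported as all-100 by convention.

## The synthetic-data generator

`synth_spec()` describes a study: segment lengths, GC, gene census, CNV
loci (with primer-compatible flanks and per-cytotype copy numbers),
SNP/InDel load and cohort composition. `generate_genome_pair()` builds the
N-type template as an element list (spacers, genes, CNV blocks), derives
the S-type from the same elements, and assembles
LSC + IRb + SSC + revcomp(IRb), so each genome's inverted repeat is exact
by construction. Design points worth stating:

* **Exact targets, not expectations.** Segment lengths are met exactly;
  GC is hit by drawing exact base counts per element (residual drift from
  per-element rounding is ~±0.02 percentage points at full scale).
  Boundary bases at the LSC and SSC edges are fixed so the planted IR
  cannot extend by a lucky complementary base.
* **Guarded InDels.** Planted InDel content is redrawn until its edge
  bases cannot alias with the flanking sequence, so the left-normalized
  call position equals the planted position — truth records are exact,
  not approximate. The same guard is applied for the mirrored IR copy.
* **IR edits are mirrored.** SNPs and InDels between cytotypes live in
  single-copy spacers; entries planted in the IR are mirrored into both
  arms (two called events), keeping each genome's repeat exact — the
  biological analogue is IR copy-correction.
* **Marker loci are engineered end-to-end.** Each CNV block embeds its
  primer pair and is sized so the N-type amplicon equals the configured
  size exactly; the S-type differs by (copy difference × unit length).
* **Cohorts are near-clonal.** The default private-SNP rate per plant is
  0 — matching the observed uniformity of inbred cultivar cohorts — with
  an optional positive rate that places private SNPs away from marker
  loci.
* **Determinism.** All randomness flows from one seed through named
  substreams (structure, snps, cohort, taxa), so fixtures are
  byte-identical across runs and stable when unrelated features are
  added.

`synth_spec_sorghum()` scales the design to a real chloroplast: N-type
segments 82,685/22,783/12,503 bp, GC 38.48%, and an inter-cytotype load
of 19 SNPs plus 142 InDels with signed sum −110 bp (the two marker
insertions +28 and +22, one +3 in the SSC, a mirrored −1 in the IR, and
74×(−3) + 62×(+1) + 1×(−1) in LSC spacers), which lands the S-type at
140,644 bp with segments 82,574/22,782/12,506. `synth_taxon_set()` adds
six congeneric genomes by lineage edits on free spacer positions — a
sister to the S lineage differing only by a 2-bp indel (p-distance 0), a
3-SNP sister to the N lineage, two mid-distance and two outgroup taxa
with shared derived SNPs supporting the deep split — reproducing the
spacing and sister relationships of published congeneric sets.

What passing tests on these fixtures do *not* show: robustness to
assembly errors, heteroplasmy, IR boundary shifts beyond exactness,
annotation disagreements, or primer-site divergence in field material.
The generator emulates clean assembled genomes, which is the regime the
pipeline is specified for.

## Problem sizes and numerical choices

The test suite runs the full design twice: at desk scale (≈14 kb genomes,
seconds per stage) for unit and property tests, and at full chloroplast
scale (≈140 kb, 8 taxa, a 1,104-plant cohort) for the study-condition
checks; the acceptance script repeats the full-scale run end to end.
Bootstrap uses 1,000 replicates via the pattern-compression path.
Alignment windows are capped at 20 kb (`max_window`); anchor coverage
below 50% of the reference raises a "too divergent" error. NJ keeps
negative branch lengths unless clamping is requested. Reported GC and
support values are rounded half-up at reporting time only.

## Known limitations

* Star alignment discards insertions relative to the reference; distances
  are exact only for the SNP-dominated, ultra-low-divergence regime.
* TN93 rate parameters are per-pair (frequencies pooled); full MCL
  pooling of rates is not implemented.
* GenBank parsing covers the flat-file subset the pipeline writes and
  consumes (gene/tRNA/rRNA features, complement/join locations); exotic
  location operators are rejected rather than guessed.
* Primer design screens hairpin-free uniqueness and thermodynamics only;
  no dimer or multiplex compatibility screening.
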