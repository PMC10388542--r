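# chlorotype

Comparative chloroplast-genome analysis for cytoplasmic male sterility
(CMS) diagnostics in *Sorghum*-like crops.

CMS-based F1 hybrid breeding needs a fast way to tell a sterile (S)
cytoplasm from a fertile (N) one. Because the chloroplast genome is
maternally inherited and nearly invariant within a breeding pool, fixed
differences between the S and N chloroplast genomes make ideal markers.
The decisive differences are *tandem-repeat copy-number InDels* in
intergenic spacers: a locus carrying *k* copies of a short unit (28 bp in
the *rpoC2*–*rps2* spacer, 22 bp in *cemA*–*petA*) in one cytotype and
*k*+1 in the other shifts a PCR product by exactly one unit, which
capillary electrophoresis reads out directly.

chlorotype implements the whole discovery-to-application pipeline:

* **Structure** — detect the quadripartite architecture (LSC, IRb, SSC,
  IRa) of a circular genome as the maximal pair of disjoint exact
  reverse-complement repeats; canonicalize rotation and strand; compare
  segment lengths and junction gene context across genomes.
* **Compare** — anchored global alignment of near-identical genomes
  (unique shared k-mer chaining + affine-gap closure; match +1,
  mismatch −2, gap open −4, gap extend −1) and VCF-style left-normalized
  SNP/MNP/InDel calls with genic/intergenic context.
* **Markers** — explain large InDels as tandem-repeat copy-number
  variants (smallest primitive unit, exact copy counts, so
  |Δcopies| × unit = InDel length), select intergenic InDels > 20 bp, and
  design primer pairs (18–25 nt, nearest-neighbor Tm 55–62 °C, GC 40–60%,
  unique sites, product ≤ 400 bp) or inject published primers verbatim.
* **Genotype** — in-silico PCR on either strand across the circular
  origin; per-sample S/N/ambiguous calls from product sizes within a
  ±2 bp tolerance; per-cultivar cohort tallies.
* **Phylo** — p or Tamura–Nei (composite, pooled-frequency) distances
  from a star alignment, hand-written Saitou–Nei neighbor joining with
  deterministic tie-breaks, and pattern-compressed bootstrap supports.
* **Simulate** — a fully deterministic generator of quadripartite genome
  pairs, congeneric taxon sets and genotyping cohorts with exact truth
  records, so the entire pipeline is testable with no downloads.

Everything is data-frame first: variant calls, marker candidates,
amplicons, cytotype calls, cohort summaries and pairwise distances are
tibbles; fitted objects have `tidy()`/`glance()` methods and plot helpers
(`autoplot()`, `plot_cohort()`).

## Worked example

Generate a desk-scale S/N genome pair, find the diagnostic markers, and
type a small cohort:

```r
library(chlorotype)

spec <- synth_spec(seed = 42)            # ~14 kb toy chloroplast pair
pair <- generate_genome_pair(spec)

detect_structure(pair$N)
#> <cp_structure> N_type: 14,200 bp, GC 38.57%
#> # A tibble: 4 × 3
#>   region start length
#>   <chr>  <int>  <int>
#> 1 lsc        0   8000
#> 2 irb     8000   2500
#> 3 ssc    10500   1200
#> 4 ira    11700   2500

aln  <- align_genomes(pair$N, pair$S)
vars <- call_variants(aln, features = pair$N$features)
as.data.frame(variant_summary(vars))
#>   n_snp n_mnp n_snp_decomposed n_indel indel_signed_sum n_genic n_intergenic
#> 1     2     0                2      11               44       0           13

as.data.frame(select_marker_candidates(vars, pair$N, pair$S)[,
  c("name", "length", "flank_genes", "unit_len", "copies_ref", "copies_qry")])
#>    name length flank_genes unit_len copies_ref copies_qry
#> 1 cp_01     28  rpoC2-rps2       28          1          2
#> 2 cp_02     22   cemA-petA       22          1          2

mk <- truth_markers(pair$truth)          # the planted primer pairs
as.data.frame(classify_cytotype(pair$S, mk))
#>   sample call len_cp_01 len_cp_02
#> 1 S_type    S       270       265
```

The two candidates are the planted tandem-repeat CNVs: each is one extra
copy of its unit in the S cytotype (28 and 22 bp), so the S amplicons run
exactly one unit larger than the N amplicons (270 vs 242, 265 vs 243) and
the calls follow. `synth_spec_sorghum()` scales the same study to full
chloroplast size (140,754 bp N-type; 19 SNPs and 142 InDels between
cytotypes, signed sum −110 bp), and `synth_taxon_set()` surrounds the pair
with six congeneric genomes for the phylogenetics stages.

File-based workflows use the `run_*()` stage functions
(`run_simulate()`, `run_structure()`, `run_compare()`, `run_markers()`,
`run_genotype()`, `run_phylo()`), each writing TSV/VCF/Newick outputs plus
a JSON provenance manifest; `inst/scripts/chlorotype` wraps them as shell
subcommands.

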