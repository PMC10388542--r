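#' Specification for a synthetic chloroplast genome study
#'
#' Bundles every tunable of the generator: segment lengths of the
#' quadripartite template, target GC, gene census, tandem-repeat CNV loci
#' (with primer-compatible flanks and per-cytotype copy numbers),
#' inter-cytotype SNP/InDel load and the cohort design. All randomness
#' flows from the single `seed` through named substreams, so the same spec
#' always yields byte-identical genomes.
#'
#' The defaults describe a desk-scale genome (LSC 8,000 / IR 2,500 /
#' SSC 1,200 bp, GC 38.5%) whose two cytotypes differ by the two
#' diagnostic tandem-repeat CNVs (28- and 22-bp units, one extra copy in
#' the S cytotype), a handful of short InDels and a low SNP load;
#' [synth_spec_sorghum()] scales the same design to full chloroplast size.
#'
#' @param seed integer master seed.
#' @param lsc,ir,ssc segment lengths (bp) of the N-type template.
#' @param gc target GC percentage, hit by exact base counts.
#' @param n_genes total annotated genes (two are placed in the SSC, one
#'   spans the IRb-SSC junction, four flank the CNV loci).
#' @param gene_size length range for the synthetic genes (bp).
#' @param cnvs CNV locus table, see [default_cnvs()].
#' @param n_snps exact number of inter-cytotype SNPs planted (overrides
#'   `snp_rate` when not `NULL`).
#' @param snp_rate per-site SNP probability between cytotypes, used when
#'   `n_snps` is `NULL`.
#' @param indels named list of signed InDel lengths to plant per region
#'   (`lsc`, `ssc`, `ir`; positive = insertion in the S cytotype). Entries
#'   under `ir` are mirrored into both arms (two events each).
#' @param junction_frags bp of the junction-spanning gene falling in IRb
#'   and SSC respectively.
#' @param cohort cultivar table (`cultivar`, `n_plants`, `cytotype`).
#' @param private_snp_rate per-site rate of neutral private SNPs per
#'   cohort plant (0 by default: breeding lines are near-clonal).
#' @param ids names for the two template genomes.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(seed = 42,
                       lsc = 8000, ir = 2500, ssc = 1200,
                       gc = 38.5,
                       n_genes = 14, gene_size = c(300, 700),
                       cnvs = default_cnvs(),
                       n_snps = 2, snp_rate = 1.4e-4,
                       indels = list(lsc = c(-3, -3, -2, 1, 1, 2, -2, -1),
                                     ssc = c(1), ir = integer(0)),
                       junction_frags = c(irb = 2188, ssc = 600),
                       cohort = default_cohort(),
                       private_snp_rate = 0,
                       ids = c(S = "S_type", N = "N_type")) {
  stopifnot(lsc > 0, ir > 0, ssc > 0, n_genes >= 7,
            all(cnvs$unit_len >= 1), all(cnvs$copies_S >= 1),
            all(cnvs$copies_N >= 1), all(cohort$n_plants > 0))
  structure(list(seed = seed, lsc = lsc, ir = ir, ssc = ssc, gc = gc,
                 n_genes = n_genes, gene_size = gene_size, cnvs = cnvs,
                 n_snps = n_snps, snp_rate = snp_rate, indels = indels,
                 junction_frags = junction_frags, cohort = cohort,
                 private_snp_rate = private_snp_rate, ids = ids),
            class = "synth_spec")
}

#' @rdname synth_spec
#' @export
default_cnvs <- function() {
  tibble(
    name = c("cp_01", "cp_02"),
    flank_left = c("rpoC2", "cemA"),
    flank_right = c("rps2", "petA"),
    unit_len = c(28L, 22L),
    copies_S = c(2L, 2L),
    copies_N = c(1L, 1L),
    amp_N = c(242L, 243L),
    fwd = c("AGAGACCCCGTTTACCCCTA", "CGTGTTTGAAATTTTGGGTCT"),
    rev = c("TTGTTCCGATGGAACCTTCT", "CGAGTCTGTTGTCATTCTACTGC")
  )
}

#' @rdname synth_spec
#' @export
default_cohort <- function() {
  tibble(
    cultivar = c("Nampoongchal", "Donganme", "Sodamchal", "Hwanggeumchal",
                 "Bareme", "Noeulchal"),
    n_plants = c(195L, 170L, 236L, 313L, 95L, 95L),
    cytotype = c("N", "S", "S", "N", "S", "N")
  )
}

#' Full-chloroplast-scale spec
#'
#' Same generator, scaled to the dimensions of a real *Sorghum* chloroplast
#' genome pair: N-type segments 82,685 / 22,783 / 12,503 bp (total
#' 140,754), GC 38.48%, 30 genes, and an inter-cytotype load of 19 SNPs
#' plus 142 InDels whose signed sum is -110 bp, so the S-type genome comes
#' out at 140,644 bp with segments 82,574 / 22,782 / 12,506.
#'
#' @param seed integer master seed.
#' @export
synth_spec_sorghum <- function(seed = 42) {
  synth_spec(
    seed = seed,
    lsc = 82685, ir = 22783, ssc = 12503,
    gc = 38.48,
    n_genes = 30, gene_size = c(300, 900),
    n_snps = 19,
    indels = list(lsc = c(rep(-3L, 74), rep(1L, 62), -1L),
                  ssc = c(3L), ir = c(-1L)),
    cohort = default_cohort(),
    ids = c(S = "ATx623_syn", N = "BTx623_syn")
  )
}

GENE_POOL <- c("ndhD", "psaA", "psaB", "rbcL", "atpA", "atpB", "rpoB",
               "rpoC1", "psbA", "matK", "rps16", "petB", "petD", "ndhA",
               "ndhB", "rps4", "rps7", "rpl2", "rpl16", "ycf3", "clpP",
               "accD", "psbB", "psbC", "psbD", "atpF", "rps8", "rpl14",
               "rps3", "rpl22", "infA", "rps11", "rpoA", "petG", "psaJ")

## internal element record: each genome is a concatenation of elements,
## each carrying its N-type and S-type realisation
el <- function(region, type, n, s = n, name = NA_character_,
               kind = NA_character_, strand = "+", no_var = FALSE) {
  list(region = region, type = type, n = n, s = s, name = name,
       kind = kind, strand = strand, no_var = no_var)
}

#' Generate a matched S/N cytotype genome pair with its truth record
#'
#' Builds the N-type quadripartite template (LSC + IRb + SSC + revcomp(IRb))
#' with exact segment lengths and GC base counts, plants gene features and
#' the CNV marker loci (primer sites included), then derives the S-type
#' genome by changing CNV copy numbers and planting the spec's SNPs and
#' InDels in intergenic single-copy spacers (IR entries are mirrored into
#' both arms so each genome's repeat stays exact). Planted InDels are
#' guarded against left/right shift so their left-normalized positions are
#' knowable in advance; the truth record lists every planted event in both
#' coordinate systems plus the unused candidate positions.
#'
#' @param spec a [synth_spec()].
#' @return list with `S` and `N` ([cp_genome()]) and `truth`.
#' @export
generate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, "structure"))
  elements <- build_layout(spec)
  set.seed(substream_seed(spec$seed, "snps"))
  carved <- carve_variants(elements, spec)
  assemble_pair(carved$elements, carved$slots_free, spec)
}

# ---- layout -----------------------------------------------------------

build_layout <- function(spec) {
  gs <- spec$gene_size
  rand_gene_len <- function(k) sample(gs[1]:gs[2], k, replace = TRUE)
  cnv_blocks <- map(seq_len(nrow(spec$cnvs)), function(z) cnv_block(spec$cnvs[z, ], spec$gc))

  n_cnv <- nrow(spec$cnvs)
  n_lsc_genes <- spec$n_genes - 2L - 1L          # 2 SSC genes, 1 junction gene
  extra_names <- c(GENE_POOL, sprintf("gene%02d", 1:99))
  extra_names <- setdiff(extra_names, c(spec$cnvs$flank_left, spec$cnvs$flank_right))
  lsc_extra <- n_lsc_genes - 2L * n_cnv          # two context genes per locus
  if (lsc_extra < 0) abort("generation error: n_genes too small for the CNV layout")
  ctx_genes <- as.vector(rbind(spec$cnvs$flank_left, spec$cnvs$flank_right))
  lsc_gene_names <- c(ctx_genes, extra_names[seq_len(lsc_extra)])
  ssc_gene_names <- extra_names[lsc_extra + (1:2)]
  lens <- stats::setNames(rand_gene_len(length(lsc_gene_names) + 2),
                          c(lsc_gene_names, ssc_gene_names))
  # keep the gene census inside the segment budget at any seed
  cnv_total <- sum(map_int(cnv_blocks, ~ nchar(.x$n)))
  lsc_budget <- spec$lsc - cnv_total - 2L * n_cnv * 60L -
    (n_cnv + lsc_extra + 1L) * 160L
  if (sum(lens[lsc_gene_names]) > lsc_budget) {
    sc <- lsc_budget / sum(lens[lsc_gene_names])
    lens[lsc_gene_names] <- pmax(150L, as.integer(floor(lens[lsc_gene_names] * sc)))
  }
  ssc_budget <- spec$ssc - spec$junction_frags[["ssc"]] - 3L * 110L
  if (sum(lens[ssc_gene_names]) > ssc_budget) {
    sc <- ssc_budget / sum(lens[ssc_gene_names])
    lens[ssc_gene_names] <- pmax(100L, as.integer(floor(lens[ssc_gene_names] * sc)))
  }
  strands <- stats::setNames(sample(c("+", "-"), length(lens), replace = TRUE),
                             names(lens))
  guard <- 60L
  gene_el <- function(nm, region) {
    el(region, "gene", rand_dna(lens[[nm]], spec$gc), name = nm,
       kind = "gene", strand = strands[[nm]], no_var = TRUE)
  }
  # LSC: per CNV locus [spacer, left gene, guard, CNV, guard, right gene],
  # then [spacer, gene] for the remaining genes, then a closing spacer
  fixed <- sum(lens[lsc_gene_names]) + cnv_total + 2L * n_cnv * guard
  n_spacers <- n_cnv + lsc_extra + 1L
  room <- spec$lsc - fixed
  if (room < n_spacers * 150L) {
    abort("generation error: LSC too small for the requested genes and CNV loci")
  }
  sp_len <- rep(room %/% n_spacers, n_spacers)
  sp_len[1] <- sp_len[1] + room %% n_spacers
  sp <- function(i) el("lsc", "spacer", rand_dna(sp_len[i], spec$gc))
  gel <- function(nm) gene_el(nm, "lsc")
  gd <- function() el("lsc", "spacer", rand_dna(guard, spec$gc), no_var = TRUE)
  lsc <- list()
  si <- 1L
  for (z in seq_len(n_cnv)) {
    lsc <- c(lsc, list(sp(si), gel(spec$cnvs$flank_left[z]), gd(),
                       cnv_blocks[[z]], gd(), gel(spec$cnvs$flank_right[z])))
    si <- si + 1L
  }
  for (nm in lsc_gene_names[seq_len(lsc_extra) + 2L * n_cnv]) {
    lsc <- c(lsc, list(sp(si), gel(nm)))
    si <- si + 1L
  }
  lsc <- c(lsc, list(sp(si)))

  # IRb: open spacer, then the IRb-side fragment of the junction gene
  frag_irb <- spec$junction_frags[["irb"]]
  frag_ssc <- spec$junction_frags[["ssc"]]
  if (frag_irb >= spec$ir - 120 || frag_ssc >= spec$ssc - 120) {
    abort("generation error: junction gene fragments do not fit the IR/SSC")
  }
  irb <- list(el("irb", "spacer", rand_dna(spec$ir - frag_irb, spec$gc)),
              el("irb", "jgene_irb", rand_dna(frag_irb, spec$gc),
                 name = "ndhH", kind = "gene", no_var = TRUE))

  # SSC: junction-gene tail, then spacer/gene/spacer/gene/spacer
  ssc_fixed <- frag_ssc + sum(lens[ssc_gene_names])
  ssc_room <- spec$ssc - ssc_fixed
  if (ssc_room < 3L * 100L) abort("generation error: SSC too small")
  sl <- rep(ssc_room %/% 3L, 3L); sl[1] <- sl[1] + ssc_room %% 3L
  ssc <- list(el("ssc", "jgene_ssc", rand_dna(frag_ssc, spec$gc),
                 name = "ndhH", kind = "gene", no_var = TRUE),
              el("ssc", "spacer", rand_dna(sl[1], spec$gc)),
              gene_el(ssc_gene_names[1], "ssc"),
              el("ssc", "spacer", rand_dna(sl[2], spec$gc)),
              gene_el(ssc_gene_names[2], "ssc"),
              el("ssc", "spacer", rand_dna(sl[3], spec$gc)))
  c(lsc, irb, ssc)
}

# one CNV marker locus: FWD + pre + unit^copies + post + revcomp(REV),
# sized so the N-type amplicon equals amp_N exactly
cnv_block <- function(cnv, gc) {
  lf <- nchar(cnv$fwd); lr <- nchar(cnv$rev)
  u <- cnv$unit_len
  inner <- cnv$amp_N - lf - lr - cnv$copies_N * u
  if (inner < 2) abort("generation error: CNV amplicon too small for its primers")
  pre_len <- inner %/% 2L
  post_len <- inner - pre_len
  unit <- draw_primitive_unit(u, gc)
  pre <- rand_dna(pre_len, gc)
  post <- rand_dna(post_len, gc)
  # keep the tandem run phase-exact: context must not extend the run
  while (pre_len >= u && substr(pre, pre_len - u + 1, pre_len) == unit) {
    pre <- rand_dna(pre_len, gc)
  }
  while (post_len >= u && substr(post, 1, u) == unit) post <- rand_dna(post_len, gc)
  run_n <- strrep(unit, cnv$copies_N)
  run_s <- strrep(unit, cnv$copies_S)
  e <- el("lsc", "cnv",
          n = paste0(cnv$fwd, pre, run_n, post, revcomp(cnv$rev)),
          s = paste0(cnv$fwd, pre, run_s, post, revcomp(cnv$rev)),
          name = cnv$name, no_var = TRUE)
  e$cnv <- list(unit = unit, run_offset = lf + pre_len,
                copies_S = cnv$copies_S, copies_N = cnv$copies_N,
                fwd = cnv$fwd, rev = cnv$rev, amp_N = cnv$amp_N,
                amp_S = cnv$amp_N + (cnv$copies_S - cnv$copies_N) * u,
                unit_len = u)
  e
}

draw_primitive_unit <- function(u, gc) {
  repeat {
    unit <- rand_dna(u, gc)
    if (is_primitive(unit)) return(unit)
  }
}

# ---- variant carving --------------------------------------------------

carve_variants <- function(elements, spec) {
  margin <- 40L; step <- 60L
  slot_tab <- list()
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (e$type != "spacer" || isTRUE(e$no_var)) next
    len <- nchar(e$n)
    if (len < 2 * margin + 20) next
    offs <- seq(margin, len - margin - 10L, by = step)
    if (length(offs)) {
      slot_tab[[length(slot_tab) + 1]] <- tibble(elem = i, off = offs,
                                                 region = e$region)
    }
  }
  slots <- bind_rows(slot_tab)
  wanted <- variant_plan(spec, sum(nchar(map_chr(elements, "n"))))
  if (nrow(wanted) == 0) return(list(elements = elements, slots_free = slots))
  picked <- list()
  for (rg in unique(wanted$region)) {
    pool <- slots %>% filter(.data$region == rg)
    need <- sum(wanted$region == rg)
    if (nrow(pool) < need) {
      abort(sprintf("generation error: %s has %d variant slots but %d needed",
                    rg, nrow(pool), need))
    }
    idx <- sample(nrow(pool), need)
    picked[[rg]] <- bind_cols(pool[idx, ],
                              wanted[wanted$region == rg, c("type", "len")])
    slots <- anti_join(slots, pool[idx, ], by = c("elem", "off"))
  }
  picked <- bind_rows(picked)
  # carve from the back so earlier offsets stay valid
  picked <- arrange(picked, desc(.data$elem), desc(.data$off))
  for (z in seq_len(nrow(picked))) {
    i <- picked$elem[z]; o <- picked$off[z]
    elements <- splice_variant(elements, i, o, picked$type[z], picked$len[z])
  }
  list(elements = elements, slots_free = slots)
}

variant_plan <- function(spec, genome_len) {
  n_snp <- spec$n_snps %||% stats::rbinom(1, genome_len, spec$snp_rate)
  rows <- list()
  if (n_snp > 0) {
    # SNPs go to single-copy regions, mostly LSC
    n_ssc <- min(2L, n_snp %/% 8L)
    rows[[1]] <- tibble(region = c(rep("lsc", n_snp - n_ssc), rep("ssc", n_ssc)),
                        type = "snp", len = 0L)
  }
  for (rg in names(spec$indels)) {
    v <- spec$indels[[rg]]
    if (length(v)) {
      rows[[length(rows) + 1]] <- tibble(
        region = if (rg == "ir") "irb" else rg,
        type = ifelse(v > 0, "ins", "del"), len = abs(as.integer(v)))
    }
  }
  bind_rows(rows)
}

splice_variant <- function(elements, i, o, type, len) {
  e <- elements[[i]]
  s <- e$n
  left <- substr(s, 1, o)
  lchar <- substr(left, o, o)
  if (type == "snp") {
    base <- substr(s, o + 1, o + 1)
    alt <- sample(setdiff(DNA_BASES, base), 1)
    mid <- el(e$region, "snp", n = base, s = alt)
    right <- substr(s, o + 2, nchar(s))
  } else if (type == "ins") {
    right <- substr(s, o + 1, nchar(s))
    rchar <- substr(right, 1, 1)
    ins <- draw_guarded(len, lchar, rchar)
    mid <- el(e$region, "ins", n = "", s = ins)
  } else {
    right <- substr(s, o + len + 1, nchar(s))
    rchar <- substr(right, 1, 1)
    dseq <- draw_guarded(len, lchar, rchar)
    mid <- el(e$region, "del", n = dseq, s = "")
  }
  new <- list(el(e$region, "spacer", left),
              mid,
              el(e$region, "spacer", right))
  append(elements[-i], new, after = i - 1L)
}

# InDel content whose ends cannot alias with the flanking bases, so the
# left-normalized call lands exactly at the planted position (in both the
# forward and the mirrored IR copy)
draw_guarded <- function(len, lchar, rchar) {
  repeat {
    s <- chars_seq(sample(DNA_BASES, len, replace = TRUE))
    if (substr(s, len, len) != lchar && substr(s, 1, 1) != rchar) return(s)
  }
}

# ---- assembly ---------------------------------------------------------

assemble_pair <- function(elements, slots_free, spec) {
  regions <- map_chr(elements, "region")
  fix <- fix_boundaries(elements, regions)
  elements <- fix

  cat_n <- function(rg) chars_seq(map_chr(elements[regions == rg], "n"))
  cat_s <- function(rg) chars_seq(map_chr(elements[regions == rg], "s"))
  n_lsc <- cat_n("lsc"); s_lsc <- cat_s("lsc")
  n_irb <- cat_n("irb"); s_irb <- cat_s("irb")
  n_ssc <- cat_n("ssc"); s_ssc <- cat_s("ssc")
  n_seq <- paste0(n_lsc, n_irb, n_ssc, revcomp(n_irb))
  s_seq <- paste0(s_lsc, s_irb, s_ssc, revcomp(s_irb))
  stopifnot(nchar(n_lsc) == spec$lsc, nchar(n_irb) == spec$ir,
            nchar(n_ssc) == spec$ssc)

  coords <- element_coords(elements)
  feats <- element_features(elements, coords, spec)
  N <- cp_genome(spec$ids[["N"]], n_seq, features = feats$n, source = "synthetic")
  S <- cp_genome(spec$ids[["S"]], s_seq, features = feats$s, source = "synthetic")

  truth <- build_truth(elements, coords, slots_free, spec,
                       n_len = nchar(n_seq), s_len = nchar(s_seq),
                       irb_offset_n = nchar(n_lsc), irb_offset_s = nchar(s_lsc),
                       ir_n = nchar(n_irb), ir_s = nchar(s_irb),
                       ssc_n = nchar(n_ssc), ssc_s = nchar(s_ssc))
  list(S = S, N = N, truth = truth)
}

# block inverted-repeat extension across the segment boundaries:
# LSC must not end with the complement of its first base, and the SSC
# must not start with the complement of its last base
fix_boundaries <- function(elements, regions) {
  set_char <- function(e, where, ch) {
    for (f in c("n", "s")) {
      v <- e[[f]]
      if (nchar(v) == 0) next
      pos <- if (where == "first") 1L else nchar(v)
      substr(v, pos, pos) <- ch
      e[[f]] <- v
    }
    e
  }
  i_l1 <- which(regions == "lsc")[1]
  i_l2 <- utils::tail(which(regions == "lsc"), 1)
  i_s1 <- which(regions == "ssc")[1]
  i_s2 <- utils::tail(which(regions == "ssc"), 1)
  first <- substr(elements[[i_l1]]$n, 1, 1)
  elements[[i_l2]] <- set_char(elements[[i_l2]], "last", first)
  last_ssc <- substr(elements[[i_s2]]$n, nchar(elements[[i_s2]]$n),
                     nchar(elements[[i_s2]]$n))
  elements[[i_s1]] <- set_char(elements[[i_s1]], "first", last_ssc)
  elements
}

element_coords <- function(elements) {
  nl <- map_int(elements, ~ nchar(.x$n))
  sl <- map_int(elements, ~ nchar(.x$s))
  tibble(idx = seq_along(elements),
         region = map_chr(elements, "region"),
         type = map_chr(elements, "type"),
         name = map_chr(elements, "name"),
         n_start = cumsum(c(0L, nl))[seq_along(nl)], n_len = nl,
         s_start = cumsum(c(0L, sl))[seq_along(sl)], s_len = sl)
}

element_features <- function(elements, coords, spec) {
  gene_rows <- function(startcol, lencol) {
    g <- coords %>% filter(.data$type %in% c("gene", "jgene_irb", "jgene_ssc"))
    if (nrow(g) == 0) return(empty_features())
    g %>%
      group_by(.data$name) %>%
      summarise(start = min(.data[[startcol]]),
                end = max(.data[[startcol]] + .data[[lencol]]),
                .groups = "drop") %>%
      mutate(kind = "gene",
             strand = map_chr(.data$name, function(nm) {
               e <- elements[[coords$idx[coords$name == nm][1]]]
               e$strand %||% "+"
             }),
             part = 1L) %>%
      select("name", "kind", "start", "end", "strand", "part")
  }
  list(n = validate_features(gene_rows("n_start", "n_len"), sum(coords$n_len)),
       s = validate_features(gene_rows("s_start", "s_len"), sum(coords$s_len)))
}

build_truth <- function(elements, coords, slots_free, spec, n_len, s_len,
                        irb_offset_n, irb_offset_s, ir_n, ir_s, ssc_n, ssc_s) {
  vc <- coords %>% filter(.data$type %in% c("snp", "ins", "del"))
  variants <- map(vc$idx, function(i) {
    e <- elements[[i]]
    row <- coords[coords$idx == i, ]
    tibble(region = e$region, type = e$type,
           len = as.integer(abs(nchar(e$s) - nchar(e$n))),
           pos_N = row$n_start, pos_S = row$s_start,
           n_allele = e$n, s_allele = e$s)
  })
  variants <- bind_rows(variants)
  if (nrow(variants) == 0) {
    variants <- tibble(region = character(), type = character(),
                       len = integer(), pos_N = integer(), pos_S = integer(),
                       n_allele = character(), s_allele = character())
  }
  # IRb events are mirrored into IRa in both genomes: add the mirror images
  irv <- variants %>% filter(.data$region == "irb")
  if (nrow(irv) > 0) {
    mirr <- irv %>% mutate(
      region = "ira",
      off_n = .data$pos_N - irb_offset_n,
      off_s = .data$pos_S - irb_offset_s,
      pos_N = irb_offset_n + ir_n + ssc_n + (ir_n - .data$off_n -
                nchar(.data$n_allele)),
      pos_S = irb_offset_s + ir_s + ssc_s + (ir_s - .data$off_s -
                nchar(.data$s_allele)),
      n_allele = map_chr(.data$n_allele, function(x) if (nchar(x)) revcomp(x) else x),
      s_allele = map_chr(.data$s_allele, function(x) if (nchar(x)) revcomp(x) else x)
    ) %>% select(-"off_n", -"off_s")
    variants <- bind_rows(variants, mirr)
  }
  variants <- arrange(variants, .data$pos_N)

  cnv_idx <- which(map_chr(elements, "type") == "cnv")
  cnvs <- map(cnv_idx, function(i) {
    e <- elements[[i]]
    row <- coords[coords$idx == i, ]
    tibble(name = e$name, unit = e$cnv$unit, unit_len = e$cnv$unit_len,
           copies_S = e$cnv$copies_S, copies_N = e$cnv$copies_N,
           amp_S = e$cnv$amp_S, amp_N = e$cnv$amp_N,
           fwd = e$cnv$fwd, rev = e$cnv$rev,
           run_start_N = row$n_start + e$cnv$run_offset,
           run_start_S = row$s_start + e$cnv$run_offset)
  })
  cnvs <- bind_rows(cnvs)

  # unused candidate positions, in both coordinate systems
  free <- NULL
  if (nrow(slots_free) > 0) {
    pos_n <- map_int(seq_len(nrow(slots_free)), function(z) {
      as.integer(coords$n_start[coords$idx == slots_free$elem[z]] + slots_free$off[z])
    })
    shift_at <- function(p) {
      prior <- variants[variants$pos_N <= p, ]
      sum(nchar(prior$s_allele) - nchar(prior$n_allele))
    }
    free <- tibble(region = slots_free$region, pos_N = pos_n,
                   pos_S = pos_n + map_int(pos_n, ~ as.integer(shift_at(.x))))
  }
  segs <- tibble(
    region = c("lsc", "irb", "ssc", "ira"),
    len_N = c(irb_offset_n, ir_n, ssc_n, ir_n),
    len_S = c(irb_offset_s, ir_s, ssc_s, ir_s))
  list(spec = spec, segments = segs, variants = variants, cnvs = cnvs,
       slots_free = free, n_len = n_len, s_len = s_len)
}

# ---- cohort -----------------------------------------------------------

#' Generate a genotyping cohort from a cytotype genome pair
#'
#' One genome per plant, copied from its cultivar's cytotype template;
#' private neutral SNPs are added at `private_snp_rate` (default 0: the
#' generator emulates near-clonal breeding lines) at unused candidate
#' positions away from the marker loci. Optionally writes a FASTA per
#' sample plus a manifest TSV.
#'
#' @param pair result of [generate_genome_pair()].
#' @param spec the same [synth_spec()].
#' @param dir output directory for FASTA files and `manifest.tsv`, or
#'   `NULL` to keep everything in memory.
#' @return list with `genomes` (named list of [cp_genome()]), `manifest`
#'   tibble (`sample`, `cultivar`, `cytotype`) and `paths` when written.
#' @export
generate_cohort <- function(pair, spec, dir = NULL) {
  set.seed(substream_seed(spec$seed, "cohort"))
  cohort <- spec$cohort
  if (nrow(cohort) == 0) {
    return(list(genomes = list(),
                manifest = tibble(sample = character(), cultivar = character(),
                                  cytotype = character())))
  }
  rows <- cohort[rep(seq_len(nrow(cohort)), cohort$n_plants), ]
  rows <- rows %>%
    group_by(.data$cultivar) %>%
    mutate(sample = sprintf("%s_%04d", .data$cultivar, row_number())) %>%
    ungroup()
  genomes <- vector("list", nrow(rows))
  for (z in seq_len(nrow(rows))) {
    ct <- rows$cytotype[z]
    tmpl <- if (ct == "S") pair$S else pair$N
    seq <- tmpl$seq
    if (spec$private_snp_rate > 0 && !is.null(pair$truth$slots_free)) {
      slots <- pair$truth$slots_free
      poscol <- if (ct == "S") slots$pos_S else slots$pos_N
      k <- stats::rbinom(1, nchar(seq), spec$private_snp_rate)
      k <- min(k, length(poscol))
      if (k > 0) {
        for (p in sample(poscol, k)) {
          old <- substr(seq, p + 1, p + 1)
          substr(seq, p + 1, p + 1) <- sample(setdiff(DNA_BASES, old), 1)
        }
      }
    }
    genomes[[z]] <- cp_genome(rows$sample[z], seq, source = "synthetic")
  }
  names(genomes) <- rows$sample
  manifest <- rows[, c("sample", "cultivar", "cytotype")]
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- map_chr(genomes, function(g) {
      p <- file.path(dir, paste0(g$id, ".fasta"))
      write_genome(g, p)
      p
    })
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  }
  list(genomes = genomes, manifest = manifest, paths = paths)
}

# ---- multi-taxon set --------------------------------------------------

#' Apply SNP/InDel edits to a sequence
#'
#' Edits are 0-based; insertions insert `alt` before `pos`, deletions
#' remove `len` bases at `pos`, SNPs replace one base with `alt`.
#' @param seq DNA string.
#' @param edits tibble with `pos`, `type` (snp/ins/del), `len`, `alt`.
#' @return the edited string.
#' @export
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- arrange(edits, desc(.data$pos))
  for (z in seq_len(nrow(edits))) {
    p <- edits$pos[z]
    if (edits$type[z] == "snp") {
      substr(seq, p + 1, p + 1) <- edits$alt[z]
    } else if (edits$type[z] == "ins") {
      seq <- paste0(substr(seq, 1, p), edits$alt[z],
                    substr(seq, p + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, p),
                    substr(seq, p + edits$len[z] + 1, nchar(seq)))
    }
  }
  seq
}

#' Generate a congeneric taxon set around the cytotype pair
#'
#' Emulates a small genus: the S/N pair plus six relatives derived from
#' the same template by lineage-specific SNP/InDel loads, so that the S
#' lineage splits into two near-identical taxa (p-distance 0), the N
#' lineage has a very close sister (3 SNPs apart), and two distant taxa
#' act as outgroups. Genome length offsets per taxon are configurable; the
#' defaults reproduce the spacing of published congeneric chloroplast
#' genomes (+1, -2, +56, +67, -125, +11 bp relative to the N template).
#'
#' @param spec a [synth_spec()] (use [synth_spec_sorghum()] for
#'   full-scale genomes).
#' @return list: `genomes` (named list, S/N pair first), `pair`, and
#'   `truth` describing the planted lineage edits and the expected sister
#'   pairs.
#' @export
synth_taxon_set <- function(spec = synth_spec_sorghum()) {
  pair <- generate_genome_pair(spec)
  set.seed(substream_seed(spec$seed, "taxa"))
  free <- pair$truth$slots_free
  if (is.null(free) || nrow(free) < 600) {
    abort("generation error: not enough free positions for the taxon set")
  }
  take <- local({
    remaining <- free[sample(nrow(free)), ]
    function(k) {
      stopifnot(nrow(remaining) >= k)
      out <- remaining[seq_len(k), ]
      remaining <<- remaining[-seq_len(k), ]
      out
    }
  })
  snp_edits <- function(slots, on = c("N", "S")) {
    on <- match.arg(on)
    tibble(pos = if (on == "S") slots$pos_S else slots$pos_N,
           type = "snp", len = 0L,
           alt = map_chr(seq_len(nrow(slots)), ~ sample(DNA_BASES, 1)))
  }
  # a SNP edit must actually change the base; resample clashes lazily
  fix_snp_alt <- function(seq, ed) {
    for (z in seq_len(nrow(ed))) {
      if (ed$type[z] != "snp") next
      cur <- substr(seq, ed$pos[z] + 1, ed$pos[z] + 1)
      if (ed$alt[z] == cur) ed$alt[z] <- sample(setdiff(DNA_BASES, cur), 1)
    }
    ed
  }
  indel_edits <- function(slots, lens, on = c("N", "S")) {
    on <- match.arg(on)
    tibble(pos = if (on == "S") slots$pos_S else slots$pos_N,
           type = ifelse(lens > 0, "ins", "del"),
           len = abs(lens),
           alt = map_chr(abs(lens), ~ rand_dna(.x, spec$gc)))
  }
  s4 <- take(4)      # shared by every taxon except the N pair (BTx/sudanense)
  common4_N <- snp_edits(s4, "N"); common4_S <- snp_edits(s4, "S")
  common4_S$alt <- common4_N$alt
  sudan_sn <- snp_edits(take(3), "N")
  sudan_ins <- indel_edits(take(1), c(1L))
  prop_del <- indel_edits(take(1), c(-2L), on = "S")
  halep <- bind_rows(snp_edits(take(30), "N"), indel_edits(take(2), c(25L, 31L)))
  arund <- bind_rows(snp_edits(take(35), "N"), indel_edits(take(2), c(33L, 34L)))
  out25 <- snp_edits(take(25), "N")
  timor <- bind_rows(out25, snp_edits(take(100), "N"),
                     indel_edits(take(2), c(-60L, -65L)))
  mekong <- bind_rows(out25, snp_edits(take(350), "N"),
                      indel_edits(take(1), c(11L)))

  mk <- function(id, base_seq, edits) {
    edits <- fix_snp_alt(base_seq, edits)
    cp_genome(id, apply_edits(base_seq, edits), source = "synthetic")
  }
  nseq <- pair$N$seq; sseq <- pair$S$seq
  genomes <- list(
    ATx623_syn = mk("ATx623_syn", sseq, common4_S),
    BTx623_syn = cp_genome("BTx623_syn", nseq, source = "synthetic"),
    S_propinquum_syn = mk("S_propinquum_syn", sseq,
                          bind_rows(common4_S, prop_del)),
    S_sudanense_syn = mk("S_sudanense_syn", nseq, bind_rows(sudan_sn, sudan_ins)),
    S_halepense_syn = mk("S_halepense_syn", nseq, bind_rows(common4_N, halep)),
    S_arundinaceum_syn = mk("S_arundinaceum_syn", nseq, bind_rows(common4_N, arund)),
    S_timorense_syn = mk("S_timorense_syn", nseq, bind_rows(common4_N, timor)),
    H_mekongense_syn = mk("H_mekongense_syn", nseq, bind_rows(common4_N, mekong))
  )
  truth <- list(
    sister_pairs = list(c("ATx623_syn", "S_propinquum_syn"),
                        c("BTx623_syn", "S_sudanense_syn")),
    outgroup_clade = c("S_timorense_syn", "H_mekongense_syn"),
    n_snps_btx_sudan = 3L,
    length_offsets = c(ATx623_syn = nchar(sseq) - nchar(nseq),
                       S_propinquum_syn = nchar(sseq) - nchar(nseq) - 2L,
                       S_sudanense_syn = 1L, S_halepense_syn = 56L,
                       S_arundinaceum_syn = 67L, S_timorense_syn = -125L,
                       H_mekongense_syn = 11L))
  list(genomes = genomes, pair = pair, truth = truth)
}
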