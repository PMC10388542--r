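variant_of_length <- function(vars, L) vars[vars$length == L, ][1, ]

test_that("a unit insertion in a matching tandem context is explained as a CNV", {
  # ATATAT inserted where the reference already reads ...ATAT...
  set.seed(40)
  left <- rand_seq(150); right <- rand_seq(150)
  substr(left, 150, 150) <- "G"; substr(right, 1, 1) <- "G"
  ref <- cp_genome("r", paste0(left, "ATAT", right))
  qry <- cp_genome("q", paste0(left, "ATATATATAT", right))
  vars <- call_variants(align_genomes(ref, qry, k = 11))
  v <- vars[vars$type == "insertion", ][1, ]
  expect_equal(v$length, 6L)
  cnv <- detect_tandem_unit(v, ref, qry)
  expect_equal(cnv$unit, "AT")
  expect_equal(cnv$unit_len, 2L)
  expect_equal(cnv$copies_ref, 2L)
  expect_equal(cnv$copies_qry, 5L)
  expect_equal(abs(cnv$copies_ref - cnv$copies_qry) * cnv$unit_len, v$length)
})

test_that("an insertion without tandem context has no CNV explanation", {
  set.seed(41)
  left <- rand_seq(120); right <- rand_seq(120)
  substr(left, 120, 120) <- "A"; substr(right, 1, 1) <- "A"
  ref <- cp_genome("r", paste0(left, right))
  qry <- cp_genome("q", paste0(left, "GCGT", right))
  vars <- call_variants(align_genomes(ref, qry, k = 11))
  v <- vars[vars$type == "insertion", ][1, ]
  expect_null(detect_tandem_unit(v, ref, qry))
  expect_error(detect_tandem_unit(tibble::tibble(type = "SNP"), ref, qry),
               "insertion or deletion")
})

test_that("tandem unit detection agrees with the exhaustive unit/phase oracle", {
  for (seed in 1:6) {
    set.seed(seed * 7)
    u_len <- sample(c(2, 3, 4, 7, 11, 14), 1)
    copies_ref <- sample(1:3, 1)
    extra <- sample(1:3, 1)
    unit <- rand_seq(u_len)
    if (!chlorotype:::is_primitive(unit)) next
    left <- rand_seq(150); right <- rand_seq(150)
    substr(left, 150, 150) <- "G"
    run_ref <- strrep(unit, copies_ref)
    # guard the run phase on both sides
    while (substr(right, 1, u_len) == unit) right <- rand_seq(150)
    ref <- cp_genome("r", paste0(left, run_ref, right))
    qry <- cp_genome("q", paste0(left, strrep(unit, copies_ref + extra), right))
    vars <- call_variants(align_genomes(ref, qry, k = 11))
    v <- vars[vars$type == "insertion", ]
    if (nrow(v) != 1) next                       # aliasing contexts: skip draw
    cnv <- detect_tandem_unit(v[1, ], ref, qry)
    ins_seq <- substr(v$alt[1], 2, v$length[1] + 1)
    oracle <- brute_tandem(ins_seq, ref$seq, qry$seq,
                           p_ref = v$ref_pos[1], p_qry = v$qry_pos[1],
                           is_ins = TRUE)
    expect_false(is.null(cnv))
    expect_equal(cnv$unit, oracle$unit)
    expect_equal(cnv$copies_ref, oracle$copies_ref)
    expect_equal(cnv$copies_qry, oracle$copies_qry)
  }
})

test_that("marker candidate selection applies the strict >20 bp and intergenic rules", {
  feats <- tibble::tibble(name = c("gL", "gR"), kind = "gene",
                          start = c(0L, 900L), end = c(100L, 1000L),
                          strand = "+", part = 1L)
  mkall <- function(L) paste0("A", strrep("C", L))
  vars <- tibble::tibble(
    ref_pos = c(200L, 300L, 400L, 500L), qry_pos = c(200L, 300L, 400L, 500L),
    type = c("insertion", "deletion", "insertion", "insertion"),
    ref = c("A", mkall(25), "A", "A"),
    alt = c(mkall(20), "A", mkall(30), mkall(15)),
    length = c(20L, 25L, 30L, 15L),
    ev_start = c(200L, 300L, 400L, 500L), ev_end = c(200L, 325L, 400L, 500L),
    origin_spanning = FALSE,
    context = c("intergenic", "intergenic", "genic", "intergenic"),
    flank_genes = "gL-gR", gene = NA_character_)
  set.seed(43)
  g <- cp_genome("g", rand_seq(1000))
  cand <- select_marker_candidates(vars, g, g)
  expect_equal(cand$length, 25L)               # 20 excluded (strict), 30 genic
  cand2 <- select_marker_candidates(vars, g, g, require_intergenic = FALSE)
  expect_equal(cand2$length, c(30L, 25L))
  expect_equal(cand2$name, c("cp_01", "cp_02"))
  expect_equal(nrow(select_marker_candidates(vars[vars$length < 20, ], g, g)), 0)
})

test_that("the generator's CNVs are the only candidates and carry exact copy counts", {
  pair <- toy_pair()
  vars <- call_variants(align_genomes(pair$N, pair$S), features = pair$N$features)
  cand <- select_marker_candidates(vars, pair$N, pair$S)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$length, sort(pair$truth$cnvs$unit_len, decreasing = TRUE))
  expect_equal(cand$unit_len, cand$length)     # one extra copy per locus
  expect_equal(cand$copies_ref, pair$truth$cnvs$copies_N[order(-pair$truth$cnvs$unit_len)])
  expect_equal(cand$copies_qry, pair$truth$cnvs$copies_S[order(-pair$truth$cnvs$unit_len)])
})

test_that("primer design on an engineered locus meets all constraints", {
  set.seed(44)
  pair <- toy_pair()
  vars <- call_variants(align_genomes(pair$N, pair$S), features = pair$N$features)
  cand <- select_marker_candidates(vars, pair$N, pair$S)
  mk <- design_primers(cand[1, ], pair$N, pair$S)
  expect_true(nchar(mk$fwd) %in% 18:25)
  expect_true(nchar(mk$rev) %in% 18:25)
  expect_true(mk$tm_fwd >= 55 && mk$tm_fwd <= 62)
  expect_true(mk$tm_rev >= 55 && mk$tm_rev <= 62)
  # product size difference equals copy difference x unit length
  expect_equal(mk$size_qry - mk$size_ref, 28L)
  expect_true(mk$size_ref <= 400)
  # each primer occurs exactly once in each genome
  for (p in c(mk$fwd, mk$rev)) {
    expect_equal(chlorotype:::count_sites(p, pair$N$seq), 1)
    expect_equal(chlorotype:::count_sites(p, pair$S$seq), 1)
  }
})

test_that("primer design fails cleanly when the flanks cannot host a primer", {
  set.seed(45)
  g <- cp_genome("g", rand_seq(60))
  cand <- tibble::tibble(name = "x", locus_start = 10L, locus_end = 50L)
  expect_error(design_primers(cand, g, g, flank = 8),
               "no primer", class = "chlorotype_no_primer")
})

test_that("published primers can be injected verbatim", {
  pair <- toy_pair()
  mk_truth <- truth_markers(pair$truth)
  vars <- call_variants(align_genomes(pair$N, pair$S), features = pair$N$features)
  cand <- select_marker_candidates(vars, pair$N, pair$S)
  mk <- design_primers(cand[1, ], pair$N, pair$S,
                       primers = c(fwd = mk_truth$fwd[1], rev = mk_truth$rev[1]))
  expect_equal(mk$fwd, mk_truth$fwd[1])
  expect_equal(mk$size_ref, mk_truth$expected_N[1])
  expect_equal(mk$size_qry, mk_truth$expected_S[1])
})

test_that("marker definitions round-trip through YAML", {
  mk <- marker_set(c("m1", "m2"), c("ACGTACGTACGTACGTAC", "TTGGCCAATTGGCCAATT"),
                   c("GGGTTTAAACCCGGGTTT", "AACCGGTTAACCGGTTAA"),
                   expected_S = c(270L, 265L), expected_N = c(242L, 243L),
                   tolerance_bp = c(2L, 3L))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_markers(mk, p)
  mk2 <- read_markers(p)
  expect_equal(as.data.frame(mk2), as.data.frame(mk))
})

test_that("nearest-neighbor Tm behaves sensibly", {
  tm20 <- primer_tm("AGAGACCCCGTTTACCCCTA")
  expect_true(is.finite(tm20) && tm20 > 40 && tm20 < 75)
  # longer and GC-richer primers melt higher
  expect_gt(primer_tm(strrep("GC", 12)), primer_tm(strrep("AT", 12)))
  expect_gt(primer_tm(strrep("ACGT", 6)), primer_tm(strrep("ACGT", 4)))
  expect_error(primer_tm("A"), "too short")
  expect_equal(chlorotype:::primer_gc("GGCC"), 100)
  expect_equal(chlorotype:::primer_gc("GGAA"), 50)
})
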