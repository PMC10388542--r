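test_that("a genome aligned to itself is a single all-match block", {
  set.seed(20)
  g <- cp_genome("self", rand_seq(4000))
  aln <- align_genomes(g, g)
  expect_equal(nrow(aln$ops), 1)
  expect_equal(aln$ops$op, "M")
  expect_equal(aln$ops$len, 4000L)
  expect_equal(aln$identity, 1)
  expect_equal(nrow(call_variants(aln)), 0)
})

test_that("a planted 28-bp insertion and 3 SNPs give exactly those op counts", {
  set.seed(21)
  ref <- cp_genome("r", rand_seq(5000))
  edits <- tibble::tibble(
    pos = c(800L, 2000L, 3100L, 4200L),
    type = c("snp", "ins", "snp", "snp"),
    len = c(0L, 28L, 0L, 0L),
    alt = c("A", rand_seq(28), "A", "A"))
  # guarantee the SNPs actually change the base
  for (z in c(1, 3, 4)) {
    cur <- substr(ref$seq, edits$pos[z] + 1, edits$pos[z] + 1)
    edits$alt[z] <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  qry <- cp_genome("q", apply_edits(ref$seq, edits))
  aln <- align_genomes(ref, qry)
  counts <- tapply(aln$ops$len, aln$ops$op, sum)
  expect_equal(unname(counts["I"]), 28L)
  expect_equal(unname(counts["X"]), 3L)
  expect_equal(unname(counts["M"]), 5000L - 3L)
  expect_true(is.na(counts["D"]))
})

test_that("anchored alignment attains the full-matrix optimum on a 2 kb pair", {
  set.seed(22)
  ref <- cp_genome("r", rand_seq(2000))
  edits <- tibble::tibble(pos = c(400L, 900L, 1500L),
                          type = c("snp", "ins", "del"),
                          len = c(0L, 28L, 5L),
                          alt = c("A", rand_seq(28), ""))
  cur <- substr(ref$seq, 401, 401)
  edits$alt[1] <- setdiff(c("A", "C", "G", "T"), cur)[1]
  qry <- cp_genome("q", apply_edits(ref$seq, edits))
  aln <- align_genomes(ref, qry)
  oracle <- nw_oracle(ref, qry)
  expect_equal(score_alignment(aln), nw_oracle_score(oracle))
  expect_identical(event_signature(call_variants(aln)),
                   event_signature(call_variants(oracle)))
})

test_that("anchored alignment matches full Needleman-Wunsch events on random pairs", {
  for (seed in 1:4) {
    set.seed(seed * 31)
    n <- sample(400:700, 1)
    ref <- cp_genome("r", rand_seq(n))
    k_edits <- sample(3:6, 1)
    pos <- sort(sample(seq(40, n - 60, by = 45), k_edits))
    edits <- tibble::tibble(
      pos = as.integer(pos),
      type = sample(c("snp", "ins", "del"), k_edits, replace = TRUE),
      len = 0L, alt = "")
    for (z in seq_len(k_edits)) {
      if (edits$type[z] == "snp") {
        cur <- substr(ref$seq, edits$pos[z] + 1, edits$pos[z] + 1)
        edits$alt[z] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      } else {
        edits$len[z] <- sample(1:8, 1)
        edits$alt[z] <- rand_seq(edits$len[z])
      }
    }
    qry <- cp_genome("q", apply_edits(ref$seq, edits))
    aln <- align_genomes(ref, qry, k = 11)
    oracle <- nw_oracle(ref, qry)
    expect_equal(score_alignment(aln), nw_oracle_score(oracle))
    expect_identical(event_signature(call_variants(aln)),
                     event_signature(call_variants(oracle)),
                     label = paste("event sets, seed", seed))
  }
})

test_that("InDels are left-normalized to the lowest equivalent position", {
  # ACACAC -> ACACACAC: the two extra bases shift to the run start
  set.seed(23)
  left <- rand_seq(200); right <- rand_seq(200)
  substr(left, 200, 200) <- "G"      # block shifting out of the run
  substr(right, 1, 1) <- "G"
  ref <- cp_genome("r", paste0(left, "ACACAC", right))
  qry <- cp_genome("q", paste0(left, "ACACACAC", right))
  vars <- call_variants(align_genomes(ref, qry, k = 11))
  expect_equal(nrow(vars), 1)
  expect_equal(vars$type, "insertion")
  expect_equal(vars$length, 2L)
  # oracle: enumerate every equivalent placement, take the minimum
  pts <- equivalent_insertion_points(ref$seq, 206L, "AC")
  expect_equal(vars$ref_pos, min(pts))   # anchor base = position before run
  expect_equal(min(pts), 200L)
})

test_that("variant calling is symmetric up to allele swap", {
  pair <- toy_pair()
  fwd <- call_variants(align_genomes(pair$N, pair$S))
  rev <- call_variants(align_genomes(pair$S, pair$N))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sum(fwd$type == "SNP"), sum(rev$type == "SNP"))
  expect_equal(sum(fwd$type == "insertion"), sum(rev$type == "deletion"))
  expect_equal(sum(fwd$type == "deletion"), sum(rev$type == "insertion"))
  expect_setequal(fwd$alt[fwd$type == "SNP"], rev$ref[rev$type == "SNP"])
  s_fwd <- variant_summary(fwd)$indel_signed_sum
  s_rev <- variant_summary(rev)$indel_signed_sum
  expect_equal(s_fwd, -s_rev)
})

test_that("signed InDel lengths sum to the genome length difference", {
  pair <- toy_pair()
  vars <- call_variants(align_genomes(pair$N, pair$S))
  expect_equal(variant_summary(vars)$indel_signed_sum,
               nchar(pair$S$seq) - nchar(pair$N$seq))
})

test_that("adjacent mismatches form MNPs by default and decompose on request", {
  set.seed(25)
  ref <- cp_genome("r", rand_seq(500))
  qry_seq <- ref$seq
  old <- substr(qry_seq, 201, 202)
  new <- chartr("ACGT", "GTAC", old)    # both bases change
  substr(qry_seq, 201, 202) <- new
  qry <- cp_genome("q", qry_seq)
  aln <- align_genomes(ref, qry, k = 11)
  v1 <- call_variants(aln, mnp = TRUE)
  expect_equal(v1$type, "MNP")
  expect_equal(v1$ref, old)
  expect_equal(v1$alt, new)
  v2 <- call_variants(aln, mnp = FALSE)
  expect_equal(v2$type, c("SNP", "SNP"))
  expect_equal(v2$ref_pos, c(201L, 202L))
  expect_equal(variant_summary(v1)$n_snp_decomposed, 2L)
})

test_that("genic/intergenic context and flanking gene labels are assigned", {
  pair <- toy_pair()
  vars <- call_variants(align_genomes(pair$N, pair$S), features = pair$N$features)
  cnv_ins <- vars[vars$length == 28L, ]
  expect_equal(cnv_ins$context, "intergenic")
  expect_equal(cnv_ins$flank_genes, "rpoC2-rps2")
  cnv_ins2 <- vars[vars$length == 22L, ]
  expect_equal(cnv_ins2$flank_genes, "cemA-petA")
})

test_that("gene variant scan counts overlaps and rejects unknown genes", {
  set.seed(26)
  feats <- tibble::tibble(name = c("G", "H"), kind = "gene",
                          start = c(100L, 300L), end = c(200L, 400L),
                          strand = "+", part = 1L)
  ref <- cp_genome("r", rand_seq(600), features = feats)
  qseq <- ref$seq
  cur <- substr(qseq, 151, 151)
  substr(qseq, 151, 151) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  qry <- cp_genome("q", qseq)
  vars <- call_variants(align_genomes(ref, qry, k = 11), features = feats)
  scan <- gene_variant_scan(vars, c("G", "H"), feats)
  expect_equal(scan$n_variants, c(1L, 0L))
  expect_equal(gene_variant_scan(vars[0, ], c("G", "H"), feats)$n_variants,
               c(0L, 0L))
  expect_error(gene_variant_scan(vars, "nope", feats), "unknown gene")
})

test_that("too-divergent genomes are reported rather than force-aligned", {
  set.seed(27)
  a <- cp_genome("a", rand_seq(3000))
  b <- cp_genome("b", rand_seq(3000))
  expect_error(align_genomes(a, b), "divergent")
})

test_that("VCF output is well-formed", {
  pair <- toy_pair()
  vars <- call_variants(align_genomes(pair$N, pair$S), features = pair$N$features)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vars, pair$N, p)
  lines <- readLines(p)
  expect_equal(lines[1], "##fileformat=VCFv4.3")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(vars))
  cols <- strsplit(body[1], "\t")[[1]]
  expect_length(cols, 8)
  expect_match(cols[8], "TYPE=")
  # REF allele matches the reference sequence at POS
  pos <- as.integer(cols[2])
  expect_equal(substr(pair$N$seq, pos, pos + nchar(cols[4]) - 1L), cols[4])
})
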