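test_that("planted primer sites give one amplicon of the planted outer-edge distance", {
  set.seed(50)
  fwd <- "ACGGTTCCAAGGTTCCAACG"
  rev <- "TTCCGGAACCGGTTAAGGCC"
  insert <- rand_seq(160)
  g <- cp_genome("t", paste0(rand_seq(500), fwd, insert,
                             chlorotype:::revcomp(rev), rand_seq(500)))
  amps <- insilico_pcr(g, fwd, rev)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, nchar(fwd) + 160L + nchar(rev))
  expect_equal(amps$start, 500L)
  expect_equal(amps$end - amps$start, amps$length)
})

test_that("primers with no binding site yield an empty amplicon table", {
  set.seed(51)
  g <- cp_genome("t", rand_seq(2000))
  amps <- insilico_pcr(g, "ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA")
  expect_equal(nrow(amps), 0)
})

test_that("products spanning the circular origin are found", {
  set.seed(52)
  fwd <- "GGAACCTTGGAACCTTGGCA"
  rev <- "CCTTGGAACCTTGGAACCAG"
  # fwd site ends 40 bp before the origin; rev site starts 60 bp after it
  g <- cp_genome("t", paste0(chlorotype:::revcomp(rev), rand_seq(1800),
                             fwd, rand_seq(40)))
  n <- nchar(g$seq)
  amps <- insilico_pcr(g, fwd, rev)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, 40L + nchar(rev) + nchar(fwd))
  expect_true(amps$end > n)      # wraps the origin
  lin <- cp_genome("lin", g$seq, circular = FALSE)
  expect_equal(nrow(insilico_pcr(lin, fwd, rev)), 0)
})

test_that("in-silico PCR equals the brute-force all-position scan", {
  set.seed(53)
  for (case in 1:3) {
    g <- cp_genome(paste0("g", case), rand_seq(sample(3000:6000, 1)))
    # plant two site pairs, one of them origin-spanning
    fwd <- rand_seq(20); rev <- rand_seq(20)
    s <- g$seq
    s <- paste0(substr(s, 1, 700), fwd, substr(s, 721, nchar(s)))
    s <- paste0(substr(s, 1, 900), chlorotype:::revcomp(rev),
                substr(s, 921, nchar(s)))
    s <- paste0(substr(s, 1, nchar(s) - 60), fwd,
                substr(s, nchar(s) - 39, nchar(s)))
    s <- paste0(substr(s, 1, 100), chlorotype:::revcomp(rev),
                substr(s, 121, nchar(s)))
    g <- cp_genome(g$id, s)
    for (mm in 0:1) {
      mine <- insilico_pcr(g, fwd, rev, max_mismatch = mm, max_product = 1500)
      oracle <- brute_pcr(g, fwd, rev, mm = mm, max_product = 1500)
      if (is.null(oracle)) {
        expect_equal(nrow(mine), 0)
      } else {
        expect_equal(nrow(mine), nrow(oracle))
        expect_equal(mine$start, oracle$start)
        expect_equal(mine$length, oracle$length)
        expect_equal(mine$strand, oracle$strand)
      }
    }
  }
})

test_that("the 3'-anchor rule vetoes sites with terminal mismatches", {
  set.seed(54)
  fwd <- "ACGGTTCCAAGGTTCCAACG"
  rev <- "TTCCGGAACCGGTTAAGGCC"
  tmpl <- paste0(rand_seq(300), fwd, rand_seq(100),
                 chlorotype:::revcomp(rev), rand_seq(300))
  # corrupt the fwd primer 3' terminal base in the template
  substr(tmpl, 300 + 20, 300 + 20) <- if (substr(fwd, 20, 20) == "A") "C" else "A"
  g <- cp_genome("t", tmpl)
  expect_equal(nrow(insilico_pcr(g, fwd, rev, max_mismatch = 1)), 0)
  # an internal mismatch is tolerated at max_mismatch = 1
  tmpl2 <- paste0(rand_seq(300), fwd, rand_seq(100),
                  chlorotype:::revcomp(rev), rand_seq(300))
  substr(tmpl2, 300 + 5, 300 + 5) <- if (substr(fwd, 5, 5) == "A") "C" else "A"
  g2 <- cp_genome("t2", tmpl2)
  expect_equal(nrow(insilico_pcr(g2, fwd, rev, max_mismatch = 0)), 0)
  expect_equal(nrow(insilico_pcr(g2, fwd, rev, max_mismatch = 1)), 1)
})

test_that("cytotype classification follows the marker consensus rule", {
  pair <- toy_pair()
  mk <- truth_markers(pair$truth)
  expect_equal(classify_cytotype(pair$S, mk)$call, "S")
  expect_equal(classify_cytotype(pair$N, mk)$call, "N")
  cs <- classify_cytotype(pair$S, mk)
  expect_equal(cs$len_cp_01, 270L)
  expect_equal(cs$len_cp_02, 265L)
  cn <- classify_cytotype(pair$N, mk)
  expect_equal(cn$len_cp_01, 242L)
  expect_equal(cn$len_cp_02, 243L)
  # mixed marker evidence is ambiguous: S at cp_01, N at cp_02
  mixed_mk <- mk
  mixed_mk$expected_S[2] <- mk$expected_N[2]
  mixed_mk$expected_N[2] <- 999L
  expect_equal(classify_cytotype(pair$S, mixed_mk)$call, "ambiguous")
  # no marker amplifies
  none <- marker_set("dead", "ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
                     270L, 242L)
  expect_equal(classify_cytotype(pair$S, none)$call, "no_amplification")
  expect_error(classify_cytotype(pair$S, mk[0, ]), "at least one marker")
})

test_that("sizing tolerance admits near-expected products", {
  pair <- toy_pair()
  mk <- truth_markers(pair$truth)
  mk$expected_S <- mk$expected_S + 2L      # still within the +/-2 default
  expect_equal(classify_cytotype(pair$S, mk)$call, "S")
  mk$expected_S <- mk$expected_S + 3L      # now 5 bp off: amplifies, matches neither
  expect_equal(classify_cytotype(pair$S, mk, tolerance_bp = 2)$call, "ambiguous")
})

test_that("cohort summaries tally cultivars and reject unmapped samples", {
  calls <- tibble::tibble(
    sample = sprintf("p%02d", 1:10),
    call = c(rep("S", 4), rep("N", 6)))
  manifest <- tibble::tibble(sample = calls$sample,
                             cultivar = rep(c("cvA", "cvB"), each = 5))
  summ <- summarize_cohort(calls, manifest)
  total <- summ[summ$cultivar == "Total", ]
  expect_equal(total$n_S, 4L)
  expect_equal(total$n_N, 6L)
  expect_equal(total$n_total, 10L)
  expect_equal(summ$n_total[summ$cultivar != "Total"], c(5L, 5L))
  expect_equal(summarize_cohort(calls[0, ], manifest)$n_total, 0L)
  bad <- dplyr::mutate(calls, sample = sub("p01", "mystery", sample))
  expect_error(summarize_cohort(bad, manifest), "mystery")
})
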