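test_that("pairwise distances count substitutions per compared site", {
  set.seed(60)
  a <- cp_genome("a", rand_seq(1000))
  expect_equal(pairwise_distance(a, cp_genome("b", a$seq), model = "p_distance"), 0)
  # exactly 10 of 1000 sites changed
  bseq <- a$seq
  pos <- seq(50, 950, by = 100)
  for (p in pos) {
    cur <- substr(bseq, p, p)
    substr(bseq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  b <- cp_genome("b", bseq)
  expect_equal(pairwise_distance(a, b, model = "p_distance"), 0.01)
  d_tn <- pairwise_distance(a, b, model = "tn93_mcl")
  expect_gt(d_tn, 0.0099)
  expect_lt(d_tn, 0.012)
})

test_that("the TN93 closed form cross-checks against ape's implementation", {
  set.seed(61)
  a <- cp_genome("a", rand_seq(4000))
  bseq <- a$seq
  pos <- sample(seq(20, 3980, by = 20), 80)
  for (p in pos) {
    cur <- substr(bseq, p, p)
    substr(bseq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  b <- cp_genome("b", bseq)
  bin <- ape::as.DNAbin(list(a = strsplit(tolower(a$seq), "")[[1]],
                             b = strsplit(tolower(bseq), "")[[1]]))
  d_ape <- as.numeric(ape::dist.dna(bin, model = "TN93"))
  d_mine <- pairwise_distance(a, b, model = "tn93_mcl")
  # ape estimates frequencies from the pair exactly as the pooled-pair case
  expect_equal(d_mine, d_ape, tolerance = 1e-6)
})

test_that("tn93 converges to the p-distance at low divergence", {
  set.seed(62)
  a <- cp_genome("a", rand_seq(50000))
  bseq <- a$seq
  for (p in c(7000, 21000, 38000)) {
    cur <- substr(bseq, p, p)
    substr(bseq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  b <- cp_genome("b", bseq)
  p_d <- pairwise_distance(a, b, model = "p_distance")
  tn <- pairwise_distance(a, b, model = "tn93_mcl")
  expect_lt(p_d, 1e-4)
  expect_lt(abs(tn - p_d), 1e-6)
})

test_that("neighbor joining recovers additive trees exactly", {
  # closed-form 3-taxon case
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(D3)
  expect_equal(sort(tr3$tip.label), c("a", "b", "c"))
  d <- stats::setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(d[c("a", "b", "c")]), c(2, 3, 7))
  # random additive matrices from random topologies
  for (seed in 1:5) {
    set.seed(seed * 13)
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- stats::runif(nrow(true_tree$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(true_tree)
    D <- D[order(rownames(D)), order(colnames(D))]
    mine <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), mine)), 0)
    # branch lengths are recovered (additivity)
    Dhat <- ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
    expect_equal(unname(Dhat), unname(D), tolerance = 1e-8)
    # cross-check against ape's NJ topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), mine)), 0)
  }
})

test_that("neighbor joining validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3)),
               "symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "3 taxa")
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- NA
  expect_error(neighbor_joining(m), "symmetric|finite")
})

test_that("bootstrap supports strong planted clades and is taxon-order invariant", {
  set.seed(63)
  base <- rand_seq(4000)
  clade_edit <- function(seq, positions) {
    for (p in positions) {
      cur <- substr(seq, p, p)
      substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    seq
  }
  shared_ab <- sample(seq(10, 3990, 8), 40)
  shared_cd <- sample(setdiff(seq(10, 3990, 8), shared_ab), 40)
  shared_ef <- sample(setdiff(seq(10, 3990, 8), c(shared_ab, shared_cd)), 40)
  private <- function() sample(setdiff(seq(11, 3991, 8),
                                       c(shared_ab, shared_cd, shared_ef)), 8)
  seqs <- list(
    A = clade_edit(clade_edit(base, shared_ab), private()),
    B = clade_edit(clade_edit(base, shared_ab), private()),
    C = clade_edit(clade_edit(base, shared_cd), private()),
    D = clade_edit(clade_edit(base, shared_cd), private()),
    E = clade_edit(clade_edit(base, shared_ef), private()),
    F = clade_edit(clade_edit(base, shared_ef), private()))
  genomes <- purrr::imap(seqs, ~ cp_genome(.y, .x))
  fit <- distance_matrix(unname(genomes), model = "p_distance")
  bs <- bootstrap_support(fit, n_reps = 200, seed = 9)
  key_ab <- paste(sort(c("C", "D", "E", "F")), collapse = "|")  # complement of {A,B}
  for (k in c(key_ab, "C|D", "E|F")) {
    expect_gte(bs$splits$support[bs$splits$bipartition == k], 95)
  }
  expect_false(bs$degenerate)
  # permuting the input order leaves supports unchanged (same seed scheme)
  fit2 <- distance_matrix(unname(genomes)[c(3, 1, 6, 2, 5, 4)],
                          model = "p_distance", ref = 2)
  bs2 <- bootstrap_support(fit2, n_reps = 200, seed = 9)
  common <- intersect(bs$splits$bipartition, bs2$splits$bipartition)
  expect_gte(length(common), 3)
  for (k in common) {
    expect_equal(bs2$splits$support[bs2$splits$bipartition == k],
                 bs$splits$support[bs$splits$bipartition == k])
  }
  expect_error(bootstrap_support(fit, n_reps = 0), "n_reps")
})

test_that("identical sequences give a degenerate all-100 bootstrap", {
  set.seed(64)
  s <- rand_seq(2000)
  genomes <- purrr::map(1:4, ~ cp_genome(paste0("t", .x), s))
  fit <- distance_matrix(genomes, model = "p_distance")
  bs <- bootstrap_support(fit, n_reps = 10, seed = 1)
  expect_true(bs$degenerate)
  expect_true(all(bs$splits$support == 100))
})

test_that("distance outputs round-trip through PHYLIP and tidy forms", {
  set.seed(65)
  s <- rand_seq(1500)
  g <- purrr::map(1:3, function(i) {
    seq <- s
    p <- 100 * i
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    cp_genome(paste0("t", i), seq)
  })
  fit <- distance_matrix(g, model = "p_distance")
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(td$distance >= 0))
  p <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(fit, p)
  lines <- readLines(p)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
  gl <- glance(fit)
  expect_equal(gl$n_taxa, 3L)
  expect_equal(sum(gl$freq_A, gl$freq_C, gl$freq_G, gl$freq_T), 1)
})
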