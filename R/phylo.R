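## Distances, neighbor-joining and bootstrap over a set of genomes.
##
## The multi-genome alignment is a star alignment: every genome is aligned
## pairwise to a designated reference and projected onto reference
## coordinates (insertions relative to the reference are not columns).
## Justified here because the genomes of interest exceed 99.9% identity;
## the limitation is documented in the methods vignette.

CODE_GAP <- 6L
CODE_N <- 5L

seq_codes <- function(seq) {
  x <- match(seq_chars(seq), c("A", "C", "G", "T", "N"))
  x[is.na(x)] <- CODE_N
  as.integer(x)
}

# query bases projected onto reference coordinates (gap where deleted)
project_onto_ref <- function(aln) {
  nr <- nchar(aln$ref_seq)
  out <- rep.int(CODE_GAP, nr)
  qcodes <- seq_codes(aln$qry_seq)
  ops <- aln$ops
  for (z in seq_len(nrow(ops))) {
    op <- ops$op[z]
    if (op %in% c("M", "X")) {
      len <- ops$len[z]
      out[(ops$ref_pos[z] + 1):(ops$ref_pos[z] + len)] <-
        qcodes[(ops$qry_pos[z] + 1):(ops$qry_pos[z] + len)]
    }
  }
  out
}

#' Star alignment and genetic distance matrix for a genome set
#'
#' Aligns every genome to the first (or `ref`) with [align_genomes()],
#' builds the column matrix on reference coordinates, collapses columns to
#' site patterns, and computes all pairwise distances with pairwise
#' deletion of gap/N columns. For `tn93_mcl`, base frequencies are pooled
#' across the whole set (composite estimation) and each pair contributes
#' its own transition/transversion proportions to the Tamura-Nei closed
#' form.
#'
#' @param genomes list of [cp_genome()] objects.
#' @param model `"p_distance"` or `"tn93_mcl"`.
#' @param ref index of the star-alignment reference genome.
#' @param ... passed to [align_genomes()].
#' @return a `cp_distfit`: taxa, distance matrix `D`
#'   (substitutions/site), model, pooled frequencies and the compressed
#'   site patterns used for bootstrapping.
#' @export
distance_matrix <- function(genomes, model = c("tn93_mcl", "p_distance"),
                            ref = 1, ...) {
  model <- match.arg(model)
  if (length(genomes) < 2) abort("need at least two genomes")
  taxa <- map_chr(genomes, "id")
  if (anyDuplicated(taxa)) abort("genome ids must be unique")
  nr <- nchar(genomes[[ref]]$seq)
  M <- matrix(0L, nrow = nr, ncol = length(genomes))
  colnames(M) <- taxa
  M[, ref] <- seq_codes(genomes[[ref]]$seq)
  for (z in seq_along(genomes)) {
    if (z == ref) next
    M[, z] <- project_onto_ref(align_genomes(genomes[[ref]], genomes[[z]], ...))
  }
  pat <- compress_patterns(M)
  freqs <- pooled_base_freqs(pat$P, pat$w)
  D <- dist_from_patterns(pat$P, pat$w, model, freqs)
  dimnames(D) <- list(taxa, taxa)
  structure(
    list(taxa = taxa, D = D, model = model, freqs = freqs,
         patterns = pat, n_sites = nr, ref = taxa[ref]),
    class = "cp_distfit")
}

#' @export
print.cp_distfit <- function(x, ...) {
  cat(sprintf("<cp_distfit> %d taxa, %s model, %d site patterns over %d sites\n",
              length(x$taxa), x$model, nrow(x$patterns$P), x$n_sites))
  print(round(x$D, 6))
  invisible(x)
}

compress_patterns <- function(M) {
  key <- do.call(paste, c(as.data.frame(M), sep = ""))
  first <- !duplicated(key)
  P <- M[first, , drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(P = P, w = w)
}

pooled_base_freqs <- function(P, w) {
  counts <- numeric(4)
  for (b in 1:4) counts[b] <- sum(w * rowSums(P == b))
  stats::setNames(counts / sum(counts), c("A", "C", "G", "T"))
}

# pairwise distance matrix from site patterns P (patterns x taxa) with
# weights w; pairwise deletion of gap/N columns
dist_from_patterns <- function(P, w, model, freqs) {
  t <- ncol(P)
  D <- matrix(0, t, t)
  for (x in 1:(t - 1)) {
    for (y in (x + 1):t) {
      st <- pair_site_stats(P[, x], P[, y], w)
      if (st$n == 0) abort("zero compared sites between a genome pair")
      d <- if (model == "p_distance") {
        (st$p1 + st$p2 + st$q) / st$n
      } else {
        tn93_distance(st$p1 / st$n, st$p2 / st$n, st$q / st$n, freqs)
      }
      D[x, y] <- D[y, x] <- d
    }
  }
  D
}

pair_site_stats <- function(a, b, w) {
  valid <- a <= 4L & b <= 4L
  diff <- valid & (a != b)
  ts1 <- diff & ((a == 1L & b == 3L) | (a == 3L & b == 1L))  # A<->G
  ts2 <- diff & ((a == 2L & b == 4L) | (a == 4L & b == 2L))  # C<->T
  list(n = sum(w[valid]),
       p1 = sum(w[ts1]), p2 = sum(w[ts2]),
       q = sum(w[diff & !ts1 & !ts2]))
}

#' Tamura-Nei (1993) distance from substitution proportions
#'
#' @param P1,P2 purine (A<->G) and pyrimidine (C<->T) transition
#'   proportions; `Q` the transversion proportion.
#' @param freqs named base frequencies (A, C, G, T), typically pooled
#'   across the genome set.
#' @return distance in substitutions/site (`NaN` when saturation makes a
#'   logarithm argument non-positive).
#' @export
tn93_distance <- function(P1, P2, Q, freqs) {
  pa <- freqs[["A"]]; pc <- freqs[["C"]]; pg <- freqs[["G"]]; pt <- freqs[["T"]]
  pr <- pa + pg; py <- pc + pt
  k1 <- 2 * pa * pg / pr
  k2 <- 2 * pt * pc / py
  k3 <- 2 * (pr * py - pa * pg * py / pr - pt * pc * pr / py)
  a1 <- 1 - P1 / k1 - Q / (2 * pr)
  a2 <- 1 - P2 / k2 - Q / (2 * py)
  a3 <- 1 - Q / (2 * pr * py)
  if (a1 <= 0 || a2 <= 0 || a3 <= 0) {
    warn("TN93 distance undefined (saturated); returning NaN")
    return(NaN)
  }
  -k1 * log(a1) - k2 * log(a2) - k3 * log(a3)
}

#' Pairwise genetic distance between two genomes
#'
#' Convenience wrapper building a two-genome [distance_matrix()]; gap and N
#' columns are excluded. For `tn93_mcl` the base frequencies are pooled
#' over the pair unless `freqs` is supplied (e.g. from a larger set).
#'
#' @inheritParams distance_matrix
#' @param a,b [cp_genome()] objects.
#' @param freqs optional named base frequencies to use instead of the
#'   pair's own pooled frequencies.
#' @return a single distance (substitutions/site), unrounded.
#' @export
pairwise_distance <- function(a, b, model = c("tn93_mcl", "p_distance"),
                              freqs = NULL, ...) {
  model <- match.arg(model)
  fit <- distance_matrix(list(a, b), model = "p_distance", ...)
  if (model == "p_distance") return(fit$D[1, 2])
  st <- pair_site_stats(fit$patterns$P[, 1], fit$patterns$P[, 2], fit$patterns$w)
  tn93_distance(st$p1 / st$n, st$p2 / st$n, st$q / st$n,
                freqs %||% fit$freqs)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard Q-criterion agglomeration with a deterministic tie-break
#' (smallest node-index pair). Negative branch lengths are kept unless
#' `clamp = TRUE`, in which case they are set to zero and the deficit is
#' moved to the sibling branch.
#'
#' @param D distance matrix with taxon dimnames, or a `cp_distfit`.
#' @param clamp clamp negative branch lengths.
#' @return an unrooted `phylo` (ape) tree.
#' @export
neighbor_joining <- function(D, clamp = FALSE) {
  if (inherits(D, "cp_distfit")) D <- D$D
  if (any(!is.finite(D)) || !isSymmetric(unname(D))) {
    abort("distance matrix must be symmetric and finite")
  }
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  taxa <- rownames(D) %||% paste0("t", 1:n)
  node_id <- 1:n                     # ape numbering: tips 1..n
  next_internal <- n + 1L
  edges <- list()
  Dc <- D
  active <- seq_len(n)               # indices into node_id
  while (length(active) > 2) {
    m <- length(active)
    R <- rowSums(Dc)
    Q <- (m - 2) * Dc - outer(R, R, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dc[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (clamp) {
      if (vi < 0) { vj <- vj + vi; vi <- 0 }
      if (vj < 0) { vi <- vi + vj; vj <- 0 }
    }
    u <- next_internal; next_internal <- next_internal + 1L
    edges[[length(edges) + 1]] <- c(u, node_id[i], vi)
    edges[[length(edges) + 1]] <- c(u, node_id[j], vj)
    duk <- (Dc[i, ] + Dc[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    node_id <- c(node_id[keep], u)
    active <- seq_len(nrow(Dc))
  }
  edges[[length(edges) + 1]] <- c(node_id[1], node_id[2], Dc[1, 2])
  build_phylo(edges, taxa, n_internal = next_internal - n - 1L)
}

# orient an undirected edge list away from the highest-numbered internal node
build_phylo <- function(edges, taxa, n_internal) {
  E <- do.call(rbind, edges)
  n <- length(taxa)
  root <- n + n_internal            # last created internal node
  nodes <- sort(unique(c(E[, 1], E[, 2])))
  nbr <- lapply(stats::setNames(nodes, nodes), function(v) {
    which(E[, 1] == v | E[, 2] == v)
  })
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  visited <- stats::setNames(logical(length(nodes)), as.character(nodes))
  stack <- root
  visited[as.character(root)] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (ei in nbr[[as.character(v)]]) {
      w <- if (E[ei, 1] == v) E[ei, 2] else E[ei, 1]
      if (visited[as.character(w)]) next
      visited[as.character(w)] <- TRUE
      parent <- c(parent, v); child <- c(child, w); len <- c(len, E[ei, 3])
      stack <- c(stack, w)
    }
  }
  # ape numbering: tips 1..n, internal n+1..n+Nnode with the root first
  internal <- unique(parent)
  others <- setdiff(internal, root)
  remap <- stats::setNames(c(n + 1L, if (length(others)) (n + 2L):(n + 1L + length(others))),
                           as.character(c(root, others)))
  map_node <- function(v) ifelse(v <= n, v, remap[as.character(v)])
  tr <- list(edge = cbind(unname(map_node(parent)), unname(map_node(child))),
             edge.length = len,
             tip.label = taxa,
             Nnode = length(internal))
  class(tr) <- "phylo"
  tr <- tryCatch(ape::reorder.phylo(tr, "cladewise"), error = function(e) tr)
  tr
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement (via the compressed site
#' patterns), recomputes the distance matrix and NJ tree per replicate
#' (replicate r uses `seed + r`), and reports the percentage of replicates
#' containing each internal bipartition of the original tree. When all
#' pairwise distances are zero the topology carries no signal; all
#' supports are reported as 100 and the result is flagged degenerate.
#'
#' @param fit a `cp_distfit` from [distance_matrix()].
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param clamp passed to [neighbor_joining()].
#' @return list: `tree` (original NJ tree with node labels = support),
#'   `splits` tibble (bipartition, support), `degenerate` flag.
#' @export
bootstrap_support <- function(fit, n_reps = 1000, seed = 1, clamp = FALSE) {
  stopifnot(inherits(fit, "cp_distfit"))
  if (n_reps < 1) abort("n_reps must be >= 1")
  tree <- neighbor_joining(fit$D, clamp = clamp)
  sp <- tree_splits(tree)
  if (all(fit$D == 0)) {
    supports <- rep(100, length(sp$key))
    return(finish_bootstrap(tree, sp, supports, degenerate = TRUE))
  }
  P <- fit$patterns$P; w <- fit$patterns$w
  n_sites <- sum(w)
  hits <- stats::setNames(numeric(length(sp$key)), sp$key)
  for (r in seq_len(n_reps)) {
    set.seed((seed + r) %% .Machine$integer.max)
    wr <- as.vector(stats::rmultinom(1, n_sites, w / n_sites))
    Dr <- dist_from_patterns(P, wr, fit$model, pooled_base_freqs(P, wr))
    dimnames(Dr) <- dimnames(fit$D)
    spr <- tree_splits(neighbor_joining(Dr, clamp = clamp))
    hits[sp$key %in% spr$key] <- hits[sp$key %in% spr$key] + 1
  }
  finish_bootstrap(tree, sp, 100 * hits / n_reps, degenerate = FALSE)
}

finish_bootstrap <- function(tree, sp, supports, degenerate) {
  lab <- rep(NA_character_, tree$Nnode)
  lab[sp$node - length(tree$tip.label)] <- formatC(supports, format = "f", digits = 0)
  tree$node.label <- lab
  list(tree = tree,
       splits = tibble(bipartition = sp$key, support = unname(supports)),
       degenerate = degenerate)
}

# non-trivial bipartitions of an unrooted tree, canonicalized so the
# reported side excludes the first tip label (sorted)
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  desc <- clade_tips(tree)
  nodes <- (n + 2L):(n + tree$Nnode)        # skip the root trichotomy node
  if (tree$Nnode < 2) return(list(key = character(0), node = integer(0)))
  keys <- character(0); knodes <- integer(0)
  anchor <- sort(tree$tip.label)[1]
  for (v in nodes) {
    tips <- tree$tip.label[desc[[v]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
    knodes <- c(knodes, v)
  }
  list(key = keys, node = knodes)
}

# tip indices under each node (postorder accumulation)
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  res <- vector("list", n + tree$Nnode)
  for (i in 1:n) res[[i]] <- i
  E <- tree$edge
  for (ei in ape::postorder(tree)) {
    p <- E[ei, 1]; c <- E[ei, 2]
    res[[p]] <- c(res[[p]], res[[c]])
  }
  res
}

#' Write a distance matrix in square PHYLIP format
#' @param D matrix (or `cp_distfit`).
#' @param path output path.
#' @export
write_phylip <- function(D, path) {
  if (inherits(D, "cp_distfit")) D <- D$D
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste0(formatC(rownames(D)[i], width = -10),
                      paste(formatC(D[i, ], format = "f", digits = 8),
                            collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
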