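# Independent oracles: brute-force / full-matrix reference implementations
# used to validate the production code paths. These deliberately share no
# machinery with the package internals.

# ---- full-matrix affine-gap Needleman-Wunsch (row-vectorised Gotoh) ----
# Scoring convention: a gap of length L costs open + ext * L.
# Returns a cp_alignment-compatible object so call_variants() can be run
# on the oracle alignment directly.
nw_oracle <- function(ref, qry, match = 1, mismatch = -2, open = 4, ext = 1) {
  a <- strsplit(ref$seq, "")[[1]]
  b <- strsplit(qry$seq, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in ref (insertion, consumes qry)
  F <- matrix(NEG, n + 1, m + 1)  # gap in qry (deletion, consumes ref)
  H[1, ] <- -(open + ext * (0:m)); H[1, 1] <- 0
  H[, 1] <- -(open + ext * (0:n)); H[1, 1] <- 0
  E[1, ] <- H[1, ]
  F[, 1] <- H[, 1]
  for (i in 2:(n + 1)) {
    s <- ifelse(a[i - 1] == b, match, mismatch)       # length m
    F[i, ] <- pmax(H[i - 1, ] - open - ext, F[i - 1, ] - ext)
    diagv <- H[i - 1, 1:m] + s
    H0 <- pmax(c(H[i, 1], diagv), c(NEG, F[i, 2:(m + 1)]))
    # E via running max of H0[k] + k*ext (single opener dominates chains)
    run <- cummax(H0 + ext * (0:m))
    Erow <- c(NEG, run[1:m] - open - ext * (1:m))
    H[i, ] <- pmax(H0, Erow)
    E[i, ] <- Erow
  }
  # traceback
  ops <- character(0)
  i <- n + 1; j <- m + 1
  tol <- 1e-9
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 &&
        abs(H[i, j] - (H[i - 1, j - 1] +
                       if (a[i - 1] == b[j - 1]) match else mismatch)) < tol) {
      ops <- c(if (a[i - 1] == b[j - 1]) "M" else "X", ops)
      i <- i - 1; j <- j - 1
    } else if (j > 1 && abs(H[i, j] - E[i, j]) < tol) {
      repeat {
        ops <- c("I", ops); j <- j - 1
        if (j == 1 || abs(E[i, j + 1] - (H[i, j] - open - ext)) < tol) break
      }
    } else {
      repeat {
        ops <- c("D", ops); i <- i - 1
        if (i == 1 || abs(F[i + 1, j] - (H[i, j] - open - ext)) < tol) break
      }
    }
  }
  r <- rle(ops)
  obj <- list(ref_id = ref$id, qry_id = qry$id,
              ref_seq = ref$seq, qry_seq = qry$seq,
              ops = chlorotype:::add_op_positions(
                tibble::tibble(op = r$values, len = r$lengths)),
              identity = sum(ops == "M") / length(ops),
              params = list(score = H[n + 1, m + 1]))
  class(obj) <- "cp_alignment"
  obj
}

nw_oracle_score <- function(aln_obj) aln_obj$params$score

# score of any cp_alignment under the same convention
score_alignment <- function(aln, match = 1, mismatch = -2, open = 4, ext = 1) {
  with(aln$ops, sum(ifelse(op == "M", match * len,
                    ifelse(op == "X", mismatch * len,
                           -(open + ext * len)))))
}

# canonical event-set signature of a call set (order-free)
event_signature <- function(variants) {
  v <- variants[order(variants$ref_pos, variants$type, variants$alt), ]
  paste(v$ref_pos, v$type, v$ref, v$alt, sep = ":", collapse = ";")
}

# ---- brute-force maximal inverted repeat (k = 1 diagonal scan) ----
brute_max_ir <- function(seq, min_len) {
  n <- nchar(seq)
  S <- strsplit(seq, "")[[1]]
  R <- strsplit(chlorotype:::revcomp(seq), "")[[1]]
  best <- NULL
  for (d in 0:(n - 1)) {
    idx <- ((0:(n - 1) + d) %% n) + 1
    mvec <- S == R[idx]
    if (all(mvec)) next
    r <- rle(mvec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], len = r$lengths[r$values])
    if (nrow(runs) == 0) next
    # circular wrap: first and last TRUE runs join
    if (r$values[1] && r$values[length(r$values)] && nrow(runs) > 1) {
      runs$len[nrow(runs)] <- runs$len[nrow(runs)] + runs$len[1]
      runs <- runs[-1, , drop = FALSE]
    }
    for (z in seq_len(nrow(runs))) {
      L <- runs$len[z]
      if (L < min_len || L >= n) next
      a <- runs$start[z] - 1
      j0 <- (a + d) %% n
      b <- (n - j0 - L) %% n
      if (!chlorotype:::circ_disjoint(a, L, b, L, n)) next
      gap1 <- (b - (a + L)) %% n
      gap2 <- (a - (b + L)) %% n
      cand <- list(a = min(a, b), b = max(a, b), len = L,
                   ssc = min(gap1, gap2))
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$ssc < best$ssc) ||
          (cand$len == best$len && cand$ssc == best$ssc && cand$a < best$a)) {
        best <- cand
      }
    }
  }
  best
}

# ---- brute-force in-silico PCR (character-level all-position scan) ----
brute_pcr <- function(genome, fwd, rev, mm = 0, max_product = 2000) {
  s <- genome$seq
  n <- nchar(s)
  tmpl <- if (genome$circular) paste0(s, substr(s, 1, min(max_product, n))) else s
  tchars <- strsplit(tmpl, "")[[1]]
  site_scan <- function(pat, three_prime_end) {
    p <- strsplit(pat, "")[[1]]
    L <- length(p)
    out <- integer(0)
    for (st in 1:(length(tchars) - L + 1)) {
      win <- tchars[st:(st + L - 1)]
      if (sum(win != p) > mm) next
      anchor <- if (three_prime_end) (L - 2):L else 1:3
      if (any(win[anchor] != p[anchor])) next
      out <- c(out, st)
    }
    out
  }
  one_dir <- function(left, right, strand) {
    lf <- nchar(left); lr <- nchar(right)
    fs <- site_scan(left, TRUE)
    fs <- fs[fs <= n]
    rs <- site_scan(chlorotype:::revcomp(right), FALSE)
    res <- list()
    for (f in fs) {
      ends <- rs[rs >= f + lf] + lr - 1
      len <- ends - f + 1
      keep <- len <= max_product
      if (any(keep)) {
        res[[length(res) + 1]] <- data.frame(
          start = (f - 1) %% n, length = len[keep], strand = strand)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  out <- rbind(one_dir(fwd, rev, "+"), one_dir(rev, fwd, "-"))
  if (is.null(out)) return(out)
  out <- out[out$length <= n, , drop = FALSE]     # no product past a full circle
  if (nrow(out) == 0) return(NULL)
  unique(out[order(out$length, out$start), ])
}

# ---- exhaustive tandem-unit search -----------------------------------
brute_tandem <- function(event_seq, ref_seq, qry_seq, p_ref, p_qry, is_ins,
                         max_unit = 100) {
  L <- nchar(event_seq)
  ref_chars <- strsplit(ref_seq, "")[[1]]
  qry_chars <- strsplit(qry_seq, "")[[1]]
  ev <- strsplit(event_seq, "")[[1]]
  count_from <- function(chars, p, unit) {
    u <- length(unit); cnt <- 0
    while (p + (cnt + 1) * u <= length(chars) &&
           all(chars[(p + cnt * u + 1):(p + (cnt + 1) * u)] == unit)) {
      cnt <- cnt + 1
    }
    cnt
  }
  for (u in 1:min(L, max_unit)) {
    if (L %% u != 0) next
    unit <- ev[1:u]
    if (!all(ev == rep(unit, L / u))) next
    # primitivity
    prim <- TRUE
    for (d in 1:(u - 1)) {
      if (u %% d == 0 && all(unit == rep(unit[1:d], u / d))) { prim <- FALSE; break }
    }
    if (u > 1 && !prim) next
    c_ref <- count_from(ref_chars, p_ref, unit)
    c_qry <- count_from(qry_chars, p_qry, unit)
    extra <- if (is_ins) c_ref else c_ref - L / u
    if (extra < 1) next
    if (abs(c_ref - c_qry) * u != L) next
    return(list(unit = paste(unit, collapse = ""), unit_len = u,
                copies_ref = c_ref, copies_qry = c_qry))
  }
  NULL
}

# ---- misc -------------------------------------------------------------
# all 1-based positions at which an insertion of `s` into `ref` yields the
# same haplotype; the minimum is the left-normalized position
equivalent_insertion_points <- function(ref_seq, p0, s) {
  hap <- paste0(substr(ref_seq, 1, p0), s,
                substr(ref_seq, p0 + 1, nchar(ref_seq)))
  L <- nchar(s)
  keep <- integer(0)
  for (p in 0:nchar(ref_seq)) {
    cand <- paste0(substr(ref_seq, 1, p),
                   substr(hap, p + 1, p + L),
                   substr(ref_seq, p + 1, nchar(ref_seq)))
    if (cand == hap) keep <- c(keep, p)
  }
  keep
}

rand_seq <- function(n, gc = 40) chlorotype:::rand_dna(n, gc)
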