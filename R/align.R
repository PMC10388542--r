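#' Anchored global alignment of two near-identical genomes
#'
#' Shared k-mers that are unique in both sequences anchor a collinear chain
#' (longest strictly increasing subsequence in query order); the intervals
#' between anchor runs are closed by affine-gap global alignment
#' (match +1, mismatch -2, gap open -4, gap extend -1 per gapped base).
#' Both genomes should be canonically rotated first so that coordinates are
#' comparable; the alignment is computed on the linearizations, so an event
#' at the very ends is flagged as potentially origin-spanning downstream.
#'
#' @param ref,qry [cp_genome()] objects (reference and query).
#' @param k anchor k-mer size.
#' @param max_window largest inter-anchor window the banded closer will
#'   attempt (bp); larger windows raise an error suggesting parameters.
#' @param min_coverage minimum fraction of the reference that anchor runs
#'   must cover before the genomes are declared too divergent.
#' @return a `cp_alignment`: run-length encoded column operations
#'   (`M` match, `X` mismatch, `I` insertion in query, `D` deletion from
#'   query) with 0-based `ref_pos`/`qry_pos` run starts, plus both sequences
#'   and the column identity.
#' @export
align_genomes <- function(ref, qry, k = 21, max_window = 20000,
                          min_coverage = 0.5) {
  stopifnot(inherits(ref, "cp_genome"), inherits(qry, "cp_genome"))
  rs <- ref$seq; qs <- qry$seq
  nr <- nchar(rs); nq <- nchar(qs)
  params <- list(k = k, max_window = max_window,
                 scoring = c(match = 1, mismatch = -2, gap_open = -4, gap_ext = -1))

  if (rs == qs) {
    ops <- tibble(op = "M", len = nr, ref_pos = 0L, qry_pos = 0L)
    return(new_cp_alignment(ref, qry, ops, params))
  }
  anchors <- shared_unique_anchors(rs, qs, k)
  if (nrow(anchors) == 0) {
    abort("genomes too divergent: no unique shared anchors")
  }
  chain_idx <- lis_chain(anchors$qpos)
  chain <- anchors[chain_idx, , drop = FALSE]
  covered <- anchor_coverage(chain$rpos, k)
  if (covered < min_coverage * nr) {
    abort(sprintf(
      "genomes too divergent: anchor chain covers %.1f%% of the reference (need >= %.0f%%)",
      100 * covered / nr, 100 * min_coverage))
  }
  runs <- anchors_to_runs(chain, k)
  runs <- trim_run_overlaps(runs)

  pieces <- list()
  r_at <- 0L; q_at <- 0L
  for (z in seq_len(nrow(runs))) {
    pieces[[length(pieces) + 1]] <-
      window_ops(substr(rs, r_at + 1, runs$r0[z]),
                 substr(qs, q_at + 1, runs$q0[z]), max_window)
    pieces[[length(pieces) + 1]] <- tibble(op = "M", len = runs$len[z])
    r_at <- runs$r0[z] + runs$len[z]
    q_at <- runs$q0[z] + runs$len[z]
  }
  pieces[[length(pieces) + 1]] <-
    window_ops(substr(rs, r_at + 1, nr), substr(qs, q_at + 1, nq), max_window)
  ops <- bind_rows(compact(pieces))
  ops <- rle_merge(ops)
  ops <- add_op_positions(ops)
  new_cp_alignment(ref, qry, ops, params)
}

new_cp_alignment <- function(ref, qry, ops, params) {
  ops <- add_op_positions(ops)
  nr <- nchar(ref$seq); nq <- nchar(qry$seq)
  stopifnot(sum(ops$len[ops$op %in% c("M", "X", "D")]) == nr,
            sum(ops$len[ops$op %in% c("M", "X", "I")]) == nq)
  structure(
    list(ref_id = ref$id, qry_id = qry$id,
         ref_seq = ref$seq, qry_seq = qry$seq,
         ops = ops,
         identity = sum(ops$len[ops$op == "M"]) / sum(ops$len),
         params = params),
    class = "cp_alignment")
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat(sprintf("<cp_alignment> %s vs %s: %d columns, identity %.4f%%\n",
              x$ref_id, x$qry_id, sum(x$ops$len), 100 * x$identity))
  tab <- x$ops %>% group_by(.data$op) %>%
    summarise(events = n(), columns = sum(.data$len))
  print(tab)
  invisible(x)
}

add_op_positions <- function(ops) {
  dr <- ifelse(ops$op %in% c("M", "X", "D"), ops$len, 0L)
  dq <- ifelse(ops$op %in% c("M", "X", "I"), ops$len, 0L)
  ops$ref_pos <- as.integer(cumsum(c(0L, dr))[seq_len(nrow(ops))])
  ops$qry_pos <- as.integer(cumsum(c(0L, dq))[seq_len(nrow(ops))])
  ops
}

rle_merge <- function(ops) {
  if (nrow(ops) < 2) return(ops)
  same <- c(FALSE, ops$op[-1] == ops$op[-nrow(ops)])
  grp <- cumsum(!same)
  ops %>%
    mutate(.g = grp) %>%
    group_by(.data$.g) %>%
    summarise(op = first(.data$op), len = sum(.data$len), .groups = "drop") %>%
    select("op", "len") %>%
    filter(.data$len > 0)
}

shared_unique_anchors <- function(rs, qs, k) {
  nr <- nchar(rs); nq <- nchar(qs)
  rk <- substring(rs, 1:(nr - k + 1), k:nr)
  qk <- substring(qs, 1:(nq - k + 1), k:nq)
  r_uni <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  q_uni <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
  hit <- match(qk, rk)
  keep <- which(q_uni & !is.na(hit) & r_uni[hit])
  tb <- tibble(rpos = hit[keep] - 1L, qpos = keep - 1L)
  arrange(tb, .data$rpos)
}

# longest strictly increasing subsequence; returns indices into q
lis_chain <- function(q) {
  n <- length(q)
  tails <- integer(n)
  tails_idx <- integer(n)
  tlen <- 0L
  prev <- integer(n)
  for (t in seq_len(n)) {
    if (tlen > 0L && q[t] > tails[tlen]) {
      j <- tlen                          # common case: extends the chain
    } else {
      lo <- 1L; hi <- tlen; j <- 0L      # binary search: last tail < q[t]
      while (lo <= hi) {
        mid <- (lo + hi) %/% 2L
        if (tails[mid] < q[t]) { j <- mid; lo <- mid + 1L } else hi <- mid - 1L
      }
    }
    prev[t] <- if (j > 0L) tails_idx[j] else 0L
    tails[j + 1L] <- q[t]
    tails_idx[j + 1L] <- t
    if (j + 1L > tlen) tlen <- j + 1L
  }
  out <- integer(tlen)
  t <- tails_idx[tlen]
  pos <- tlen
  while (t > 0L) { out[pos] <- t; pos <- pos - 1L; t <- prev[t] }
  out
}

anchor_coverage <- function(rpos, k) {
  if (length(rpos) == 0) return(0L)
  starts <- rpos
  ends <- rpos + k
  gap_new <- c(TRUE, starts[-1] > ends[-length(ends)])
  grp <- cumsum(gap_new)
  sum(tapply(ends, grp, max) - tapply(starts, grp, min))
}

anchors_to_runs <- function(chain, k) {
  d <- chain$rpos - chain$qpos
  brk <- c(TRUE, !(diff(chain$rpos) <= k & diff(d) == 0))
  grp <- cumsum(brk)
  tibble(
    r0 = as.integer(tapply(chain$rpos, grp, min)),
    q0 = as.integer(tapply(chain$qpos, grp, min)),
    len = as.integer(tapply(chain$rpos, grp, max) - tapply(chain$rpos, grp, min) + k)
  )
}

trim_run_overlaps <- function(runs) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (z in 2:nrow(runs)) {
    cur <- runs[z, ]
    prev <- out[nrow(out), ]
    t <- max(prev$r0 + prev$len - cur$r0, prev$q0 + prev$len - cur$q0, 0L)
    if (t >= cur$len) next
    cur$r0 <- cur$r0 + t; cur$q0 <- cur$q0 + t; cur$len <- cur$len - t
    out <- bind_rows(out, cur)
  }
  out
}

# close one inter-anchor window with Biostrings' global aligner
window_ops <- function(refseg, qryseg, max_window) {
  lr <- nchar(refseg); lq <- nchar(qryseg)
  if (lr == 0 && lq == 0) return(NULL)
  if (lr == 0) return(tibble(op = "I", len = lq))
  if (lq == 0) return(tibble(op = "D", len = lr))
  if (max(lr, lq) > max_window) {
    abort(sprintf(
      "inter-anchor window of %d bp exceeds max_window = %d; raise max_window or lower k",
      max(lr, lq), max_window))
  }
  if (refseg == qryseg) return(tibble(op = "M", len = lr))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qryseg),
    subject = Biostrings::DNAString(refseg),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  aligned_ops(as.character(Biostrings::alignedSubject(pa)),
              as.character(Biostrings::alignedPattern(pa)))
}

# per-column ops from two gapped strings (ref row, qry row)
aligned_ops <- function(ref_row, qry_row) {
  a <- charToRaw(ref_row)
  b <- charToRaw(qry_row)
  gap <- charToRaw("-")[1]
  op <- ifelse(a == gap, "I", ifelse(b == gap, "D", ifelse(a == b, "M", "X")))
  r <- rle(op)
  tibble(op = r$values, len = r$lengths)
}
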