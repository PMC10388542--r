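#' Detect the quadripartite structure of a chloroplast genome
#'
#' Finds the maximal pair of disjoint exact reverse-complement repeats of at
#' least `min_ir_len` bp on the circular sequence (the inverted repeats IRa
#' and IRb), maximally extended. The shorter single-copy segment between the
#' arms is the SSC, the longer is the LSC; IRb is the arm adjacent to the
#' LSC's right end in the linear order LSC-IRb-SSC-IRa. Ties between equally
#' long arm pairs are broken by smaller SSC, then by lowest start coordinate.
#'
#' @param genome a [cp_genome()].
#' @param min_ir_len minimum inverted-repeat arm length (bp).
#' @return a `cp_structure`: list with `genome_id`, `genome_length`,
#'   `gc_percent` (two decimals, half-up) and a `regions` tibble
#'   (region/start/length; `start` is 0-based on the input linearization and
#'   a region may wrap the origin).
#' @export
detect_structure <- function(genome, min_ir_len = 1000) {
  stopifnot(inherits(genome, "cp_genome"))
  n <- nchar(genome$seq)
  if (n <= 2 * min_ir_len) {
    abort(sprintf("genome length %d too short for min_ir_len %d", n, min_ir_len))
  }
  cand <- find_inverted_repeats(genome$seq, min_ir_len)
  if (nrow(cand) == 0) {
    abort(
      sprintf("no quadripartite structure: no inverted repeat >= %d bp in %s",
              min_ir_len, genome$id),
      class = "chlorotype_no_structure")
  }
  best <- cand %>%
    mutate(
      gap1 = (.data$b - (.data$a + .data$len)) %% n,
      gap2 = (.data$a - (.data$b + .data$len)) %% n,
      ssc_len = pmin(.data$gap1, .data$gap2)
    ) %>%
    arrange(desc(.data$len), .data$ssc_len, .data$a) %>%
    slice(1)

  L <- best$len
  # the longer gap is LSC; IRb is the arm at the LSC's right end
  if (best$gap1 >= best$gap2) {
    lsc_start <- (best$a + L) %% n; lsc_len <- best$gap1
    irb_start <- best$b; ssc_start <- (best$b + L) %% n; ssc_len <- best$gap2
    ira_start <- best$a
  } else {
    lsc_start <- (best$b + L) %% n; lsc_len <- best$gap2
    irb_start <- best$a; ssc_start <- (best$a + L) %% n; ssc_len <- best$gap1
    ira_start <- best$b
  }
  regions <- tibble(
    region = c("lsc", "irb", "ssc", "ira"),
    start = as.integer(c(lsc_start, irb_start, ssc_start, ira_start)),
    length = as.integer(c(lsc_len, L, ssc_len, L))
  )
  stopifnot(sum(regions$length) == n)
  structure(
    list(genome_id = genome$id, genome_length = n,
         gc_percent = gc_percent(genome$seq), regions = regions),
    class = "cp_structure")
}

#' @export
print.cp_structure <- function(x, ...) {
  cat(sprintf("<cp_structure> %s: %s bp, GC %.2f%%\n", x$genome_id,
              format(x$genome_length, big.mark = ","), x$gc_percent))
  print(x$regions)
  invisible(x)
}

# All maximal disjoint exact inverted-repeat pairs >= min_len on the circle.
# Seed k-mers of the sequence are joined against k-mers of its reverse
# complement; runs of consecutive seeds on one diagonal are maximal exact
# matches (every k-mer inside a maximal match is itself a matching seed).
find_inverted_repeats <- function(seq, min_len, k = NULL, max_hits_per_kmer = 16L) {
  n <- nchar(seq)
  k <- k %||% min(31L, min_len)
  D <- paste0(seq, substr(seq, 1, k - 1))          # circular k-mers
  R <- revcomp(seq)
  DR <- paste0(R, substr(R, 1, k - 1))
  sk <- substring(D, 1:n, (1:n) + k - 1L)
  rk <- substring(DR, 1:n, (1:n) + k - 1L)

  u <- unique(sk)
  si <- match(sk, u)
  ri <- match(rk, u)
  cnt_s <- tabulate(si, nbins = length(u))
  cnt_r <- tabulate(ri[!is.na(ri)], nbins = length(u))
  # 1:1 k-mers pair vectorised; repeated k-mers go through a capped join
  spos <- match(seq_along(u), si)
  rpos <- match(seq_along(u), ri)
  ok <- which(cnt_s == 1L & cnt_r == 1L)
  i <- spos[ok] - 1L
  j <- rpos[ok] - 1L
  keep <- !is.na(j)
  i <- i[keep]; j <- j[keep]
  multi <- which((cnt_s > 1L | cnt_r > 1L) & cnt_r >= 1L)
  if (length(multi)) {
    ms <- which(si %in% multi)
    mr <- which(ri %in% multi)
    slist <- split(ms - 1L, si[ms])
    rlist <- split(mr - 1L, ri[mr])
    for (key in names(slist)) {
      sp <- slist[[key]]
      rp <- rlist[[key]]
      if (is.null(rp) || length(sp) * length(rp) > max_hits_per_kmer^2) next
      i <- c(i, rep(sp, each = length(rp)))
      j <- c(j, rep(rp, length(sp)))
    }
  }
  if (length(i) == 0) return(empty_ir_table())
  diag <- (j - i) %% n
  o <- order(diag, i)
  i <- i[o]; j <- j[o]; diag <- diag[o]

  new_run <- c(TRUE, !(diff(i) == 1 & diff(diag) == 0))
  run_id <- cumsum(new_run)
  run_start <- tapply(i, run_id, min)
  run_len_seeds <- tapply(i, run_id, length)
  run_diag <- tapply(diag, run_id, `[`, 1)
  runs <- tibble(i0 = as.integer(run_start),
                 m = as.integer(run_len_seeds),
                 d = as.integer(run_diag))
  # circular merge: a run ending at i = n-1 continues at i = 0 on same diagonal
  tail_runs <- runs %>% filter(.data$i0 + .data$m == n)
  head_runs <- runs %>% filter(.data$i0 == 0)
  if (nrow(tail_runs) > 0 && nrow(head_runs) > 0) {
    for (z in seq_len(nrow(tail_runs))) {
      hit <- which(head_runs$d == tail_runs$d[z])
      if (length(hit)) {
        h <- head_runs[hit[1], ]
        runs <- runs %>%
          filter(!(.data$i0 == h$i0 & .data$d == h$d & .data$m == h$m))
        runs$m[runs$i0 == tail_runs$i0[z] & runs$d == tail_runs$d[z]] <-
          tail_runs$m[z] + h$m
      }
    }
  }
  runs <- runs %>%
    mutate(len = .data$m + k - 1L) %>%
    filter(.data$len >= min_len, .data$len < n)
  if (nrow(runs) == 0) return(empty_ir_table())
  # arm in sequence space: [i0, i0+len); mirrored arm from the revcomp match
  runs <- runs %>% mutate(
    a = .data$i0 %% n,
    j0 = (.data$i0 + .data$d) %% n,
    b = (n - .data$j0 - .data$len) %% n
  )
  # disjoint on the circle and deduplicated (each pair found from both arms)
  ok <- vapply(seq_len(nrow(runs)), function(z) {
    circ_disjoint(runs$a[z], runs$len[z], runs$b[z], runs$len[z], n)
  }, TRUE)
  runs <- runs[ok, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_ir_table())
  lo <- pmin(runs$a, runs$b); hi <- pmax(runs$a, runs$b)
  runs <- runs %>% mutate(a = lo, b = hi) %>% distinct(.data$a, .data$b, .data$len)
  runs[, c("a", "b", "len")]
}

empty_ir_table <- function() tibble(a = integer(), b = integer(), len = integer())

circ_disjoint <- function(a, la, b, lb, n) {
  # circular intervals [a, a+la), [b, b+lb) disjoint?
  da <- (b - a) %% n
  db <- (a - b) %% n
  da >= la && db >= lb
}

#' Tabulate and compare quadripartite structures across genomes
#'
#' One row per genome with total/LSC/SSC/IRa/IRb lengths and GC%, plus
#' per-column deltas relative to the first genome.
#' @param structures list of `cp_structure` objects (>= 2).
#' @return a tibble.
#' @export
compare_structures <- function(structures) {
  if (length(structures) < 2) abort("need at least two structures to compare")
  rows <- map(structures, function(s) {
    r <- s$regions
    tibble(
      genome_id = s$genome_id,
      total_bp = s$genome_length,
      lsc_bp = r$length[r$region == "lsc"],
      ssc_bp = r$length[r$region == "ssc"],
      ira_bp = r$length[r$region == "ira"],
      irb_bp = r$length[r$region == "irb"],
      gc_percent = s$gc_percent
    )
  })
  tb <- bind_rows(rows)
  ref <- tb[1, ]
  tb %>% mutate(
    d_total = .data$total_bp - ref$total_bp,
    d_lsc = .data$lsc_bp - ref$lsc_bp,
    d_ssc = .data$ssc_bp - ref$ssc_bp,
    d_ira = .data$ira_bp - ref$ira_bp,
    d_irb = .data$irb_bp - ref$irb_bp
  )
}

#' Report annotation context at the four quadripartite junctions
#'
#' For each junction (LSC-IRb, IRb-SSC, SSC-IRa, IRa-LSC) reports the
#' feature spanning it (with the fragment lengths falling on each side) and
#' the nearest features on either side. Expects the genome in the same
#' linearization the structure was computed on (canonical order
#' recommended).
#'
#' @inheritParams canonical_rotation
#' @return tibble with one row per junction/context entry.
#' @export
junction_report <- function(genome, structure) {
  n <- nchar(genome$seq)
  if (structure$genome_length != n) abort("structure/genome length mismatch")
  r <- structure$regions
  pos_of <- function(region) r$start[r$region == region]
  jx <- tibble(
    junction = c("LSC-IRb", "IRb-SSC", "SSC-IRa", "IRa-LSC"),
    position = c(pos_of("irb"), pos_of("ssc"), pos_of("ira"), pos_of("lsc"))
  )
  f <- genome$features
  if (nrow(f) == 0) {
    warn("genome carries no annotation features; junction report is empty")
    return(mutate(jx, spanning = NA_character_, frag_left = NA_integer_,
                  frag_right = NA_integer_, nearest_left = NA_character_,
                  nearest_right = NA_character_))
  }
  # reassemble origin-wrapping features into circular intervals (end > n)
  fc <- f %>%
    group_by(.data$name, .data$kind, .data$strand) %>%
    summarise(
      start = if (n() > 1 && any(.data$end == n) && any(.data$start == 0))
        .data$start[.data$end == n][1] else min(.data$start),
      span = sum(.data$end - .data$start),
      .groups = "drop") %>%
    mutate(end = .data$start + .data$span)

  out <- map(seq_len(nrow(jx)), function(z) {
    p <- jx$position[z]
    # spanning: junction strictly inside the (possibly wrapped) interval
    rel <- (p - fc$start) %% n
    spans <- rel > 0 & rel < fc$span
    sp_name <- if (any(spans)) fc$name[which(spans)[1]] else NA_character_
    frag_l <- if (any(spans)) as.integer(rel[which(spans)[1]]) else NA_integer_
    frag_r <- if (any(spans)) as.integer(fc$span[which(spans)[1]] - rel[which(spans)[1]]) else NA_integer_
    dist_l <- (p - (fc$start + fc$span)) %% n   # feature ends before junction
    dist_r <- (fc$start - p) %% n               # feature starts after junction
    tibble(
      junction = jx$junction[z], position = p,
      spanning = sp_name, frag_left = frag_l, frag_right = frag_r,
      nearest_left = fc$name[which.min(dist_l)],
      left_gap = as.integer(min(dist_l)),
      nearest_right = fc$name[which.min(dist_r)],
      right_gap = as.integer(min(dist_r))
    )
  })
  bind_rows(out)
}
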