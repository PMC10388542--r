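## Primer thermodynamics and diagnostic-marker design.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
           GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Unified nearest-neighbor thermodynamics with terminal initiation terms,
#' an entropic monovalent-salt correction of 0.368 (N-1) ln[Na+] and the
#' two-state Tm = dH / (dS + R ln(CT/4)) - 273.15.
#'
#' @param seq primer sequence (5'->3').
#' @param primer_conc total primer concentration (M); default 0.5 uM.
#' @param na_conc monovalent cation concentration (M); default 50 mM.
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(seq, primer_conc = 5e-7, na_conc = 0.05) {
  assert_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 2) abort("primer too short for nearest-neighbor Tm")
  pairs <- substring(seq, 1:(n - 1), 2:n)
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  ends <- substring(seq, c(1, n), c(1, n))
  dh <- dh + sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3))
  ds <- ds + sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1))
  ds <- ds + 0.368 * (n - 1) * log(na_conc)
  dh * 1000 / (ds + 1.987 * log(primer_conc / 4)) - 273.15
}

primer_gc <- function(seq) {
  100 * sum(seq_chars(seq) %in% c("G", "C")) / nchar(seq)
}

# number of exact occurrences on either strand
count_sites <- function(primer, seq) {
  Biostrings::countPattern(primer, seq) +
    Biostrings::countPattern(revcomp(primer), seq)
}

#' Design a diagnostic primer pair around a marker candidate
#'
#' Searches the flanking windows on each side of the CNV locus (excluding
#' the locus itself) for primer pairs with length 18-25 nt, Tm in
#' `tm_range` (nearest-neighbor model, 50 mM monovalent salt, 0.5 uM
#' primer), GC 40-60%, a single exact binding site in both genomes and a
#' product of at most `max_product` bp. The highest-scoring admissible pair
#' (score = -|Tm_fwd - Tm_rev| - |product - 250|/100) is returned together
#' with the expected amplicon size in each genome from in-silico PCR.
#' Published primers can be injected verbatim through `primers`, bypassing
#' the search (required to reproduce reported amplicon sizes exactly).
#'
#' @param candidate one row of [select_marker_candidates()].
#' @param ref,qry the two [cp_genome()] objects.
#' @param flank width of each search window (bp).
#' @param primer_len allowed primer lengths.
#' @param tm_range,gc_range admissible Tm (Celsius) and GC (%) windows.
#' @param max_product largest admissible product (bp).
#' @param primers optional `c(fwd = ..., rev = ...)` override.
#' @return one-row tibble: marker name, primers, Tm values, and
#'   `size_ref`/`size_qry` expected amplicon lengths.
#' @export
design_primers <- function(candidate, ref, qry, flank = 200,
                           primer_len = 18:25, tm_range = c(55, 62),
                           gc_range = c(40, 60), max_product = 400,
                           primers = NULL) {
  locus_s <- candidate$locus_start[1]
  locus_e <- candidate$locus_end[1]
  if (!is.null(primers)) {
    fwd <- unname(primers[["fwd"]]); rev <- unname(primers[["rev"]])
    return(marker_row(candidate$name[1], fwd, rev, ref, qry, max_product = Inf))
  }
  rs <- ref$seq
  fwd_win <- substr(rs, max(1, locus_s - flank + 1), locus_s)
  rev_win <- substr(rs, locus_e + 1, min(nchar(rs), locus_e + flank))
  if (nchar(fwd_win) < min(primer_len) || nchar(rev_win) < min(primer_len)) {
    abort("no primer found: flanking windows shorter than the primer length",
          class = "chlorotype_no_primer")
  }
  fwd_cand <- window_primer_candidates(fwd_win, primer_len, tm_range, gc_range)
  rev_cand <- window_primer_candidates(rev_win, primer_len, tm_range, gc_range)
  rev_cand$seq <- vapply(rev_cand$seq, revcomp, "")   # reverse primer anneals bottom strand
  diag_msg <- sprintf("fwd window: %d candidates in Tm/GC range; rev window: %d",
                      nrow(fwd_cand), nrow(rev_cand))
  if (nrow(fwd_cand) == 0 || nrow(rev_cand) == 0) {
    abort(paste0("no primer found: ", diag_msg), class = "chlorotype_no_primer")
  }
  fwd_cand <- keep_unique_sites(fwd_cand, ref, qry)
  rev_cand <- keep_unique_sites(rev_cand, ref, qry)
  if (nrow(fwd_cand) == 0 || nrow(rev_cand) == 0) {
    abort(paste0("no primer found (no single-site candidate): ", diag_msg),
          class = "chlorotype_no_primer")
  }
  # keep the best-tempered candidates on each side before pairing
  fwd_cand <- head(arrange(fwd_cand, abs(.data$tm - mean(tm_range))), 40)
  rev_cand <- head(arrange(rev_cand, abs(.data$tm - mean(tm_range))), 40)
  grid <- tidyr::expand_grid(f = seq_len(nrow(fwd_cand)), r = seq_len(nrow(rev_cand)))
  best <- NULL
  for (z in seq_len(nrow(grid))) {
    fc <- fwd_cand[grid$f[z], ]; rc <- rev_cand[grid$r[z], ]
    amp_r <- insilico_pcr(ref, fc$seq, rc$seq, max_product = max_product)
    amp_q <- insilico_pcr(qry, fc$seq, rc$seq, max_product = max_product)
    if (nrow(amp_r) != 1 || nrow(amp_q) != 1) next
    score <- -abs(fc$tm - rc$tm) - abs(amp_r$length - 250) / 100
    if (is.null(best) || score > best$score) {
      best <- list(fwd = fc$seq, rev = rc$seq, score = score)
    }
  }
  if (is.null(best)) {
    abort(paste0("no primer found (no admissible pair amplifies uniquely): ",
                 diag_msg), class = "chlorotype_no_primer")
  }
  marker_row(candidate$name[1], best$fwd, best$rev, ref, qry, max_product)
}

window_primer_candidates <- function(win, primer_len, tm_range, gc_range) {
  n <- nchar(win)
  out <- list()
  for (L in primer_len) {
    if (L > n) next
    starts <- 1:(n - L + 1)
    seqs <- substring(win, starts, starts + L - 1)
    seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
    if (!length(seqs)) next
    gc <- vapply(seqs, primer_gc, 0)
    keep <- gc >= gc_range[1] & gc <= gc_range[2]
    seqs <- seqs[keep]
    if (!length(seqs)) next
    tm <- unname(vapply(seqs, primer_tm, 0))
    keep <- tm >= tm_range[1] & tm <= tm_range[2]
    if (any(keep)) out[[length(out) + 1]] <- tibble(seq = unname(seqs[keep]),
                                                    tm = tm[keep])
  }
  if (length(out)) distinct(bind_rows(out), .data$seq, .keep_all = TRUE)
  else tibble(seq = character(), tm = numeric())
}

keep_unique_sites <- function(cand, ref, qry) {
  if (nrow(cand) == 0) return(cand)
  ok <- vapply(cand$seq, function(p) {
    count_sites(p, ref$seq) == 1 && count_sites(p, qry$seq) == 1
  }, TRUE)
  cand[ok, , drop = FALSE]
}

marker_row <- function(name, fwd, rev, ref, qry, max_product = 2000) {
  fwd <- unname(fwd); rev <- unname(rev)
  if (is.infinite(max_product)) max_product <- 2000
  amp_r <- insilico_pcr(ref, fwd, rev, max_product = max_product)
  amp_q <- insilico_pcr(qry, fwd, rev, max_product = max_product)
  tibble(
    name = name, fwd = fwd, rev = rev,
    tm_fwd = primer_tm(fwd), tm_rev = primer_tm(rev),
    size_ref = if (nrow(amp_r)) amp_r$length[1] else NA_integer_,
    size_qry = if (nrow(amp_q)) amp_q$length[1] else NA_integer_
  )
}

#' Marker definitions: build, read and write
#'
#' A marker definition is the portable unit used for genotyping: primer
#' pair, expected amplicon size per cytotype and a sizing tolerance.
#' `marker_set()` builds the tibble; `write_markers()`/`read_markers()`
#' round-trip it through YAML.
#'
#' @param name,fwd,rev,expected_S,expected_N,tolerance_bp vectors of equal
#'   length (tolerance defaults to 2 bp, mimicking capillary sizing error).
#' @return a tibble of marker definitions.
#' @export
marker_set <- function(name, fwd, rev, expected_S, expected_N,
                       tolerance_bp = 2L) {
  tibble(name = name, fwd = toupper(fwd), rev = toupper(rev),
         expected_S = as.integer(expected_S),
         expected_N = as.integer(expected_N),
         tolerance_bp = as.integer(tolerance_bp))
}

#' @rdname marker_set
#' @param markers marker tibble.
#' @param path YAML file path.
#' @export
write_markers <- function(markers, path) {
  lst <- purrr::transpose(as.list(markers))
  lst <- map(lst, function(m) {
    list(name = m$name, fwd = m$fwd, rev = m$rev,
         expected = list(S = m$expected_S, N = m$expected_N),
         tolerance_bp = m$tolerance_bp)
  })
  yaml::write_yaml(list(markers = lst), path)
  invisible(path)
}

#' @rdname marker_set
#' @export
read_markers <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- map(y$markers, function(m) {
    marker_set(m$name, m$fwd, m$rev, m$expected$S, m$expected$N,
               m$tolerance_bp %||% 2L)
  })
  bind_rows(rows)
}
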