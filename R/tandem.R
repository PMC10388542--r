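#' Explain an InDel as a tandem-repeat copy-number variant
#'
#' Finds the smallest primitive unit `u` (1..`max_unit` bp) such that the
#' inserted/deleted sequence is an integer number of exact copies of `u`
#' and `u` occurs tandemly at least once more in the flanking reference
#' context. Copy numbers are the maximal exact tandem runs at the locus in
#' each genome; the copy-number difference times the unit length equals the
#' InDel length by construction.
#'
#' @param variant one row of a [call_variants()] tibble (an InDel).
#' @param ref,qry the aligned [cp_genome()] objects the call came from.
#' @param max_unit largest unit length considered (bp).
#' @return a one-row tibble (`unit`, `unit_len`, `copies_ref`, `copies_qry`,
#'   `locus_start`, `locus_end` in 0-based reference coordinates of the
#'   tandem run) or `NULL` when the InDel has no tandem explanation.
#' @export
detect_tandem_unit <- function(variant, ref, qry, max_unit = 100) {
  if (!variant$type[1] %in% c("insertion", "deletion")) {
    abort("detect_tandem_unit expects an insertion or deletion variant")
  }
  rs <- ref$seq; qs <- qry$seq
  L <- variant$length[1]
  is_ins <- variant$type[1] == "insertion"
  # recover the event sequence and its left-normalized 0-based start
  if (is_ins) {
    s <- substr(variant$alt[1], 2, L + 1)
    p_ref <- variant$ref_pos[1]          # insertion point, 0-based (anchor is at p-1)
    p_qry <- variant$qry_pos[1]          # inserted copies start here in qry (0-based)
    if (variant$ev_start[1] == 0L) { s <- substr(variant$alt[1], 1, L); p_ref <- 0L; p_qry <- 0L }
  } else {
    s <- substr(variant$ref[1], 2, L + 1)
    p_ref <- variant$ref_pos[1]
    p_qry <- variant$qry_pos[1]
    if (variant$ev_start[1] == 0L) { s <- substr(variant$ref[1], 1, L); p_ref <- 0L; p_qry <- 0L }
  }
  if (L < 1 || nchar(s) != L) return(NULL)   # malformed/anchorless event
  units <- divisors(L)
  units <- units[units <= max_unit]
  for (u in units) {
    unit <- substr(s, 1, u)
    if (!is_repetition(s, unit)) next
    if (!is_primitive(unit)) next
    # count maximal exact tandem runs starting at the event position
    c_ref <- count_tandem(rs, p_ref, unit)
    c_qry <- count_tandem(qs, p_qry, unit)
    extra <- if (is_ins) c_ref else c_ref - L / u
    if (extra < 1) next                 # needs >= 1 copy in the flanking context
    if (abs(c_ref - c_qry) * u != L) next
    return(tibble(
      unit = unit, unit_len = as.integer(u),
      copies_ref = as.integer(c_ref), copies_qry = as.integer(c_qry),
      locus_start = as.integer(p_ref),
      locus_end = as.integer(p_ref + c_ref * u)))
  }
  NULL
}

divisors <- function(L) (1:L)[L %% (1:L) == 0]

is_repetition <- function(s, unit) {
  strrep(unit, nchar(s) / nchar(unit)) == s
}

is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1) return(TRUE)
  dv <- divisors(u)
  dv <- dv[dv < u]
  !any(vapply(dv, function(d) is_repetition(unit, substr(unit, 1, d)), TRUE))
}

# maximal number of exact copies of unit starting at 0-based position p
count_tandem <- function(seq, p, unit) {
  u <- nchar(unit)
  n <- nchar(seq)
  c <- 0L
  while (p + (c + 1L) * u <= n &&
         substr(seq, p + c * u + 1, p + (c + 1L) * u) == unit) {
    c <- c + 1L
  }
  c
}

#' Select large InDels as diagnostic marker candidates
#'
#' Keeps InDels strictly longer than `min_len` (the field's ">20 bp" rule),
#' restricted to intergenic context when `require_intergenic` is set, each
#' annotated with its tandem-repeat CNV explanation when one exists;
#' ordered by length descending and named `cp_01`, `cp_02`, ...
#'
#' @param variants tibble from [call_variants()] (with context assigned).
#' @param ref,qry the aligned [cp_genome()] objects.
#' @param min_len keep InDels with `length > min_len` (strict).
#' @param require_intergenic drop genic InDels.
#' @param max_unit passed to [detect_tandem_unit()].
#' @return tibble of candidates with CNV columns (`unit` is `NA` when the
#'   InDel is not a tandem-repeat CNV).
#' @export
select_marker_candidates <- function(variants, ref, qry, min_len = 20,
                                     require_intergenic = TRUE,
                                     max_unit = 100) {
  cand <- variants %>%
    filter(.data$type %in% c("insertion", "deletion"), .data$length > min_len)
  if (require_intergenic) {
    cand <- filter(cand, is.na(.data$context) | .data$context == "intergenic")
  }
  cand <- arrange(cand, desc(.data$length), .data$ref_pos)
  if (nrow(cand) == 0) {
    return(mutate(cand, name = character(0), unit = character(0),
                  unit_len = integer(0), copies_ref = integer(0),
                  copies_qry = integer(0), locus_start = integer(0),
                  locus_end = integer(0)))
  }
  cnv <- map(seq_len(nrow(cand)), function(z) {
    detect_tandem_unit(cand[z, ], ref, qry, max_unit = max_unit) %||%
      tibble(unit = NA_character_, unit_len = NA_integer_,
             copies_ref = NA_integer_, copies_qry = NA_integer_,
             locus_start = cand$ev_start[z],
             locus_end = pmax(cand$ev_end[z], cand$ev_start[z] + 1L))
  })
  bind_cols(
    tibble(name = sprintf("cp_%02d", seq_len(nrow(cand)))),
    cand, bind_rows(cnv))
}
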