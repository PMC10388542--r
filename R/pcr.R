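#' In-silico PCR against a (circular) genome
#'
#' Locates every forward/reverse primer site pair on either strand with at
#' most `max_mismatch` mismatches per primer (the three 3'-terminal bases
#' must always match exactly, modelling primer extension chemistry) and a
#' product of at most `max_product` bp, scanning across the circular
#' origin. Product length is inclusive of both primer footprints.
#'
#' @param genome a [cp_genome()].
#' @param fwd,rev primer sequences (5'->3', each on its own strand).
#' @param max_mismatch allowed mismatches per primer site.
#' @param max_product largest reported product (bp).
#' @return tibble of amplicons (`start` 0-based on the genome, `end` =
#'   start + length and may exceed the genome length for origin-spanning
#'   products, `length`, `strand`), sorted by length.
#' @export
insilico_pcr <- function(genome, fwd, rev, max_mismatch = 0,
                         max_product = 2000) {
  stopifnot(inherits(genome, "cp_genome"))
  assert_dna(fwd, "fwd primer"); assert_dna(rev, "rev primer")
  s <- genome$seq
  n <- nchar(s)
  tmpl <- if (genome$circular) paste0(s, substr(s, 1, min(max_product, n))) else s
  a <- pcr_one_orientation(tmpl, n, fwd, rev, max_mismatch, max_product, "+",
                           circular = genome$circular)
  b <- pcr_one_orientation(tmpl, n, rev, fwd, max_mismatch, max_product, "-",
                           circular = genome$circular)
  amps <- bind_rows(a, b)
  # a product cannot run past a full circle
  if (nrow(amps) > 0) amps <- filter(amps, .data$length <= n)
  if (nrow(amps) == 0) {
    return(tibble(genome_id = character(), start = integer(), end = integer(),
                  length = integer(), strand = character()))
  }
  amps %>%
    mutate(genome_id = genome$id, .before = 1) %>%
    distinct(.data$start, .data$length, .data$strand, .keep_all = TRUE) %>%
    arrange(.data$length, .data$start)
}

# left primer extends rightward on the top strand; the right primer's
# reverse complement sits downstream on the top strand
pcr_one_orientation <- function(tmpl, n, left, right, mm, max_product, strand,
                                circular) {
  lf <- nchar(left); lr <- nchar(right)
  f_sites <- primer_sites(left, tmpl, mm, three_prime = "end")
  if (!length(f_sites)) return(NULL)
  r_sites <- primer_sites(revcomp(right), tmpl, mm, three_prime = "start")
  if (!length(r_sites)) return(NULL)
  f_sites <- f_sites[f_sites <= n]                  # starts live on the genome
  out <- list()
  for (f in f_sites) {
    ends <- r_sites[r_sites >= f + lf] + lr - 1L    # 0-based: site start + lr
    len <- ends - f + 1L
    keep <- len <= max_product
    if (any(keep)) {
      out[[length(out) + 1]] <- tibble(
        start = f - 1L, end = f - 1L + len[keep], length = len[keep],
        strand = strand)
    }
  }
  if (!length(out)) return(NULL)
  res <- bind_rows(out)
  if (circular) res <- distinct(mutate(res, start = .data$start %% n,
                                       end = .data$start + .data$length),
                                .data$start, .data$length, .keep_all = TRUE)
  res
}

# 1-based starts of primer matches; the 3' terminal 3 bases must be exact
primer_sites <- function(pattern, tmpl, mm, three_prime = c("end", "start")) {
  three_prime <- match.arg(three_prime)
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(tmpl),
                                   max.mismatch = mm, with.indels = FALSE)
  starts <- Biostrings::start(hits)
  if (mm > 0 && length(starts)) {
    L <- nchar(pattern)
    anchor <- if (three_prime == "end") substr(pattern, L - 2, L) else substr(pattern, 1, 3)
    at <- if (three_prime == "end") starts + L - 3L else starts
    ok <- substring(tmpl, at, at + 2L) == anchor
    starts <- starts[ok]
  }
  starts
}

#' Classify the cytotype of one genome with a set of InDel markers
#'
#' Runs in-silico PCR for every marker and compares the product sizes to
#' the expected S and N sizes within each marker's tolerance. The sample is
#' called S only if every amplifying marker matches its S expectation
#' (likewise N); mixed or unmatched amplifying markers give `ambiguous`,
#' and no product from any marker gives `no_amplification`.
#'
#' @param genome a [cp_genome()].
#' @param markers tibble from [marker_set()] / [read_markers()].
#' @param tolerance_bp overrides the per-marker tolerance when not `NULL`.
#' @param max_mismatch,max_product passed to [insilico_pcr()].
#' @return one-row tibble: `sample`, `call`, and one `len_<marker>` column
#'   per marker (NA when the marker did not amplify).
#' @export
classify_cytotype <- function(genome, markers, tolerance_bp = NULL,
                              max_mismatch = 0, max_product = 2000) {
  if (nrow(markers) == 0) abort("need at least one marker definition")
  per <- map(seq_len(nrow(markers)), function(z) {
    m <- markers[z, ]
    tol <- tolerance_bp %||% m$tolerance_bp
    amps <- insilico_pcr(genome, m$fwd, m$rev, max_mismatch, max_product)
    if (nrow(amps) == 0) {
      return(tibble(marker = m$name, len = NA_integer_, verdict = "no_amp"))
    }
    hit_s <- abs(amps$length - m$expected_S) <= tol
    hit_n <- abs(amps$length - m$expected_N) <= tol
    verdict <- if (any(hit_s) && any(hit_n)) "ambiguous"
      else if (any(hit_s)) "S"
      else if (any(hit_n)) "N"
      else "ambiguous"
    # report the product nearest an expected size
    nearest <- which.min(pmin(abs(amps$length - m$expected_S),
                              abs(amps$length - m$expected_N)))
    tibble(marker = m$name, len = amps$length[nearest], verdict = verdict)
  })
  per <- bind_rows(per)
  amplifying <- per$verdict[per$verdict != "no_amp"]
  call <- if (length(amplifying) == 0) "no_amplification"
    else if (all(amplifying == "S")) "S"
    else if (all(amplifying == "N")) "N"
    else "ambiguous"
  wide <- per %>%
    select("marker", "len") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "len",
                       names_prefix = "len_")
  bind_cols(tibble(sample = genome$id, call = call), wide)
}

#' Classify every genome of a cohort
#'
#' @param genomes list of [cp_genome()] objects (or paths readable by
#'   [read_genome()]).
#' @inheritParams classify_cytotype
#' @return tibble with one [classify_cytotype()] row per genome.
#' @export
classify_cohort <- function(genomes, markers, tolerance_bp = NULL,
                            max_mismatch = 0, max_product = 2000) {
  rows <- map(genomes, function(g) {
    if (is.character(g)) g <- read_genome(g)
    classify_cytotype(g, markers, tolerance_bp, max_mismatch, max_product)
  })
  bind_rows(rows)
}

#' Tally cytotype calls per cultivar
#'
#' @param calls tibble from [classify_cohort()].
#' @param manifest tibble mapping `sample` to `cultivar`.
#' @return per-cultivar tallies (`n_total`, `n_S`, `n_N`, `n_other`) plus a
#'   `Total` row.
#' @export
summarize_cohort <- function(calls, manifest) {
  if (nrow(calls) == 0) {
    return(tibble(cultivar = "Total", n_total = 0L, n_S = 0L, n_N = 0L,
                  n_other = 0L))
  }
  unmapped <- setdiff(calls$sample, manifest$sample)
  if (length(unmapped)) {
    abort(paste0("sample(s) missing from manifest: ",
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  joined <- left_join(calls, manifest[, c("sample", "cultivar")], by = "sample")
  per <- joined %>%
    group_by(.data$cultivar) %>%
    summarise(
      n_total = n(),
      n_S = sum(.data$call == "S"),
      n_N = sum(.data$call == "N"),
      n_other = sum(!.data$call %in% c("S", "N")),
      .groups = "drop")
  total <- per %>%
    summarise(cultivar = "Total", n_total = sum(.data$n_total),
              n_S = sum(.data$n_S), n_N = sum(.data$n_N),
              n_other = sum(.data$n_other))
  bind_rows(per, total)
}
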