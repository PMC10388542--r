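#' Circular genome container
#'
#' A light S3 container for a (usually circular) organelle genome: an
#' uppercase DNA sequence over {A,C,G,T,N}, an identifier, and an optional
#' annotation table. Internal coordinates are 0-based half-open throughout
#' the package; file output (GFF3, VCF) is 1-based per those formats.
#'
#' @param id genome identifier.
#' @param seq DNA sequence (uppercased; U is mapped to T).
#' @param circular logical; index arithmetic is modulo length when `TRUE`.
#' @param features annotation tibble with columns `name`, `kind`
#'   (gene/tRNA/rRNA/other), `start`, `end` (0-based half-open), `strand`
#'   (+/-) and `part` (sub-interval index for features wrapping the origin).
#' @param source provenance string (file path or accession).
#' @return object of class `cp_genome`.
#' @export
cp_genome <- function(id, seq, circular = TRUE, features = empty_features(),
                      source = NA_character_) {
  seq <- toupper(chartr("u", "t", seq))
  seq <- chartr("U", "T", seq)
  assert_dna(seq, paste0("genome '", id, "' sequence"))
  features <- validate_features(features, nchar(seq))
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular),
         features = features, source = source),
    class = "cp_genome"
  )
}

#' @export
print.cp_genome <- function(x, ...) {
  cat(sprintf("<cp_genome> %s: %s bp, %s, %d features\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' @export
length.cp_genome <- function(x) nchar(x$seq)

#' @rdname cp_genome
#' @export
empty_features <- function() {
  tibble(name = character(), kind = character(), start = integer(),
         end = integer(), strand = character(), part = integer())
}

validate_features <- function(features, genome_len) {
  features <- as_tibble(features)
  if (nrow(features) == 0) return(empty_features())
  if (!"part" %in% names(features)) features$part <- 1L
  if (!"strand" %in% names(features)) features$strand <- "+"
  if (!"kind" %in% names(features)) features$kind <- "gene"
  features <- features[, c("name", "kind", "start", "end", "strand", "part")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start < 0 | features$end > genome_len |
    features$start >= features$end
  if (any(bad)) {
    abort(paste0("invalid feature interval(s): ",
                 paste(features$name[bad], collapse = ", ")))
  }
  features
}

#' Read a genome from FASTA or GenBank flat file
#'
#' FASTA input is assumed circular unless `circular = FALSE`; GenBank input
#' carries gene/tRNA/rRNA features into the annotation table.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`; guessed from the extension when
#'   omitted.
#' @param circular assume circular topology (FASTA only; GenBank records
#'   declare it).
#' @return a [cp_genome()].
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank", "gbff")) "genbank" else "fasta"
  }
  if (format == "fasta") read_genome_fasta(path, circular) else read_genome_genbank(path)
}

read_genome_fasta <- function(path, circular = TRUE) {
  # BStringSet, not DNAStringSet: keep lowercase/U so cp_genome() can map
  # them instead of Biostrings silently dropping invalid letters
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("cannot parse FASTA '", path, "': ",
                                                   conditionMessage(e))))
  if (length(set) == 0) abort(paste0("no sequence records in ", path))
  if (length(set) > 1) warn(paste0(path, " has multiple records; using the first"))
  id <- sub("\\s.*$", "", names(set)[1])
  seq <- as.character(set[[1]])
  if (nchar(seq) == 0) abort(paste0("empty sequence in ", path))
  cp_genome(id, seq, circular = circular, source = path)
}

#' Write a genome to FASTA
#' @param genome a [cp_genome()].
#' @param path output path.
#' @param width line width.
#' @export
write_genome <- function(genome, path, width = 70) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

## ---- GenBank flat file (minimal subset: LOCUS/DEFINITION/FEATURES/ORIGIN) ----

read_genome_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) abort(paste0("not a GenBank flat file (no LOCUS line): ", path))
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0) abort(paste0("GenBank record without ORIGIN block: ", path))
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1):(end_i - 1)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0) abort(paste0("empty sequence in GenBank record: ", path))

  feats <- parse_genbank_features(lines, origin_i[1], path)
  g <- cp_genome(id, seq, circular = circular, features = feats, source = path)
  stated <- suppressWarnings(as.integer(locus[3]))
  if (!is.na(stated) && stated != nchar(g$seq)) {
    abort(sprintf("GenBank record %s: LOCUS length %d != sequence length %d",
                  id, stated, nchar(g$seq)))
  }
  g
}

parse_genbank_features <- function(lines, origin_i, path) {
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i) == 0) return(empty_features())
  block <- lines[(feat_i[1] + 1):(origin_i - 1)]
  # feature headers start at column 6; qualifiers at column 22
  hdr <- grepl("^\\s{4,6}\\S", block)
  idx <- which(hdr)
  out <- list()
  for (j in seq_along(idx)) {
    ln <- block[idx[j]]
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- parts[1]
    if (!key %in% c("gene", "tRNA", "rRNA", "CDS", "misc_feature")) next
    loc <- paste(parts[-1], collapse = "")
    # continuation lines of the location (no "/" qualifier prefix)
    k <- idx[j] + 1L
    while (k <= length(block) && !hdr[k] && !grepl("^\\s+/", block[k])) {
      loc <- paste0(loc, trimws(block[k])); k <- k + 1L
    }
    quals <- character()
    while (k <= length(block) && !hdr[k]) {
      quals <- c(quals, trimws(block[k])); k <- k + 1L
    }
    gm <- regmatches(quals, regexec('^/(?:gene|label|product)="?([^"]+)"?', quals))
    nm <- unlist(lapply(gm, function(m) if (length(m) == 2) m[2] else NULL))
    nm <- if (length(nm)) nm[1] else paste0(tolower(key), "_", j)
    ints <- parse_genbank_location(loc, path)
    kind <- switch(key, gene = "gene", CDS = "gene", tRNA = "tRNA",
                   rRNA = "rRNA", "other")
    for (p in seq_len(nrow(ints))) {
      out[[length(out) + 1]] <- tibble(
        name = nm, kind = kind,
        start = ints$start[p], end = ints$end[p],
        strand = ints$strand[p], part = p)
    }
  }
  if (length(out) == 0) empty_features() else bind_rows(out)
}

parse_genbank_location <- function(loc, path) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(spans, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", spans))
  if (any(vapply(m, length, 1L) != 3)) {
    abort(paste0("unparseable GenBank location '", loc, "' in ", path))
  }
  tibble(
    start = vapply(m, function(x) as.integer(x[2]), 1L) - 1L,  # to 0-based
    end = vapply(m, function(x) as.integer(x[3]), 1L),
    strand = strand
  )
}

#' Write a genome as a minimal GenBank flat file
#'
#' Emits LOCUS, FEATURES (gene/tRNA/rRNA with 1-based locations,
#' complement() for minus strand, join() for origin-wrapping features) and
#' ORIGIN blocks; enough for lossless round-trips through [read_genome()].
#' @inheritParams write_genome
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     genome$id, n,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- genome$features
  if (nrow(f) > 0) {
    for (nm in unique(f$name)) {
      ff <- f[f$name == nm, , drop = FALSE]
      ff <- ff[order(ff$part), , drop = FALSE]
      spans <- sprintf("%d..%d", ff$start + 1L, ff$end)
      loc <- if (length(spans) > 1) paste0("join(", paste(spans, collapse = ","), ")") else spans
      if (ff$strand[1] == "-") loc <- paste0("complement(", loc, ")")
      key <- switch(ff$kind[1], gene = "gene", tRNA = "tRNA", rRNA = "rRNA", "misc_feature")
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', nm), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1, n, by = 60)
  for (s in starts) {
    chunk <- substr(genome$seq, s, min(s + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- GFF3 ----

#' Read/write annotation features as GFF3
#'
#' @param path GFF3 file path.
#' @return `read_features()` returns a feature tibble (0-based half-open
#'   internally, converted from GFF3's 1-based closed intervals).
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_features())
  m <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(m, length, 1L) != 9)) {
    abort(paste0("malformed GFF3 (expected 9 columns): ", path))
  }
  attr_name <- function(a) {
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    kv <- kv[vapply(kv, length, 1L) == 2]
    vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    vals[["Name"]] %||% vals[["gene"]] %||% vals[["ID"]] %||% NA_character_
  }
  tb <- tibble(
    name = vapply(m, function(x) attr_name(x[9]), ""),
    kind = vapply(m, function(x) switch(x[3], gene = "gene", tRNA = "tRNA",
                                        rRNA = "rRNA", "other"), ""),
    start = vapply(m, function(x) as.integer(x[4]), 1L) - 1L,
    end = vapply(m, function(x) as.integer(x[5]), 1L),
    strand = vapply(m, function(x) if (x[7] %in% c("+", "-")) x[7] else "+", "")
  )
  tb %>%
    group_by(.data$name) %>%
    mutate(part = row_number()) %>%
    ungroup()
}

#' @rdname read_features
#' @param features feature tibble (or a [cp_genome()], whose features are used).
#' @param seqid sequence name for column 1.
#' @export
write_features <- function(features, path, seqid = "genome") {
  if (inherits(features, "cp_genome")) {
    seqid <- features$id
    features <- features$features
  }
  lines <- c("##gff-version 3")
  if (nrow(features) > 0) {
    type <- ifelse(features$kind %in% c("gene", "tRNA", "rRNA"), features$kind, "region")
    lines <- c(lines, sprintf(
      "%s\tchlorotype\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%d;Name=%s",
      seqid, type, features$start + 1L, features$end, features$strand,
      features$name, features$part, features$name))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- canonical rotation ----

#' Rotate (and orient) a genome into canonical quadripartite order
#'
#' Produces the linearization LSC, IRb, SSC, IRa with position 0 at the
#' first LSC base. Both strands yield a valid canonical order (the IR arm
#' following LSC is IRb by definition); the strand whose canonical sequence
#' is lexicographically smaller is chosen, which makes the result invariant
#' to rotation and to reverse-complementation of the input. Features are
#' remapped; features crossing the new origin are split into two parts.
#'
#' @param genome a [cp_genome()].
#' @param structure a [detect_structure()] result computed on this genome.
#' @return the canonical [cp_genome()]; idempotent.
#' @export
canonical_rotation <- function(genome, structure) {
  n <- nchar(genome$seq)
  if (structure$genome_length != n) {
    abort("structure/genome length mismatch: structure was not computed on this genome")
  }
  fwd <- rotate_genome(genome, structure$regions$start[structure$regions$region == "lsc"])
  rc <- revcomp_genome(genome)
  st_rc <- mirror_structure(structure, n)
  rev <- rotate_genome(rc, st_rc$regions$start[st_rc$regions$region == "lsc"])
  if (fwd$seq <= rev$seq) fwd else rev
}

rotate_genome <- function(genome, offset) {
  n <- nchar(genome$seq)
  offset <- offset %% n
  if (offset == 0) return(genome)
  seq <- paste0(substr(genome$seq, offset + 1, n), substr(genome$seq, 1, offset))
  f <- genome$features
  if (nrow(f) > 0) {
    ns <- (f$start - offset) %% n
    ne <- ns + (f$end - f$start)
    rows <- list()
    for (i in seq_len(nrow(f))) {
      if (ne[i] <= n) {
        rows[[length(rows) + 1]] <- mutate(f[i, ], start = ns[i], end = ne[i])
      } else {  # wraps the new origin: split
        rows[[length(rows) + 1]] <- mutate(f[i, ], start = ns[i], end = n, part = 1L)
        rows[[length(rows) + 1]] <- mutate(f[i, ], start = 0L, end = ne[i] - n, part = 2L)
      }
    }
    f <- bind_rows(rows) %>% mutate(start = as.integer(.data$start), end = as.integer(.data$end))
    f <- rejoin_split_features(f, n)
  }
  cp_genome(genome$id, seq, genome$circular, f, genome$source)
}

# merge feature parts that became contiguous after rotation
rejoin_split_features <- function(f, n) {
  if (nrow(f) < 2) return(f)
  f <- arrange(f, .data$name, .data$start)
  out <- list()
  i <- 1
  while (i <= nrow(f)) {
    if (i < nrow(f) && f$name[i] == f$name[i + 1] && f$end[i] == f$start[i + 1] &&
        f$strand[i] == f$strand[i + 1]) {
      out[[length(out) + 1]] <- mutate(f[i, ], end = f$end[i + 1], part = 1L)
      i <- i + 2
    } else {
      out[[length(out) + 1]] <- mutate(f[i, ], part = 1L)
      i <- i + 1
    }
  }
  bind_rows(out) %>%
    group_by(.data$name) %>%
    mutate(part = row_number()) %>%
    ungroup()
}

revcomp_genome <- function(genome) {
  n <- nchar(genome$seq)
  f <- genome$features
  if (nrow(f) > 0) {
    f <- f %>% mutate(
      start2 = n - .data$end, end2 = n - .data$start,
      strand = ifelse(.data$strand == "+", "-", "+")
    ) %>%
      mutate(start = as.integer(.data$start2), end = as.integer(.data$end2)) %>%
      select(-"start2", -"end2")
  }
  cp_genome(genome$id, revcomp(genome$seq), genome$circular, f, genome$source)
}

# structure intervals under reverse complementation: position p -> n - p
mirror_structure <- function(structure, n) {
  r <- structure$regions
  # region [s, s+len) maps to [(n - s - len) mod n, ...); lsc stays lsc etc.
  # but the arm ordering flips: old irb becomes the arm *preceding* LSC, i.e. ira.
  new <- r %>% mutate(
    start = as.integer((n - .data$start - .data$length) %% n),
    region = dplyr::recode(.data$region, irb = "ira", ira = "irb")
  )
  structure$regions <- new[match(c("lsc", "irb", "ssc", "ira"), new$region), ]
  structure
}
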