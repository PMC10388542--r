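#' Call SNPs, MNPs and InDels from a global pairwise alignment
#'
#' Adjacent gap columns are merged into single InDel events and every InDel
#' is left-normalized against the reference (shifted to the lowest position
#' that preserves the haplotype, VCF style, with an anchor base). Runs of
#' two or more adjacent mismatch columns form an MNP by default; with
#' `mnp = FALSE` they are decomposed into individual SNPs. Genic/intergenic
#' context is assigned from the annotation; intergenic events are labelled
#' with the flanking gene pair.
#'
#' @param aln a `cp_alignment` from [align_genomes()].
#' @param features annotation tibble in reference coordinates (defaults to
#'   none: all events get `context = NA`).
#' @param mnp merge adjacent mismatches into MNPs (`TRUE`, default) or
#'   report them as individual SNPs.
#' @return tibble with one row per variant: `ref_pos` (1-based VCF-style
#'   anchor), `qry_pos`, `type` (SNP/MNP/insertion/deletion), `ref`, `alt`,
#'   `length` (absolute InDel length, 0 for substitutions), `context`,
#'   `flank_genes`, `gene`, and `origin_spanning` (event touches the
#'   linearization ends of the circular molecule).
#' @export
call_variants <- function(aln, features = NULL, mnp = TRUE) {
  stopifnot(inherits(aln, "cp_alignment"))
  rs <- aln$ref_seq; qs <- aln$qry_seq
  nr <- nchar(rs)
  ncol_total <- sum(aln$ops$len)
  ops <- aln$ops
  out <- list()
  col_at <- cumsum(c(0, ops$len))[seq_len(nrow(ops))]
  for (z in seq_len(nrow(ops))) {
    op <- ops$op[z]; len <- ops$len[z]
    rp <- ops$ref_pos[z]; qp <- ops$qry_pos[z]
    at_edge <- col_at[z] == 0 || col_at[z] + len == ncol_total
    if (op == "M") next
    if (op == "X") {
      if (mnp && len >= 2) {
        out[[length(out) + 1]] <- tibble(
          ref_pos = rp + 1L, qry_pos = qp + 1L, type = "MNP",
          ref = substr(rs, rp + 1, rp + len), alt = substr(qs, qp + 1, qp + len),
          length = 0L, ev_start = rp, ev_end = rp + len, origin_spanning = FALSE)
      } else {
        out[[length(out) + 1]] <- tibble(
          ref_pos = rp + seq_len(len), qry_pos = qp + seq_len(len), type = "SNP",
          ref = substring(rs, rp + seq_len(len), rp + seq_len(len)),
          alt = substring(qs, qp + seq_len(len), qp + seq_len(len)),
          length = 0L, ev_start = rp + seq_len(len) - 1L,
          ev_end = rp + seq_len(len), origin_spanning = FALSE)
      }
    } else if (op == "I") {
      ins <- substr(qs, qp + 1, qp + len)
      norm <- normalize_insertion(rs, rp, ins)
      shift <- rp - norm$p
      out[[length(out) + 1]] <- vcf_style_insertion(rs, norm$p, norm$seq,
                                                    qp - shift, at_edge)
    } else if (op == "D") {
      norm <- normalize_deletion(rs, rp, len)
      shift <- rp - norm$p
      out[[length(out) + 1]] <- vcf_style_deletion(rs, norm$p, len,
                                                   qp - shift, at_edge)
    }
  }
  v <- if (length(out)) bind_rows(out) else empty_variants()
  v <- arrange(v, .data$ref_pos, .data$type)
  v <- assign_context(v, features, nr)
  attr(v, "ref_id") <- aln$ref_id
  attr(v, "qry_id") <- aln$qry_id
  v
}

empty_variants <- function() {
  tibble(ref_pos = integer(), qry_pos = integer(), type = character(),
         ref = character(), alt = character(), length = integer(),
         ev_start = integer(), ev_end = integer(), origin_spanning = logical())
}

# shift a deletion of ref[p, p+L) to its lowest equivalent position
normalize_deletion <- function(rs, p, L) {
  while (p > 0 && substr(rs, p, p) == substr(rs, p + L, p + L)) p <- p - 1L
  list(p = p)
}

# shift an insertion (before ref position p, 0-based) to its lowest position
normalize_insertion <- function(rs, p, s) {
  L <- nchar(s)
  while (p > 0 && substr(s, L, L) == substr(rs, p, p)) {
    s <- paste0(substr(rs, p, p), substr(s, 1, L - 1))
    p <- p - 1L
  }
  list(p = p, seq = s)
}

vcf_style_insertion <- function(rs, p, s, qp, at_edge) {
  L <- nchar(s)
  if (p == 0) {  # no base to the left: anchor on the following base
    anchor <- substr(rs, 1, 1)
    tibble(ref_pos = 1L, qry_pos = 1L, type = "insertion",
           ref = anchor, alt = paste0(s, anchor), length = L,
           ev_start = 0L, ev_end = 0L, origin_spanning = at_edge)
  } else {
    anchor <- substr(rs, p, p)
    tibble(ref_pos = p, qry_pos = qp, type = "insertion",
           ref = anchor, alt = paste0(anchor, s), length = L,
           ev_start = p, ev_end = p, origin_spanning = at_edge)
  }
}

vcf_style_deletion <- function(rs, p, L, qp, at_edge) {
  del <- substr(rs, p + 1, p + L)
  if (p == 0) {
    anchor <- substr(rs, L + 1, L + 1)
    tibble(ref_pos = 1L, qry_pos = 1L, type = "deletion",
           ref = paste0(del, anchor), alt = anchor, length = L,
           ev_start = 0L, ev_end = L, origin_spanning = at_edge)
  } else {
    anchor <- substr(rs, p, p)
    tibble(ref_pos = p, qry_pos = qp, type = "deletion",
           ref = paste0(anchor, del), alt = anchor, length = L,
           ev_start = p, ev_end = p + L, origin_spanning = at_edge)
  }
}

assign_context <- function(v, features, genome_len) {
  if (nrow(v) == 0) {
    v$context <- character(0); v$flank_genes <- character(0); v$gene <- character(0)
    return(v)
  }
  if (is.null(features) || nrow(features) == 0) {
    v$context <- NA_character_; v$flank_genes <- NA_character_; v$gene <- NA_character_
    return(v)
  }
  genes <- features %>% filter(.data$kind %in% c("gene", "tRNA", "rRNA"))
  if (nrow(genes) == 0) {
    v$context <- "intergenic"; v$flank_genes <- NA_character_; v$gene <- NA_character_
    return(v)
  }
  ctx <- map(seq_len(nrow(v)), function(z) {
    s <- v$ev_start[z]; e <- v$ev_end[z]
    hit <- if (e > s) {
      which(genes$start < e & genes$end > s)
    } else {  # insertion point: strictly inside a feature
      which(genes$start < s & genes$end > s)
    }
    if (length(hit)) {
      list(context = "genic", gene = genes$name[hit[1]], flank = NA_character_)
    } else {
      dl <- (s - genes$end) %% genome_len
      dr <- (genes$start - e) %% genome_len
      list(context = "intergenic", gene = NA_character_,
           flank = paste0(genes$name[which.min(dl)], "-",
                          genes$name[which.min(dr)]))
    }
  })
  v$context <- map_chr(ctx, "context")
  v$gene <- map_chr(ctx, "gene")
  v$flank_genes <- map_chr(ctx, "flank")
  v
}

#' Count variants overlapping named genes
#'
#' @param variants tibble from [call_variants()].
#' @param gene_names character vector of gene names to scan.
#' @param features annotation tibble (same coordinates as the variant calls).
#' @return tibble with `gene` and `n_variants`.
#' @export
gene_variant_scan <- function(variants, gene_names, features) {
  genes <- features %>% filter(.data$kind %in% c("gene", "tRNA", "rRNA"))
  missing <- setdiff(gene_names, genes$name)
  if (length(missing)) {
    abort(paste0("unknown gene name(s): ", paste(missing, collapse = ", "),
                 ". Available: ", paste(sort(unique(genes$name)), collapse = ", ")))
  }
  counts <- map_int(gene_names, function(g) {
    gg <- genes[genes$name == g, , drop = FALSE]
    if (nrow(variants) == 0) return(0L)
    hit <- map_lgl(seq_len(nrow(variants)), function(z) {
      s <- variants$ev_start[z]; e <- variants$ev_end[z]
      any(if (e > s) gg$start < e & gg$end > s else gg$start < s & gg$end > s)
    })
    sum(hit)
  })
  tibble(gene = gene_names, n_variants = counts)
}

#' Summarise a variant call set
#'
#' SNP/MNP/InDel counts in both MNP conventions plus the signed InDel sum
#' (insertions positive), which must equal the query-minus-reference length
#' difference.
#' @param variants tibble from [call_variants()].
#' @return one-row tibble.
#' @export
variant_summary <- function(variants) {
  signed <- sum(ifelse(variants$type == "insertion", variants$length,
                       ifelse(variants$type == "deletion", -variants$length, 0L)))
  tibble(
    n_snp = sum(variants$type == "SNP"),
    n_mnp = sum(variants$type == "MNP"),
    n_snp_decomposed = sum(variants$type == "SNP") +
      sum(nchar(variants$ref[variants$type == "MNP"])),
    n_indel = sum(variants$type %in% c("insertion", "deletion")),
    indel_signed_sum = signed,
    n_genic = sum(variants$context == "genic", na.rm = TRUE),
    n_intergenic = sum(variants$context == "intergenic", na.rm = TRUE)
  )
}

#' Write variant calls as VCF 4.3
#'
#' @param variants tibble from [call_variants()].
#' @param ref_genome the reference [cp_genome()].
#' @param path output path.
#' @export
write_vcf <- function(variants, ref_genome, path) {
  hdr <- c(
    "##fileformat=VCFv4.3",
    paste0("##source=chlorotype ", utils::packageVersion("chlorotype")),
    sprintf("##contig=<ID=%s,length=%d>", ref_genome$id, nchar(ref_genome$seq)),
    '##INFO=<ID=TYPE,Number=1,Type=String,Description="SNP, MNP, insertion or deletion">',
    '##INFO=<ID=LEN,Number=1,Type=Integer,Description="Absolute InDel length">',
    '##INFO=<ID=CONTEXT,Number=1,Type=String,Description="genic or intergenic">',
    '##INFO=<ID=FLANK,Number=1,Type=String,Description="Flanking gene pair for intergenic events">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(variants) > 0) {
    info <- sprintf("TYPE=%s;LEN=%d%s%s", variants$type, variants$length,
                    ifelse(is.na(variants$context), "",
                           paste0(";CONTEXT=", variants$context)),
                    ifelse(is.na(variants$flank_genes), "",
                           paste0(";FLANK=", variants$flank_genes)))
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    ref_genome$id, variants$ref_pos, variants$ref,
                    variants$alt, info)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
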