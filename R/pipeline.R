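## Pipeline entry points: one function per stage, each writing its outputs
## plus a JSON run manifest (package version, parameters, input checksums).
## A thin Rscript wrapper in inst/scripts/chlorotype exposes them as
## subcommands; logging goes to stderr, results to files only.

run_manifest <- function(out_dir, stage, params, inputs = character()) {
  man <- list(
    tool = "chlorotype",
    version = as.character(utils::packageVersion("chlorotype")),
    stage = stage,
    parameters = params,
    inputs = if (length(inputs)) {
      lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
    } else list()
  )
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

prepare_out <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

load_genomes <- function(paths) {
  map(paths, read_genome)
}

#' Pipeline stage: quadripartite structure report
#'
#' Detects the structure of every input genome and writes a per-genome
#' region table plus the cross-genome comparison TSV; genomes with
#' annotations also get a junction report (JSON).
#'
#' @param inputs FASTA/GenBank paths.
#' @param out_dir output directory.
#' @param min_ir_len passed to [detect_structure()].
#' @return the comparison tibble, invisibly.
#' @export
run_structure <- function(inputs, out_dir, min_ir_len = 1000) {
  prepare_out(out_dir)
  genomes <- load_genomes(inputs)
  structures <- map(genomes, detect_structure, min_ir_len = min_ir_len)
  tab <- if (length(structures) >= 2) compare_structures(structures)
         else glance(structures[[1]])
  readr::write_tsv(tab, file.path(out_dir, "structure.tsv"))
  jx <- imap(structures, function(st, i) {
    g <- genomes[[i]]
    if (nrow(g$features) == 0) return(NULL)
    junction_report(g, st)
  })
  jx <- compact(jx)
  if (length(jx)) {
    jsonlite::write_json(jx, file.path(out_dir, "junctions.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_manifest(out_dir, "structure", list(min_ir_len = min_ir_len), unlist(inputs))
  invisible(tab)
}

#' Pipeline stage: pairwise comparison and variant calling
#'
#' @param ref_path,qry_path genome files (reference first).
#' @param out_dir output directory.
#' @param mnp MNP mode, see [call_variants()].
#' @param k,max_window passed to [align_genomes()].
#' @return the variant tibble, invisibly.
#' @export
run_compare <- function(ref_path, qry_path, out_dir, mnp = TRUE,
                        k = 21, max_window = 20000) {
  prepare_out(out_dir)
  ref <- read_genome(ref_path); qry <- read_genome(qry_path)
  aln <- align_genomes(ref, qry, k = k, max_window = max_window)
  vars <- call_variants(aln, features = ref$features, mnp = mnp)
  readr::write_tsv(select(vars, -"ev_start", -"ev_end"),
                   file.path(out_dir, "variants.tsv"))
  write_vcf(vars, ref, file.path(out_dir, "variants.vcf"))
  readr::write_tsv(variant_summary(vars), file.path(out_dir, "variant_summary.tsv"))
  run_manifest(out_dir, "compare",
               list(mnp = mnp, k = k, max_window = max_window,
                    scoring = as.list(aln$params$scoring)),
               c(ref_path, qry_path))
  invisible(vars)
}

#' Pipeline stage: marker candidate selection and primer design
#'
#' @inheritParams run_compare
#' @param min_indel_len strict lower bound for candidate InDel length.
#' @param design design primers for each candidate (falls back to the
#'   candidate table alone when no primer is admissible).
#' @return the candidate tibble, invisibly.
#' @export
run_markers <- function(ref_path, qry_path, out_dir, min_indel_len = 20,
                        design = TRUE) {
  prepare_out(out_dir)
  ref <- read_genome(ref_path); qry <- read_genome(qry_path)
  aln <- align_genomes(ref, qry)
  vars <- call_variants(aln, features = ref$features)
  cand <- select_marker_candidates(vars, ref, qry, min_len = min_indel_len)
  readr::write_tsv(select(cand, -"ev_start", -"ev_end"),
                   file.path(out_dir, "candidates.tsv"))
  if (design && nrow(cand) > 0) {
    designed <- map(seq_len(nrow(cand)), function(z) {
      tryCatch(design_primers(cand[z, ], ref, qry),
               chlorotype_no_primer = function(e) NULL)
    })
    designed <- bind_rows(compact(designed))
    if (nrow(designed) > 0) {
      # reference is typically the N cytotype in this pipeline
      mk <- marker_set(designed$name, designed$fwd, designed$rev,
                       expected_S = designed$size_qry,
                       expected_N = designed$size_ref)
      write_markers(mk, file.path(out_dir, "markers.yaml"))
    }
  }
  run_manifest(out_dir, "markers", list(min_indel_len = min_indel_len,
                                        design = design),
               c(ref_path, qry_path))
  invisible(cand)
}

#' Pipeline stage: cohort genotyping
#'
#' @param manifest_path TSV with columns `sample`, `cultivar`, `path`.
#' @param markers_path marker YAML ([write_markers()] format).
#' @param out_dir output directory.
#' @param tolerance_bp sizing tolerance override.
#' @return the cohort summary tibble, invisibly.
#' @export
run_genotype <- function(manifest_path, markers_path, out_dir,
                         tolerance_bp = NULL) {
  prepare_out(out_dir)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  markers <- read_markers(markers_path)
  calls <- classify_cohort(as.list(manifest$path), markers,
                           tolerance_bp = tolerance_bp)
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
  summ <- summarize_cohort(calls, manifest)
  readr::write_tsv(summ, file.path(out_dir, "cohort_summary.tsv"))
  run_manifest(out_dir, "genotype", list(tolerance_bp = tolerance_bp),
               c(manifest_path, markers_path))
  invisible(summ)
}

#' Pipeline stage: distances, NJ tree and bootstrap
#'
#' @param inputs genome paths (>= 3); the first is the star-alignment
#'   reference.
#' @param out_dir output directory.
#' @param model distance model.
#' @param n_boot bootstrap replicates (0 disables).
#' @param seed bootstrap seed.
#' @return the `cp_distfit`, invisibly.
#' @export
run_phylo <- function(inputs, out_dir, model = "tn93_mcl", n_boot = 1000,
                      seed = 1) {
  prepare_out(out_dir)
  genomes <- load_genomes(inputs)
  fit <- distance_matrix(genomes, model = model)
  write_phylip(fit, file.path(out_dir, "distances.phylip"))
  readr::write_tsv(tidy(fit), file.path(out_dir, "distances.tsv"))
  if (n_boot > 0) {
    bs <- bootstrap_support(fit, n_reps = n_boot, seed = seed)
    ape::write.tree(bs$tree, file.path(out_dir, "tree.nwk"))
    readr::write_tsv(bs$splits, file.path(out_dir, "supports.tsv"))
  } else {
    ape::write.tree(neighbor_joining(fit), file.path(out_dir, "tree.nwk"))
  }
  run_manifest(out_dir, "phylo",
               list(model = model, n_boot = n_boot, seed = seed),
               unlist(inputs))
  invisible(fit)
}

#' Pipeline stage: synthetic fixture bundle
#'
#' Writes the S/N genome pair (FASTA + GFF3), marker definitions derived
#' from the planted CNV loci, the cohort FASTA set with its manifest, and
#' the truth record as JSON.
#'
#' @param out_dir output directory.
#' @param spec a [synth_spec()]; `seed` overrides its seed when given.
#' @param seed optional seed override.
#' @param cohort also emit the per-plant cohort FASTA set.
#' @return list of generated objects, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synth_spec(), seed = NULL,
                         cohort = TRUE) {
  prepare_out(out_dir)
  if (!is.null(seed)) spec$seed <- seed
  pair <- generate_genome_pair(spec)
  write_genome(pair$N, file.path(out_dir, paste0(pair$N$id, ".fasta")))
  write_genome(pair$S, file.path(out_dir, paste0(pair$S$id, ".fasta")))
  write_features(pair$N, file.path(out_dir, paste0(pair$N$id, ".gff3")))
  write_features(pair$S, file.path(out_dir, paste0(pair$S$id, ".gff3")))
  mk <- truth_markers(pair$truth)
  write_markers(mk, file.path(out_dir, "markers.yaml"))
  co <- NULL
  if (cohort && nrow(spec$cohort) > 0) {
    co <- generate_cohort(pair, spec, dir = file.path(out_dir, "cohort"))
    manifest <- co$manifest %>% mutate(path = unname(co$paths))
    readr::write_tsv(manifest, file.path(out_dir, "cohort", "manifest.tsv"))
  }
  truth <- pair$truth
  truth$spec <- unclass(truth$spec)
  truth$spec$cnvs <- as.list(truth$spec$cnvs)
  jsonlite::write_json(
    list(segments = truth$segments, variants = truth$variants,
         cnvs = truth$cnvs, n_len = truth$n_len, s_len = truth$s_len),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  run_manifest(out_dir, "simulate", list(seed = spec$seed))
  invisible(list(pair = pair, markers = mk, cohort = co))
}

#' Marker definitions from a synthetic truth record
#' @param truth the `truth` element of [generate_genome_pair()].
#' @export
truth_markers <- function(truth) {
  marker_set(truth$cnvs$name, truth$cnvs$fwd, truth$cnvs$rev,
             expected_S = truth$cnvs$amp_S, expected_N = truth$cnvs$amp_N)
}
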