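#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quadripartite structure into a region tibble
#' @param x a `cp_structure`.
#' @param ... unused.
#' @export
tidy.cp_structure <- function(x, ...) {
  x$regions %>%
    mutate(genome_id = x$genome_id, .before = 1,
           end = .data$start + .data$length)
}

#' @rdname tidy.cp_structure
#' @export
glance.cp_structure <- function(x, ...) {
  r <- x$regions
  tibble(genome_id = x$genome_id, total_bp = x$genome_length,
         lsc_bp = r$length[r$region == "lsc"],
         ssc_bp = r$length[r$region == "ssc"],
         ira_bp = r$length[r$region == "ira"],
         irb_bp = r$length[r$region == "irb"],
         gc_percent = x$gc_percent)
}

#' Tidy an alignment into its run-length operation table
#' @param x a `cp_alignment`.
#' @param ... unused.
#' @export
tidy.cp_alignment <- function(x, ...) {
  x$ops %>% mutate(ref_id = x$ref_id, qry_id = x$qry_id, .before = 1)
}

#' @rdname tidy.cp_alignment
#' @export
glance.cp_alignment <- function(x, ...) {
  tibble(ref_id = x$ref_id, qry_id = x$qry_id,
         columns = sum(x$ops$len),
         identity = x$identity,
         n_mismatch_events = sum(x$ops$op == "X"),
         n_gap_events = sum(x$ops$op %in% c("I", "D")))
}

#' Tidy a distance fit into a pairwise tibble
#' @param x a `cp_distfit`.
#' @param ... unused.
#' @export
tidy.cp_distfit <- function(x, ...) {
  idx <- which(upper.tri(x$D), arr.ind = TRUE)
  tibble(taxon_a = x$taxa[idx[, 1]], taxon_b = x$taxa[idx[, 2]],
         distance = x$D[idx])
}

#' @rdname tidy.cp_distfit
#' @export
glance.cp_distfit <- function(x, ...) {
  tibble(n_taxa = length(x$taxa), model = x$model, n_sites = x$n_sites,
         n_patterns = nrow(x$patterns$P),
         freq_A = x$freqs[["A"]], freq_C = x$freqs[["C"]],
         freq_G = x$freqs[["G"]], freq_T = x$freqs[["T"]])
}

#' Plot a quadripartite structure as a linear segment map
#' @param object a `cp_structure`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cp_structure <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                  ymin = 0, ymax = 1,
                                  fill = toupper(.data$region))) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = paste0(object$genome_id, " quadripartite structure")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-cultivar cytotype tallies
#' @param object a [summarize_cohort()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_cohort <- function(object, ...) {
  d <- object %>%
    filter(.data$cultivar != "Total") %>%
    tidyr::pivot_longer(c("n_S", "n_N", "n_other"),
                        names_to = "cytotype", values_to = "n") %>%
    mutate(cytotype = sub("^n_", "", .data$cytotype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cultivar, y = .data$n,
                                  fill = .data$cytotype)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(S = "#D55E00", N = "#0072B2",
                                          other = "grey60")) +
    ggplot2::labs(x = NULL, y = "plants", fill = "cytotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
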