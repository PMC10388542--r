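# Small fixture builders used across test files.

# assemble a circular quadripartite genome from explicit segments, with
# boundary bases adjusted so the planted IR cannot extend by chance
quadri_genome <- function(lsc, irb, ssc, id = "toy", features = NULL) {
  substr(lsc, nchar(lsc), nchar(lsc)) <- substr(lsc, 1, 1)
  substr(ssc, 1, 1) <- substr(ssc, nchar(ssc), nchar(ssc))
  seq <- paste0(lsc, irb, ssc, chlorotype:::revcomp(irb))
  cp_genome(id, seq, features = features %||% empty_features())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a ref/qry pair built by applying an explicit edit table to a random ref
edited_pair <- function(n = 600, edits, seed = 1, gc = 45) {
  set.seed(seed)
  ref <- cp_genome("ref", rand_seq(n, gc))
  qry <- cp_genome("qry", apply_edits(ref$seq, edits))
  list(ref = ref, qry = qry)
}

toy_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- synth_spec(seed = 42)
      cache <<- c(generate_genome_pair(sp), list(spec = sp))
    }
    cache
  }
})
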