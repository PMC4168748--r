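# memoized default reference + annotated event table shared across files
.ref_cache <- new.env(parent = emptyenv())

default_reference <- function() {
  if (is.null(.ref_cache$ref)) .ref_cache$ref <- build_reference(seed = 1L)
  .ref_cache$ref
}

annotated_table1 <- function() {
  if (is.null(.ref_cache$ann)) {
    .ref_cache$ann <- annotate_variants(table1_events(),
                                        default_reference()$model,
                                        catalogs = make_catalog_standins())
  }
  .ref_cache$ann
}

# tiny amplicon wrapper for alignment tests on arbitrary sequences;
# degenerate single-base primer "footprints" at the ends so no real
# positions are masked unless asked for
toy_amplicon <- function(seq, g_start = 1L) {
  L <- nchar(seq)
  genomic_amplicon(seq, g_start = g_start,
                   primer_up = c(g_start, g_start),
                   primer_down = c(g_start + L - 1L, g_start + L - 1L))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
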