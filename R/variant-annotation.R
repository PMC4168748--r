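#' Read / validate a known-variant catalog
#'
#' Catalogs are local TSV stand-ins for public variant databases with
#' columns `catalog_name`, `c_pos`, `ref`, `alt`, `protein_label`.
#' Matching is always by cDNA position + ref + alt (codon-level proximity
#' for the same-codon class), never by protein label.
#'
#' @param path TSV file path.
#' @return A validated catalog data.frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_catalog(df)
}

#' @rdname read_catalog
#' @param df A data.frame to validate.
#' @export
as_catalog <- function(df) {
  need <- c("catalog_name", "c_pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[c("catalog_name", "c_pos", "ref", "alt")])) {
    stop("catalog records must be unique on (catalog, c_pos, ref, alt)",
         call. = FALSE)
  }
  if (!"protein_label" %in% names(df)) df$protein_label <- NA_character_
  df
}

#' Classify a variant's novelty against catalogs
#'
#' `known_exact` iff some catalog record matches (c_pos, ref, alt)
#' exactly; otherwise `same_codon_different_change` iff some record falls
#' in the same codon; otherwise `novel`. Exact matches dominate same-codon
#' matches. All matching catalog names are recorded.
#'
#' @param c_pos,ref,alt The cDNA substitution.
#' @param catalogs A catalog data.frame (possibly several catalogs stacked
#'   via `catalog_name`), or `NULL` for no catalogs.
#' @return A list with `novelty` and `sources` (character vector, possibly
#'   empty).
#' @export
classify_novelty <- function(c_pos, ref, alt, catalogs = NULL) {
  if (is.null(catalogs) || nrow(catalogs) == 0L) {
    return(list(novelty = "novel", sources = character(0)))
  }
  catalogs <- as_catalog(catalogs)
  exact <- catalogs$c_pos == c_pos & catalogs$ref == ref &
    catalogs$alt == alt
  if (any(exact)) {
    return(list(novelty = "known_exact",
                sources = sort(unique(catalogs$catalog_name[exact]))))
  }
  same_codon <- (catalogs$c_pos + 2L) %/% 3L == (c_pos + 2L) %/% 3L
  if (any(same_codon)) {
    return(list(novelty = "same_codon_different_change",
                sources = sort(unique(catalogs$catalog_name[same_codon]))))
  }
  list(novelty = "novel", sources = character(0))
}

#' PY-NLS epitope intervals
#'
#' Defaults per the PY-NLS consensus mapped onto hnRNP A1-M9: epitope 1 is
#' the hydrophobic 273-FGPM-276 patch, epitope 2 the basic residue (R284,
#' assigned from the aligned FUS 522R), epitope 3 the C-terminal
#' R-X(2-5)-P-Y motif (284-289, RSSGPY).
#'
#' @param epitope1,epitope2,epitope3 Residue vectors.
#' @return A named list of residue vectors.
#' @export
pynls_epitopes <- function(epitope1 = 273:276, epitope2 = 284L,
                           epitope3 = 284:289) {
  list(epitope1 = as.integer(epitope1), epitope2 = as.integer(epitope2),
       epitope3 = as.integer(epitope3))
}

#' Epitope tag(s) of a residue
#'
#' @param aa_index Residue index.
#' @param epitopes A [pynls_epitopes()] list.
#' @return Character vector of epitope names containing the residue
#'   (possibly empty).
#' @export
epitope_of <- function(aa_index, epitopes = pynls_epitopes()) {
  names(epitopes)[vapply(epitopes, function(v) aa_index %in% v, TRUE)]
}

#' Map an hnRNP A1 residue to its aligned FUS residue
#'
#' Uses the packaged PY-NLS alignment. Residues outside the aligned window
#' (262-289) or facing a FUS gap return `NA` ("unmapped"), never an error.
#'
#' @param aa_index hnRNP A1 residue index (scalar or vector).
#' @param pynls The alignment table, as [pynls_alignment()].
#' @return Integer vector of FUS residues (`NA` where unmapped).
#' @export
map_to_fus <- function(aa_index, pynls = pynls_alignment()) {
  idx <- match(as.integer(aa_index), pynls$a1_pos)
  out <- rep(NA_integer_, length(aa_index))
  out[!is.na(idx)] <- pynls$fus_pos[idx[!is.na(idx)]]
  as.integer(out)
}

#' SNV positions aligning with ALS-associated FUS NLS mutations
#'
#' Two readings of the packaged alignment table are supported. Under
#' `criterion = "starred"` (default) the overlap is read off the table's
#' star row, which marks the two columns the study calls aligned
#' (275 <-> 510 and 284 <-> 522). Under `criterion = "mutation_row"` the
#' overlap is computed strictly: every SNV position whose aligned FUS
#' residue carries an entry in the FUS ALS mutation row. The strict
#' reading yields a superset of the starred one (the mutation row also
#' lists FUS 515 and 516, which align with hnRNP A1 280 and 281); the
#' discrepancy is documented in the package vignette.
#'
#' @param snv_positions hnRNP A1 residue indices carrying SNVs.
#' @param pynls The alignment table.
#' @param criterion `"starred"` or `"mutation_row"`.
#' @return Sorted integer vector of overlapping hnRNP A1 positions.
#' @export
fus_mutation_overlap <- function(snv_positions,
                                 pynls = pynls_alignment(),
                                 criterion = c("starred", "mutation_row")) {
  criterion <- match.arg(criterion)
  snv_positions <- unique(as.integer(snv_positions))
  rows <- pynls[!is.na(pynls$a1_pos) & pynls$a1_pos %in% snv_positions, ,
                drop = FALSE]
  hit <- if (criterion == "starred") {
    rows$starred
  } else {
    !is.na(rows$fus_pos) & !is.na(rows$fus_mut)
  }
  sort(rows$a1_pos[hit])
}

#' Annotate cDNA variants
#'
#' Turns `(c_pos, ref, alt)` substitutions into fully annotated records:
#' protein consequence, domain tags, PY-NLS epitope tag (for residues in
#' the aligned 262-289 window), aligned FUS residue, and novelty class
#' against the supplied catalogs. Reference mismatches propagate as
#' errors.
#'
#' @param variants data.frame with columns `c_pos`, `ref`, `alt` (extra
#'   columns such as `subject`/`group` are carried through).
#' @param model A [transcript_model()].
#' @param map A [domain_map()].
#' @param catalogs Catalog data.frame or `NULL`.
#' @param pynls PY-NLS alignment table or `NULL` to skip epitope/FUS
#'   annotation.
#' @param epitopes A [pynls_epitopes()] list.
#' @param code Genetic code table.
#' @return data.frame of class `annotated_variants` with columns
#'   `hgvs_c`, `g_pos`, `aa_index`, `ref_aa`, `alt_aa`, `cls`, `hgvs_p`,
#'   `protein_label`, `domains`, `epitope`, `fus_pos`, `novelty`,
#'   `sources` appended to the input columns.
#' @export
annotate_variants <- function(variants, model, map = domain_map(),
                              catalogs = NULL, pynls = pynls_alignment(),
                              epitopes = pynls_epitopes(),
                              code = genetic_code()) {
  stopifnot(all(c("c_pos", "ref", "alt") %in% names(variants)))
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    cq <- consequence(model, v$c_pos, v$ref, v$alt, code)
    nov <- classify_novelty(v$c_pos, v$ref, v$alt, catalogs)
    ep <- if (is.null(pynls)) character(0) else epitope_of(cq$aa_index,
                                                           epitopes)
    data.frame(
      hgvs_c = cq$hgvs_c, g_pos = c_to_g(model, v$c_pos),
      aa_index = cq$aa_index, ref_aa = cq$ref_aa, alt_aa = cq$alt_aa,
      cls = cq$cls, hgvs_p = cq$hgvs_p, protein_label = cq$protein_label,
      domains = paste(domains_at(cq$aa_index, map), collapse = ","),
      epitope = if (length(ep)) paste(ep, collapse = ",") else NA_character_,
      fus_pos = if (is.null(pynls)) NA_integer_ else map_to_fus(cq$aa_index,
                                                                pynls),
      novelty = nov$novelty,
      sources = if (length(nov$sources)) paste(nov$sources, collapse = ",")
                else NA_character_,
      stringsAsFactors = FALSE)
  })
  res <- cbind(variants, do.call(rbind, out))
  class(res) <- c("annotated_variants", class(res))
  res
}

#' Validate printed (c., p.) pairs against the reference model
#'
#' For each event row, recomputes the protein consequence of the cDNA
#' change and compares it to the printed protein label. Inconsistency is
#' a result, not an error: rows whose printed label cannot be produced by
#' the standard genetic code are flagged with the computed label as the
#' reason.
#'
#' @param events Event table with `c_pos`, `ref`, `alt`, `printed_p`.
#' @param model A [transcript_model()].
#' @param code Genetic code table.
#' @return The input with `computed_p` and logical `consistent` columns.
#' @export
validate_printed_pairs <- function(events, model, code = genetic_code()) {
  comp <- vapply(seq_len(nrow(events)), function(i) {
    consequence(model, events$c_pos[i], events$ref[i], events$alt[i],
                code)$protein_label
  }, "")
  events$computed_p <- comp
  events$consistent <- comp == events$printed_p
  events
}

#' Write annotated variants as TSV
#'
#' @param annotated An [annotate_variants()] result.
#' @param path Output path.
#' @export
write_variant_tsv <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF 4.2 file
#'
#' Emits the annotated variants against the amplicon as the single contig,
#' with consequence class, domain tags and novelty in INFO. Positions are
#' the amplicon-local genomic coordinates.
#'
#' @param annotated An [annotate_variants()] result (must carry `g_pos`).
#' @param amplicon The [genomic_amplicon()] used as contig.
#' @param path Output path (plain text, uncompressed).
#' @param contig Contig name.
#' @export
write_minimal_vcf <- function(annotated, amplicon, path,
                              contig = "HNRNPA1_amplicon_g3080_3690") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cloneSNV",
    sprintf("##contig=<ID=%s,length=%d>", contig, nchar(amplicon$sequence)),
    "##INFO=<ID=CLS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=DOMAINS,Number=.,Type=String,Description=\"Protein domain tags\">",
    "##INFO=<ID=NOVELTY,Number=1,Type=String,Description=\"Novelty class vs local catalogs\">",
    "##INFO=<ID=PLABEL,Number=1,Type=String,Description=\"Protein substitution label\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  pos <- annotated$g_pos - amplicon$g_start + 1L
  info <- sprintf("CLS=%s;DOMAINS=%s;NOVELTY=%s;PLABEL=%s",
                  annotated$cls, annotated$domains, annotated$novelty,
                  annotated$protein_label)
  body <- paste(contig, pos, annotated$hgvs_c, annotated$ref,
                annotated$alt, ".", ".", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
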