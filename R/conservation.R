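#' Read an ortholog alignment from aligned FASTA
#'
#' Rows must be equal length; the reference (human) row must be gap-free
#' over the region of interest so that columns map one-to-one onto human
#' residue indices.
#'
#' @param path Aligned FASTA (amino acids, `-` for gaps).
#' @param region_start Human residue index of the first column.
#' @param reference_species Name of the reference row.
#' @return An `ortholog_alignment` (named character vector with
#'   attributes).
#' @export
read_ortholog_alignment <- function(path, region_start = 268L,
                                    reference_species = "Homo sapiens") {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  structure(out, class = "ortholog_alignment",
            region_start = as.integer(region_start),
            reference_species = reference_species)
}

#' @rdname read_ortholog_alignment
#' @param alignment An `ortholog_alignment`.
#' @export
write_ortholog_alignment <- function(alignment, path) {
  x <- Biostrings::AAStringSet(unclass(alignment))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

msa_matrix <- function(alignment) {
  rows <- unclass(alignment)
  attributes(rows) <- list(names = names(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  do.call(rbind, strsplit(rows, ""))
}

#' Per-column conservation report
#'
#' For each alignment column, the fraction of non-gap, non-reference rows
#' whose residue matches the reference, plus the list of differing
#' species. Gapped rows are excluded from a column's denominator.
#' Differing-species lists never include the reference.
#'
#' @param alignment An `ortholog_alignment` (see
#'   [read_ortholog_alignment()], [make_ortholog_fixture()]).
#' @return data.frame of class `conservation_report`: `col`, `human_pos`,
#'   `ref_aa`, `n_compared`, `n_identical`, `fraction`, `differing`.
#' @export
column_conservation <- function(alignment) {
  m <- msa_matrix(alignment)
  ref_name <- attr(alignment, "reference_species")
  if (!ref_name %in% rownames(m)) {
    stop("reference species '", ref_name, "' not in alignment",
         call. = FALSE)
  }
  ref <- m[ref_name, ]
  others <- m[setdiff(rownames(m), ref_name), , drop = FALSE]
  start <- attr(alignment, "region_start")
  if (any(ref == "-")) {
    stop("reference row must be gap-free over the region", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(ref), function(j) {
    col <- others[, j]
    nongap <- col != "-"
    ident <- nongap & col == ref[j]
    diff_sp <- rownames(others)[nongap & !ident]
    data.frame(
      col = j, human_pos = start + j - 1L, ref_aa = ref[j],
      n_compared = sum(nongap), n_identical = sum(ident),
      fraction = if (sum(nongap)) sum(ident) / sum(nongap) else NA_real_,
      differing = if (length(diff_sp)) paste(diff_sp, collapse = ",")
                  else NA_character_,
      stringsAsFactors = FALSE)
  }))
  class(out) <- c("conservation_report", class(out))
  out
}

#' Overlap of SNV positions with cross-species differences
#'
#' For each SNV residue position, reports whether any species in the
#' subset differs from the reference there. Positions outside the aligned
#' region are flagged `"uncovered"` rather than raising an error.
#'
#' @param positions Human residue indices carrying SNVs.
#' @param alignment An `ortholog_alignment`.
#' @param species Species subset to compare (default: all non-reference
#'   rows). An empty subset yields an empty overlap.
#' @return A list with `per_position` (data.frame `position`, `covered`,
#'   `overlaps`, `differing`) and `overlap` (sorted positions where a
#'   selected species differs).
#' @export
snv_conservation <- function(positions, alignment, species = NULL) {
  rep_df <- column_conservation(alignment)
  ref_name <- attr(alignment, "reference_species")
  m <- msa_matrix(alignment)
  all_sp <- setdiff(rownames(m), ref_name)
  if (is.null(species)) species <- all_sp
  unknown <- setdiff(species, all_sp)
  if (length(unknown)) {
    stop("species not in alignment: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(positions)) {
    return(list(per_position = data.frame(position = integer(),
                                          covered = logical(),
                                          overlaps = logical(),
                                          differing = character(),
                                          stringsAsFactors = FALSE),
                overlap = integer(0)))
  }
  per <- do.call(rbind, lapply(as.integer(positions), function(p) {
    j <- match(p, rep_df$human_pos)
    if (is.na(j)) {
      return(data.frame(position = p, covered = FALSE, overlaps = FALSE,
                        differing = NA_character_, stringsAsFactors = FALSE))
    }
    diff_sp <- if (is.na(rep_df$differing[j])) character(0)
               else strsplit(rep_df$differing[j], ",", fixed = TRUE)[[1]]
    diff_sp <- intersect(diff_sp, species)
    data.frame(position = p, covered = TRUE,
               overlaps = length(diff_sp) > 0L,
               differing = if (length(diff_sp)) paste(diff_sp,
                                                      collapse = ",")
                           else NA_character_,
               stringsAsFactors = FALSE)
  }))
  list(per_position = per,
       overlap = as.integer(sort(per$position[per$covered & per$overlaps])))
}

#' Serialize / restore a conservation report
#'
#' @param report A [column_conservation()] result.
#' @param path TSV path.
#' @export
write_conservation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_conservation_report
#' @export
read_conservation_report <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  class(out) <- c("conservation_report", class(out))
  out
}
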