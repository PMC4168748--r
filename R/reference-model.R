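#' Standard genetic code
#'
#' Returns the standard nuclear genetic code as a named character vector of
#' 64 codon -> one-letter amino-acid entries, with `"*"` marking the three
#' stop codons. This is a thin accessor around [Biostrings::GENETIC_CODE].
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  attributes(code)["alt_init_codons"] <- NULL
  code
}

#' Translate a single codon
#'
#' @param codon A 3-letter DNA string over `{A,C,G,T}`.
#' @param code Genetic code table, as returned by [genetic_code()].
#' @return One-letter amino acid symbol, `"*"` for a stop codon.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("invalid codon: '", codon, "'", call. = FALSE)
  }
  unname(code[[codon]])
}

#' Construct a genomic amplicon
#'
#' The amplicon is the PCR product on the coding strand, addressed in local
#' gene coordinates (`g.` positions, 1-based inclusive). The default anchors
#' match the hnRNP A1 exon 8-9 product: g.3080-3690, 611 bp, with the
#' upstream primer footprint at g.3080-3100 and the downstream primer
#' footprint at g.3667-3690.
#'
#' @param sequence DNA string over `{A,C,G,T}` (the plus/coding strand).
#' @param g_start Genomic coordinate of the first base.
#' @param primer_up,primer_down Length-2 integer vectors, the genomic
#'   intervals covered by the two PCR primers.
#' @return An object of class `genomic_amplicon`.
#' @export
genomic_amplicon <- function(sequence, g_start = 3080L,
                             primer_up = c(3080L, 3100L),
                             primer_down = c(3667L, 3690L)) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("amplicon sequence must be over {A,C,G,T}", call. = FALSE)
  }
  g_start <- as.integer(g_start)
  g_end <- g_start + nchar(sequence) - 1L
  for (iv in list(primer_up, primer_down)) {
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < g_start || iv[2] > g_end) {
      stop("primer interval outside amplicon bounds", call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, g_start = g_start, g_end = g_end,
         primer_intervals = list(upstream = as.integer(primer_up),
                                 downstream = as.integer(primer_down))),
    class = "genomic_amplicon")
}

#' @export
print.genomic_amplicon <- function(x, ...) {
  cat(sprintf("<genomic_amplicon> g.%d-%d (%d bp)\n",
              x$g_start, x$g_end, nchar(x$sequence)))
  invisible(x)
}

amplicon_base <- function(amplicon, g_pos) {
  if (any(g_pos < amplicon$g_start | g_pos > amplicon$g_end)) {
    stop("position outside amplicon bounds: g.",
         paste(g_pos[g_pos < amplicon$g_start | g_pos > amplicon$g_end],
               collapse = ","), call. = FALSE)
  }
  off <- g_pos - amplicon$g_start + 1L
  substring(amplicon$sequence, off, off)
}

#' Construct a transcript model over an amplicon
#'
#' Fixes the exon structure and the genomic <-> cDNA coordinate bijection.
#' The modeled cDNA window is `c.[c_first]-[c_last]` (defaults c.752-963,
#' 212 exonic bases over exons 8 and 9); codon `n` occupies
#' `c.(3n-2)..(3n)`, so the first complete codon in the default window is
#' residue 252 and the stop codon (residue 321) is c.961-963.
#'
#' @param amplicon A [genomic_amplicon()].
#' @param exons List of length-2 integer vectors, ordered disjoint genomic
#'   intervals (exon 8, exon 9).
#' @param c_first,c_last First and last cDNA positions represented.
#' @param aa_last Last full-length residue index (320).
#' @param stop_codon_c cDNA interval of the stop codon.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(amplicon, exons, c_first = 752L, c_last = 963L,
                             aa_last = 320L, stop_codon_c = c(961L, 963L)) {
  stopifnot(inherits(amplicon, "genomic_amplicon"))
  exons <- lapply(exons, as.integer)
  starts <- vapply(exons, `[`, integer(1), 1L)
  ends <- vapply(exons, `[`, integer(1), 2L)
  if (any(starts > ends)) stop("malformed exon interval", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] <= ends[-length(ends)])) {
    stop("exons must be ordered and disjoint", call. = FALSE)
  }
  if (starts[1] < amplicon$g_start || ends[length(ends)] > amplicon$g_end) {
    stop("exons outside amplicon bounds", call. = FALSE)
  }
  g_exonic <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
  n_c <- c_last - c_first + 1L
  if (length(g_exonic) != n_c) {
    stop("exon lengths (", length(g_exonic), ") do not match cDNA window (",
         n_c, ")", call. = FALSE)
  }
  cdna <- paste(amplicon_base(amplicon, g_exonic), collapse = "")
  structure(
    list(amplicon = amplicon, exons = exons,
         c_first = as.integer(c_first), c_last = as.integer(c_last),
         aa_first_full = (as.integer(c_first) - 1L) %/% 3L + 2L,
         aa_last = as.integer(aa_last),
         stop_codon_c = as.integer(stop_codon_c),
         g_exonic = g_exonic, cdna = cdna),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> c.%d-%d over %d exons; residues %d-%d (+stop)\n",
    x$c_first, x$c_last, length(x$exons), x$aa_first_full, x$aa_last))
  invisible(x)
}

#' Convert genomic to cDNA coordinates (and back)
#'
#' `g_to_c()` maps an exonic genomic position to its cDNA position;
#' intronic or flanking positions raise a "non-coding position" error that
#' names the offending coordinate. `c_to_g()` is the inverse on the modeled
#' cDNA window.
#'
#' @param model A [transcript_model()].
#' @param g_pos,c_pos Integer coordinate(s).
#' @return Integer vector of mapped positions.
#' @export
g_to_c <- function(model, g_pos) {
  amp <- model$amplicon
  if (any(g_pos < amp$g_start | g_pos > amp$g_end)) {
    stop("position outside amplicon bounds: g.",
         paste(setdiff(g_pos, amp$g_start:amp$g_end), collapse = ","),
         call. = FALSE)
  }
  idx <- match(as.integer(g_pos), model$g_exonic)
  if (anyNA(idx)) {
    stop("non-coding position: g.",
         paste(g_pos[is.na(idx)], collapse = ","), call. = FALSE)
  }
  model$c_first + idx - 1L
}

#' @rdname g_to_c
#' @export
c_to_g <- function(model, c_pos) {
  c_pos <- as.integer(c_pos)
  if (any(c_pos < model$c_first | c_pos > model$c_last)) {
    stop("cDNA position outside modeled window: c.",
         paste(c_pos[c_pos < model$c_first | c_pos > model$c_last],
               collapse = ","), call. = FALSE)
  }
  model$g_exonic[c_pos - model$c_first + 1L]
}

#' Codon index and offset of a cDNA position
#'
#' Codon `n` occupies c.(3n-2)..(3n), the unique framing consistent with
#' the amplicon's printed (c., p.) coordinate pairs (e.g. c.826 sits in
#' codon 276, c.900 closes codon 300).
#'
#' @param c_pos cDNA position(s), integer >= 1.
#' @return A data.frame with columns `residue` and `offset` (1..3).
#' @export
codon_of <- function(c_pos) {
  c_pos <- as.integer(c_pos)
  if (any(c_pos < 1L)) stop("cDNA position must be >= 1", call. = FALSE)
  residue <- (c_pos + 2L) %/% 3L
  data.frame(residue = residue, offset = c_pos - 3L * (residue - 1L))
}

#' Reference base / codon lookup
#'
#' @param model A [transcript_model()].
#' @param c_pos cDNA position(s) within the modeled window.
#' @return `ref_base_c()`: single characters; `ref_codon()`: the 3-letter
#'   reference codon of `residue` (must lie fully inside the window).
#' @export
ref_base_c <- function(model, c_pos) {
  c_pos <- as.integer(c_pos)
  off <- c_pos - model$c_first + 1L
  if (any(off < 1L | off > nchar(model$cdna))) {
    stop("cDNA position outside modeled window: c.",
         paste(c_pos[off < 1L | off > nchar(model$cdna)], collapse = ","),
         call. = FALSE)
  }
  substring(model$cdna, off, off)
}

#' @rdname ref_base_c
#' @param residue Residue index (first full codon .. stop codon).
#' @export
ref_codon <- function(model, residue) {
  residue <- as.integer(residue)
  first <- 3L * residue - 2L
  if (first < model$c_first || first + 2L > model$c_last) {
    stop("codon ", residue, " not fully contained in the modeled window",
         call. = FALSE)
  }
  paste(ref_base_c(model, first:(first + 2L)), collapse = "")
}

#' Protein consequence of a cDNA substitution
#'
#' Translates the reference and mutated codon and classifies the change as
#' `missense`, `synonymous`, `nonsense` (sense -> stop), `stop_retained`
#' (stop -> stop) or `stop_lost`. The supplied reference base must match the
#' model; a mismatch raises a "reference mismatch" error.
#'
#' @param model A [transcript_model()].
#' @param c_pos cDNA position of the substitution.
#' @param ref,alt Single reference/alternate nucleotides (must differ).
#' @param code Genetic code table.
#' @return A one-row data.frame (class `protein_consequence`): `c_pos`,
#'   `ref`, `alt`, `hgvs_c`, `aa_index`, `ref_aa`, `alt_aa`, `cls`,
#'   `hgvs_p`, `protein_label`.
#' @export
consequence <- function(model, c_pos, ref, alt, code = genetic_code()) {
  c_pos <- as.integer(c_pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]$", ref) || !grepl("^[ACGT]$", alt) || ref == alt) {
    stop("ref and alt must be distinct single bases", call. = FALSE)
  }
  have <- ref_base_c(model, c_pos)
  if (have != ref) {
    stop(sprintf("reference mismatch at c.%d: model has %s, caller supplied %s",
                 c_pos, have, ref), call. = FALSE)
  }
  cod <- codon_of(c_pos)
  codon <- ref_codon(model, cod$residue)
  mut <- codon
  substr(mut, cod$offset, cod$offset) <- alt
  ref_aa <- translate_codon(codon, code)
  alt_aa <- translate_codon(mut, code)
  cls <- if (ref_aa == alt_aa) {
    if (ref_aa == "*") "stop_retained" else "synonymous"
  } else if (alt_aa == "*") {
    "nonsense"
  } else if (ref_aa == "*") {
    "stop_lost"
  } else {
    "missense"
  }
  out <- data.frame(
    c_pos = c_pos, ref = ref, alt = alt,
    hgvs_c = format_hgvs_c(c_pos, ref, alt),
    aa_index = cod$residue, ref_aa = ref_aa, alt_aa = alt_aa, cls = cls,
    hgvs_p = paste0("p.", ref_aa, cod$residue, alt_aa),
    protein_label = paste0(ref_aa, cod$residue, alt_aa),
    stringsAsFactors = FALSE)
  class(out) <- c("protein_consequence", class(out))
  out
}

#' Format and parse HGVS-style variant names
#'
#' Minimal HGVS c./p. substitution grammar used throughout the package:
#' `"c.<pos><ref>><alt>"` and `"p.<ref><index><alt>"` with one-letter amino
#' acids (`*` for stop), optionally prefixed by an accession
#' (`"NM_002136.2:c.755G>A"`). `parse_hgvs(format_hgvs_c(...))` is the
#' identity on well-formed variants.
#'
#' @param c_pos,ref,alt Components of a cDNA substitution.
#' @param accession Optional accession string to prefix.
#' @return `format_hgvs_c()`: character. `parse_hgvs()`: a list with
#'   `type` (`"c"` or `"p"`), `accession` (or `NA`), and the parsed fields.
#' @export
format_hgvs_c <- function(c_pos, ref, alt, accession = NULL) {
  base <- sprintf("c.%d%s>%s", as.integer(c_pos), toupper(ref), toupper(alt))
  if (is.null(accession) || is.na(accession)) base
  else paste0(accession, ":", base)
}

#' @rdname format_hgvs_c
#' @param aa_index,ref_aa,alt_aa Components of a protein substitution.
#' @export
format_hgvs_p <- function(aa_index, ref_aa, alt_aa, accession = NULL) {
  base <- sprintf("p.%s%d%s", ref_aa, as.integer(aa_index), alt_aa)
  if (is.null(accession) || is.na(accession)) base
  else paste0(accession, ":", base)
}

#' @rdname format_hgvs_c
#' @param text String to parse.
#' @export
parse_hgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  acc <- NA_character_
  body <- text
  if (grepl(":", text, fixed = TRUE)) {
    parts <- strsplit(text, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1])) {
      stop("malformed HGVS string (bad accession prefix): '", text, "'",
           call. = FALSE)
    }
    acc <- parts[1]
    body <- parts[2]
  }
  m <- regmatches(body, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", body))[[1]]
  if (length(m) == 4L) {
    return(list(type = "c", accession = acc, c_pos = as.integer(m[2]),
                ref = m[3], alt = m[4]))
  }
  m <- regmatches(body, regexec("^p\\.([A-Z*])([0-9]+)([A-Z*=])$", body))[[1]]
  if (length(m) == 4L) {
    return(list(type = "p", accession = acc, ref_aa = m[2],
                aa_index = as.integer(m[3]), alt_aa = m[4]))
  }
  stop("malformed HGVS string: '", body, "'", call. = FALSE)
}

#' Protein domain map of the hnRNP A1 C-terminal region
#'
#' Named inclusive residue intervals: the prion-like domain (PrLD), the M9
#' nucleocytoplasmic transport domain, the core transportin-1 binding
#' domain, the MS IgG epitope and the residual C-terminus. Two interval
#' conventions are in use in the field: under the `"default"` convention
#' PrLD = 233-267 and TPNO1_core = 268-289; under the `"overlap"`
#' convention PrLD extends to 272 and TPNO1_core starts at 263, so the two
#' overlap over 263-272. Intervals may overlap; a residue can carry
#' multiple tags.
#'
#' @param convention `"default"` or `"overlap"`.
#' @return A data.frame with columns `name`, `start`, `end` and attribute
#'   `convention`.
#' @export
domain_map <- function(convention = c("default", "overlap")) {
  convention <- match.arg(convention)
  prld_end <- if (convention == "overlap") 272L else 267L
  core_start <- if (convention == "overlap") 263L else 268L
  out <- data.frame(
    name = c("PrLD", "M9", "TPNO1_core", "MS_IgG", "C_terminal"),
    start = c(233L, 268L, core_start, 293L, 306L),
    end = c(prld_end, 305L, 289L, 304L, 320L),
    stringsAsFactors = FALSE)
  attr(out, "convention") <- convention
  out
}

#' Domain tags containing a residue
#'
#' @param aa_index Residue index (1-based), scalar or vector.
#' @param map A [domain_map()].
#' @return For scalar input, a character vector of domain names; for vector
#'   input, a list of such vectors.
#' @export
domains_at <- function(aa_index, map = domain_map()) {
  one <- function(i) map$name[map$start <= i & i <= map$end]
  if (length(aa_index) == 1L) one(as.integer(aa_index))
  else lapply(as.integer(aa_index), one)
}

#' Residue membership for a region or union of regions
#'
#' @param residue Residue indices.
#' @param region Character vector of domain names (the union is taken).
#' @param map A [domain_map()].
#' @return Logical vector.
#' @export
in_region <- function(residue, region, map = domain_map()) {
  unknown <- setdiff(region, map$name)
  if (length(unknown)) {
    stop("unknown region name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- map[map$name %in% region, , drop = FALSE]
  out <- rep(FALSE, length(residue))
  for (k in seq_len(nrow(rows))) {
    out <- out | (residue >= rows$start[k] & residue <= rows$end[k])
  }
  out
}

#' Serialize / restore a transcript model as JSON
#'
#' The JSON document carries the amplicon sequence, anchors and exon
#' intervals, so a model can be rebuilt without re-running the generator.
#'
#' @param model A [transcript_model()].
#' @param path File path.
#' @return `model_from_json()` returns the restored [transcript_model()].
#' @export
model_to_json <- function(model, path) {
  doc <- list(
    sequence = model$amplicon$sequence,
    g_start = model$amplicon$g_start,
    primer_up = model$amplicon$primer_intervals$upstream,
    primer_down = model$amplicon$primer_intervals$downstream,
    exons = lapply(model$exons, as.integer),
    c_first = model$c_first, c_last = model$c_last,
    aa_last = model$aa_last, stop_codon_c = model$stop_codon_c)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  amp <- genomic_amplicon(doc$sequence, g_start = doc$g_start,
                          primer_up = doc$primer_up,
                          primer_down = doc$primer_down)
  exons <- if (is.matrix(doc$exons)) {
    lapply(seq_len(nrow(doc$exons)), function(i) doc$exons[i, ])
  } else {
    doc$exons
  }
  transcript_model(amp, exons, c_first = doc$c_first, c_last = doc$c_last,
                   aa_last = doc$aa_last, stop_codon_c = doc$stop_codon_c)
}

#' Write the amplicon as single-record FASTA
#'
#' @param amplicon A [genomic_amplicon()].
#' @param path Output path.
#' @param name FASTA record name.
#' @export
write_amplicon_fasta <- function(amplicon, path,
                                 name = "HNRNPA1_amplicon_g3080_3690") {
  x <- Biostrings::DNAStringSet(amplicon$sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
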