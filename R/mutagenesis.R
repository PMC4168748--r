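revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Melting temperature by the mutagenesis-kit formula
#'
#' `Tm = 81.5 + 0.41 * %GC - 675 / N - %mismatch`, where `N` is the primer
#' length in bases, `%GC` is `100 * (G + C) / N` computed on the primer
#' sequence as synthesized (mutated bases included in the composition),
#' and `%mismatch` is `100 * n_mismatch / N` (the natural reading of the
#' manufacturer formula; the convention is stated because it is not
#' defined by the kit documentation).
#'
#' @param seq Primer sequence (nonempty DNA string).
#' @param n_mismatch Number of template mismatches carried by the primer.
#' @return One-row data.frame: `n`, `pct_gc`, `pct_mismatch`,
#'   `tm_celsius`.
#' @export
melting_temperature <- function(seq, n_mismatch = 0L) {
  seq <- toupper(gsub("[ \t]", "", seq))
  if (!nzchar(seq)) stop("empty primer sequence", call. = FALSE)
  if (!grepl("^[ACGT]+$", seq)) {
    stop("primer must be over {A,C,G,T}", call. = FALSE)
  }
  stopifnot(n_mismatch >= 0)
  n <- nchar(seq)
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C"))
  pct_gc <- 100 * gc / n
  pct_mismatch <- 100 * n_mismatch / n
  data.frame(n = n, pct_gc = pct_gc, pct_mismatch = pct_mismatch,
             tm_celsius = 81.5 + 0.41 * pct_gc - 675 / n - pct_mismatch)
}

#' Design a QuikChange-style mutagenic primer pair
#'
#' Chooses the sense codon for the desired amino acid reachable from the
#' reference codon with the fewest nucleotide changes (ties broken by
#' lexicographically smallest codon), centers the forward primer on the
#' mutated codon with `flank` reference bases on each side, and emits the
#' reverse primer as the exact reverse complement. The three printed
#' designs of the study (F273L via c.817T>C/CTT, M276L via c.826A>C/CTG,
#' F281L via c.841T>C/CTT) are all single-base changes consistent with
#' this rule.
#'
#' @param model A [transcript_model()] providing the cDNA context.
#' @param residue Target residue index.
#' @param to_aa Desired one-letter amino acid (must differ from the
#'   reference residue).
#' @param flank Reference bases on each side of the mutated codon.
#' @param code Genetic code table.
#' @return A list of class `primer_pair`: `forward`, `reverse`,
#'   `residue`, `ref_aa`, `alt_aa`, `ref_codon`, `new_codon`,
#'   `n_mismatch`, `c_start`, `tm` (the [melting_temperature()] row of
#'   the forward primer) and `warnings`.
#' @export
design_primer_pair <- function(model, residue, to_aa, flank = 15L,
                               code = genetic_code()) {
  residue <- as.integer(residue)
  to_aa <- toupper(to_aa)
  refc <- ref_codon(model, residue)
  ref_aa <- translate_codon(refc, code)
  if (to_aa == ref_aa) {
    stop("desired amino acid equals the reference residue", call. = FALSE)
  }
  cands <- names(code)[code == to_aa]
  if (!length(cands)) {
    stop("no sense codon encodes '", to_aa, "'", call. = FALSE)
  }
  dist <- vapply(cands, function(cd) {
    sum(strsplit(cd, "")[[1]] != strsplit(refc, "")[[1]])
  }, integer(1))
  cands <- sort(cands[dist == min(dist)])
  new_codon <- cands[1]
  n_mm <- min(dist)

  first <- 3L * residue - 2L
  c_start <- max(model$c_first, first - flank)
  c_end <- min(model$c_last, first + 2L + flank)
  ctx <- paste(ref_base_c(model, c_start:c_end), collapse = "")
  off <- first - c_start + 1L
  fwd <- ctx
  substr(fwd, off, off + 2L) <- new_codon
  warnings <- character(0)
  changed <- which(strsplit(new_codon, "")[[1]] != strsplit(refc, "")[[1]])
  mut_pos <- off + changed - 1L
  if (min(mut_pos) < 10L || max(mut_pos) > nchar(fwd) - 9L) {
    warnings <- c(warnings, "mutation near terminus")
  }
  structure(
    list(forward = fwd, reverse = revcomp(fwd), residue = residue,
         ref_aa = ref_aa, alt_aa = to_aa, ref_codon = refc,
         new_codon = new_codon, n_mismatch = n_mm, c_start = c_start,
         tm = melting_temperature(fwd, n_mm), warnings = warnings),
    class = "primer_pair")
}

# best ungapped placement of a primer on a reference string; returns the
# minimal-mismatch offset (1-based) and the mismatch positions within the
# primer
best_ungapped_fit <- function(primer, reference) {
  np <- nchar(primer); nr <- nchar(reference)
  if (np > nr) return(NULL)
  pc <- strsplit(primer, "")[[1]]
  best <- NULL
  for (s in 1:(nr - np + 1L)) {
    rc <- strsplit(substr(reference, s, s + np - 1L), "")[[1]]
    mm <- which(pc != rc)
    if (is.null(best) || length(mm) < length(best$mismatches)) {
      best <- list(offset = s, mismatches = mm)
    }
  }
  best
}

#' Validate a (possibly printed) mutagenic primer pair
#'
#' Reports, without guessing intended sequences: (a) whether the reverse
#' primer is the exact reverse complement of the forward, with the
#' differing positions (or a length mismatch); (b) where the forward
#' primer sits on the reference cDNA and which positions mismatch the
#' template; (c) the substitution those mismatches imply, when they fall
#' in one full codon. Two of the study's printed pairs fail check (a)
#' verbatim; the validator reports this as data.
#'
#' @param forward,reverse Primer sequences.
#' @param model Optional [transcript_model()]; enables checks (b)/(c).
#' @param code Genetic code table.
#' @return A list of class `primer_validation`: `revcomp_ok`,
#'   `length_mismatch`, `revcomp_diff_positions`, `template_offset_c`,
#'   `template_mismatch_c`, `inferred_substitution` (a
#'   `protein_consequence` row or `NULL`), `warnings`.
#' @export
validate_primer_pair <- function(forward, reverse, model = NULL,
                                 code = genetic_code()) {
  forward <- toupper(gsub("[ \t]", "", forward))
  reverse <- toupper(gsub("[ \t]", "", reverse))
  rc <- revcomp(forward)
  length_mismatch <- nchar(reverse) != nchar(forward)
  diffs <- integer(0)
  if (!length_mismatch) {
    diffs <- which(strsplit(reverse, "")[[1]] != strsplit(rc, "")[[1]])
  }
  out <- list(revcomp_ok = !length_mismatch && length(diffs) == 0L,
              length_mismatch = length_mismatch,
              revcomp_diff_positions = diffs,
              template_offset_c = NA_integer_,
              template_mismatch_c = integer(0),
              inferred_substitution = NULL, warnings = character(0))
  if (!is.null(model)) {
    fit <- best_ungapped_fit(forward, model$cdna)
    if (!is.null(fit)) {
      out$template_offset_c <- model$c_first + fit$offset - 1L
      mm_c <- out$template_offset_c + fit$mismatches - 1L
      out$template_mismatch_c <- mm_c
      if (length(fit$mismatches)) {
        if (min(fit$mismatches) < 10L ||
            max(fit$mismatches) > nchar(forward) - 9L) {
          out$warnings <- c(out$warnings, "mutation near terminus")
        }
        codons <- unique((mm_c + 2L) %/% 3L)
        if (length(codons) == 1L && length(mm_c) == 1L) {
          alt <- substr(forward, fit$mismatches, fit$mismatches)
          out$inferred_substitution <-
            consequence(model, mm_c, ref_base_c(model, mm_c), alt, code)
        }
      }
    }
  }
  class(out) <- "primer_validation"
  out
}
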