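ext_file <- function(...) {
  system.file("extdata", ..., package = "cloneSNV", mustWork = TRUE)
}

#' Packaged variant event table (subjects x cohorts)
#'
#' The amino-acid-changing SNV events observed per subject in the clone
#' sequencing study: 30 events over 20 subjects in four groups (HC n=6,
#' RRMS n=5, SPMS n=5, PPMS n=4), each with the printed cDNA change and
#' protein label. Convenience columns `residue`/`offset` (codon arithmetic)
#' and `hgvs_c` are added on load.
#'
#' @return data.frame: `subject`, `group`, `c_pos`, `ref`, `alt`,
#'   `printed_p`, `residue`, `offset`, `hgvs_c`.
#' @export
table1_events <- function() {
  df <- utils::read.delim(ext_file("table1_variants.tsv"),
                          stringsAsFactors = FALSE)
  cod <- codon_of(df$c_pos)
  df$residue <- cod$residue
  df$offset <- cod$offset
  df$hgvs_c <- mapply(format_hgvs_c, df$c_pos, df$ref, df$alt)
  df
}

#' Cohort configuration of the clone sequencing study
#'
#' Groups, subject ids and per-group clones-sequenced denominators
#' (HC 481, RRMS 358, SPMS 355, PPMS 317).
#'
#' @return A list with `groups` (data.frame `group`, `n_subjects`,
#'   `clones`) and `subjects` (data.frame `subject`, `group`).
#' @export
cohort_config <- function() {
  groups <- data.frame(
    group = c("HC", "RRMS", "SPMS", "PPMS"),
    n_subjects = c(6L, 5L, 5L, 4L),
    clones = c(481L, 358L, 355L, 317L),
    stringsAsFactors = FALSE)
  subjects <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(
      subject = paste0(groups$group[i], "-", seq_len(groups$n_subjects[i])),
      group = groups$group[i], stringsAsFactors = FALSE)
  }))
  list(groups = groups, subjects = subjects)
}

#' Packaged PY-NLS alignment of hnRNP A1-M9 to the FUS NLS
#'
#' Column-by-column pairing of hnRNP A1 residues 262-289 with FUS residues
#' 507-526, including the gap columns, the MS-associated hnRNP A1 SNV
#' substitutions, the ALS-associated FUS mutations, and the two starred
#' columns (hnRNP A1 275 <-> FUS 510 and 284 <-> 522).
#'
#' @return data.frame: `col`, `a1_pos`, `a1_aa`, `a1_snv`, `fus_pos`,
#'   `fus_aa`, `fus_mut`, `starred`. Gap residues are `"-"`; positions
#'   absent from a row are `NA`.
#' @export
pynls_alignment <- function() {
  df <- utils::read.delim(ext_file("pynls_alignment.tsv"),
                          stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$a1_snv[df$a1_snv == "."] <- NA_character_
  df$fus_mut[df$fus_mut == "."] <- NA_character_
  df$fus_aa[df$fus_aa == "."] <- NA_character_
  df
}

#' Packaged dbSNP submission list
#'
#' The 26 submitted somatic SNVs as HGVS strings with their local ids and
#' ss accessions; used as a parsing fixture.
#'
#' @return data.frame: `number`, `hgvs_name`, `local_id`, `ss_id`.
#' @export
dbsnp_submissions <- function() {
  utils::read.delim(ext_file("dbsnp_submissions.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged site-directed mutagenesis primer pairs
#'
#' The three printed QuikChange-style primer pairs (F273L, M276L, F281L)
#' with the cDNA start coordinate of each forward primer and the cDNA
#' position of its single substituted base (`c_mut`). Two of the printed
#' pairs are internally inconsistent (see [validate_primer_pair()]); they
#' are stored verbatim.
#'
#' @return data.frame: `variant`, `target_residue`, `ref_aa`, `alt_aa`,
#'   `c_start_forward`, `c_mut`, `forward`, `reverse`.
#' @export
mutagenesis_primer_table <- function() {
  utils::read.delim(ext_file("mutagenesis_primers.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged known-variant catalog stand-ins
#'
#' Local stand-ins for the public catalog records the study compared
#' against: the COSMIC entries c.818T>G (p.F273C), c.755G>T (p.S252I) and
#' c.789T>G (p.F263L), and the dbSNP entry c.922T>C (p.S308P). See
#' [make_catalog_standins()] to extend these with seeded decoys.
#'
#' @return data.frame: `catalog_name`, `c_pos`, `ref`, `alt`,
#'   `protein_label`.
#' @export
catalog_standin_entries <- function() {
  utils::read.delim(ext_file("catalog_standins.tsv"),
                    stringsAsFactors = FALSE)
}
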