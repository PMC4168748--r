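#' Reference constraints for the amplicon stand-in
#'
#' The true genomic sequence of the amplicon is not part of the packaged
#' inputs, but the printed data pin a large part of it. This function
#' collects those constraints from the packaged fixtures:
#'
#' * every variant event contributes its reference base at `c_pos` and,
#'   where jointly satisfiable, the (ref aa, alt base -> alt aa) codon
#'   constraint implied by its printed protein label;
#' * the wild-type context of the mutagenesis primers pins c.805-857
#'   (codons 269-286) base-by-base;
#' * the PY-NLS alignment pins the protein sequence of residues 262-289;
#' * catalog stand-in records contribute their reference bases;
#' * cDNA-context anchors: c.900A with c.900A>G synonymous at R300 forces
#'   the R300 codon to CGA, and c.963A with c.963A>G stop-retained forces
#'   the stop codon to TAA.
#'
#' @param events Variant event table, as [table1_events()].
#' @param primers Mutagenesis primer table, as [mutagenesis_primer_table()].
#' @param pynls PY-NLS alignment, as [pynls_alignment()].
#' @param catalogs Catalog stand-in entries, as [catalog_standin_entries()].
#' @return A list of class `reference_constraints` with components `nt`
#'   (data.frame `c_pos`, `base`, `source`), `aa` (data.frame `residue`,
#'   `aa`, `source`) and `rows` (per-event codon constraints).
#' @export
reference_constraints <- function(events = table1_events(),
                                  primers = mutagenesis_primer_table(),
                                  pynls = pynls_alignment(),
                                  catalogs = catalog_standin_entries()) {
  nt <- data.frame(c_pos = integer(), base = character(),
                   source = character(), stringsAsFactors = FALSE)
  add_nt <- function(c_pos, base, source) {
    rbind(nt, data.frame(c_pos = as.integer(c_pos), base = base,
                         source = source, stringsAsFactors = FALSE))
  }
  nt <- add_nt(events$c_pos, events$ref, paste0("event:", events$hgvs_c))
  if (!is.null(catalogs)) {
    nt <- add_nt(catalogs$c_pos, catalogs$ref,
                 paste0("catalog:", catalogs$catalog_name))
  }
  # wild-type primer context: every base of each forward primer is
  # template sequence except the single substituted base (the printed
  # designs are all single-base changes)
  if (!is.null(primers)) {
    for (i in seq_len(nrow(primers))) {
      seqc <- strsplit(primers$forward[i], "")[[1]]
      pos <- primers$c_start_forward[i] + seq_along(seqc) - 1L
      keep <- pos != primers$c_mut[i]
      nt <- add_nt(pos[keep], seqc[keep],
                   paste0("primer:", primers$variant[i]))
    }
  }
  nt <- add_nt(c(900L, 963L), c("A", "A"), "anchor:text")
  # consistency across sources
  agg <- split(nt, nt$c_pos)
  for (grp in agg) {
    if (length(unique(grp$base)) > 1L) {
      stop("conflicting nucleotide constraints at c.", grp$c_pos[1],
           call. = FALSE)
    }
  }

  aa <- data.frame(residue = integer(), aa = character(),
                   source = character(), stringsAsFactors = FALSE)
  if (!is.null(pynls)) {
    al <- pynls[!is.na(pynls$a1_pos), c("a1_pos", "a1_aa")]
    aa <- rbind(aa, data.frame(residue = al$a1_pos, aa = al$a1_aa,
                               source = "pynls", stringsAsFactors = FALSE))
  }
  aa <- rbind(aa,
              data.frame(residue = c(300L, 321L), aa = c("R", "*"),
                         source = "anchor:text", stringsAsFactors = FALSE))

  rows <- data.frame(
    row_id = seq_len(nrow(events)),
    subject = events$subject, c_pos = events$c_pos,
    ref = events$ref, alt = events$alt,
    ref_aa = substr(events$printed_p, 1L, 1L),
    alt_aa = substr(events$printed_p, nchar(events$printed_p),
                    nchar(events$printed_p)),
    label = events$printed_p, stringsAsFactors = FALSE)
  # text-reported silent changes double as codon constraints
  rows <- rbind(rows, data.frame(
    row_id = c(NA_integer_, NA_integer_), subject = "anchor",
    c_pos = c(900L, 963L), ref = c("A", "A"), alt = c("G", "G"),
    ref_aa = c("R", "*"), alt_aa = c("R", "*"),
    label = c("R300R", "*321*"), stringsAsFactors = FALSE))
  structure(list(nt = nt, aa = aa, rows = rows),
            class = "reference_constraints")
}

codon_candidates <- function(code = genetic_code()) {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(codons)  # lexicographic, so the first satisfying codon is minimal
}

row_satisfied <- function(codon, offset, ref, alt, ref_aa, alt_aa, code) {
  if (substr(codon, offset, offset) != ref) return(FALSE)
  if (translate_codon(codon, code) != ref_aa) return(FALSE)
  mut <- codon
  substr(mut, offset, offset) <- alt
  translate_codon(mut, code) == alt_aa
}

solve_codon <- function(residue, nt, aa, rows, code, sense_only = TRUE) {
  first <- 3L * residue - 2L
  cands <- codon_candidates(code)
  # hard filters: nucleotide anchors and protein anchors
  for (k in 0:2) {
    hit <- nt[nt$c_pos == first + k, , drop = FALSE]
    if (nrow(hit)) {
      cands <- cands[substr(cands, k + 1L, k + 1L) == hit$base[1]]
    }
  }
  aa_hit <- aa[aa$residue == residue, , drop = FALSE]
  if (nrow(aa_hit)) {
    cands <- cands[vapply(cands, translate_codon, "", code = code) ==
                     aa_hit$aa[1]]
  } else if (sense_only) {
    cands <- cands[vapply(cands, translate_codon, "", code = code) != "*"]
  }
  if (!length(cands)) {
    stop("no codon satisfies the anchors at residue ", residue,
         call. = FALSE)
  }
  rws <- rows[(rows$c_pos + 2L) %/% 3L == residue, , drop = FALSE]
  sat_by <- function(keep) {
    ok <- cands
    for (j in keep) {
      off <- rws$c_pos[j] - first + 1L
      ok <- ok[vapply(ok, row_satisfied, TRUE, offset = off,
                      ref = rws$ref[j], alt = rws$alt[j],
                      ref_aa = rws$ref_aa[j], alt_aa = rws$alt_aa[j],
                      code = code)]
    }
    ok
  }
  n <- nrow(rws)
  kept <- seq_len(n)
  dropped <- integer(0)
  if (n > 0L) {
    found <- FALSE
    for (ndrop in 0:n) {
      combos <- utils::combn(seq_len(n), n - ndrop, simplify = FALSE)
      for (keep in combos) {
        ok <- sat_by(keep)
        if (length(ok)) {
          cands <- ok
          kept <- keep
          dropped <- setdiff(seq_len(n), keep)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  list(codon = cands[1],
       dropped = rws[dropped, , drop = FALSE])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministically rewrite restriction-site hits whose coordinates fall in
# `free` (editable positions, 1-based within seq)
scrub_site <- function(seq, free, site = "GAATTC") {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  repeat {
    hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    fixed_any <- FALSE
    for (h in hits) {
      pos <- h:(h + nchar(site) - 1L)
      editable <- intersect(pos, free)
      if (length(editable)) {
        p <- editable[1]
        substr(seq, p, p) <- rot[[substr(seq, p, p)]]
        fixed_any <- TRUE
        break
      }
    }
    if (!fixed_any) break  # site forced by constrained sequence; keep it
  }
  seq
}

#' Build the constraint-satisfying reference amplicon and transcript model
#'
#' For every codon of residues 252-321 the generator enumerates the 64
#' codons, keeps those satisfying the nucleotide/protein anchors, then
#' searches for the largest subset of attached variant-event constraints
#' that is jointly satisfiable (rows that cannot be satisfied are excluded
#' and reported as discrepancies, not errors) and picks the
#' lexicographically smallest satisfying codon. Unconstrained coding
#' positions receive seeded random sense codons; intron and primer-flank
#' sequence is seeded random, with the PCR primer footprints fixed to the
#' printed primer sequences, and brings the total length to 611 bp.
#' Editable (unconstrained) sequence is kept free of the EcoRI motif, since
#' the insert screen presupposes exactly two vector sites.
#'
#' @param constraints A [reference_constraints()] object.
#' @param intron_length Length of the intervening intron (default 250).
#' @param exon8_end_c Last cDNA position of exon 8 (not printed in the
#'   source data; configurable, default c.800).
#' @param flank5 Length of genomic sequence before exon 8 (default 60).
#' @param seed Integer seed for the unconstrained fill.
#' @param code Genetic code table.
#' @return A list of class `built_reference`: `amplicon`
#'   ([genomic_amplicon()]), `model` ([transcript_model()]),
#'   `discrepancies` (the excluded event rows, with their printed labels)
#'   and `codons` (data.frame of chosen codons per residue).
#' @export
build_reference <- function(constraints = reference_constraints(),
                            intron_length = 250L, exon8_end_c = 800L,
                            flank5 = 60L, seed = 1L,
                            code = genetic_code()) {
  stopifnot(inherits(constraints, "reference_constraints"))
  c_first <- 752L; c_last <- 963L
  total_len <- 611L; g_start <- 3080L
  len8 <- exon8_end_c - c_first + 1L
  len9 <- c_last - exon8_end_c
  flank3 <- total_len - flank5 - len8 - intron_length - len9
  if (flank3 < 24L || flank5 < 21L) {
    stop("layout leaves no room for the primer footprints", call. = FALSE)
  }
  set.seed(as.integer(seed))

  residues <- 252:321
  chosen <- character(length(residues))
  dropped <- list()
  for (i in seq_along(residues)) {
    r <- residues[i]
    sol <- solve_codon(r, constraints$nt, constraints$aa, constraints$rows,
                       code, sense_only = (r <= 320L))
    chosen[i] <- sol$codon
    if (nrow(sol$dropped)) dropped[[length(dropped) + 1L]] <- sol$dropped
  }
  discrepancies <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    constraints$rows[0, , drop = FALSE]
  }
  discrepancies <- discrepancies[discrepancies$subject != "anchor", ,
                                 drop = FALSE]
  rownames(discrepancies) <- NULL

  # partial codon 251: c.752-753 are its 2nd and 3rd base; unconstrained
  lead <- random_dna(2L)
  cdna <- paste0(lead, paste(chosen, collapse = ""))
  stopifnot(nchar(cdna) == c_last - c_first + 1L)

  up_primer <- "CAGATAAAGGCCCTCTTTCCC"            # g.3080-3100
  down_primer <- "CTCAGCTACATTAGGGTTATTGGG"       # g.3667-3690, reverse
  down_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(down_primer)))

  f5 <- random_dna(flank5)
  substr(f5, 1L, nchar(up_primer)) <- up_primer
  intron <- random_dna(intron_length)
  f3 <- random_dna(flank3)
  substr(f3, flank3 - nchar(down_site) + 1L, flank3) <- down_site

  exon8 <- substr(cdna, 1L, len8)
  exon9 <- substr(cdna, len8 + 1L, nchar(cdna))
  seq <- paste0(f5, exon8, intron, exon9, f3)
  stopifnot(nchar(seq) == total_len)

  # editable positions: random fill only (flanks minus primer footprints,
  # intron, and the two lead cdna bases)
  free <- c(
    (nchar(up_primer) + 1L):flank5,
    flank5 + 1L, flank5 + 2L,
    (flank5 + len8 + 1L):(flank5 + len8 + intron_length),
    (total_len - flank3 + 1L):(total_len - nchar(down_site)))
  seq <- scrub_site(seq, free)

  amp <- genomic_amplicon(seq, g_start = g_start,
                          primer_up = c(3080L, 3100L),
                          primer_down = c(3667L, 3690L))
  e8 <- c(g_start + flank5, g_start + flank5 + len8 - 1L)
  e9_start <- e8[2] + intron_length + 1L
  model <- transcript_model(amp, list(e8, c(e9_start, e9_start + len9 - 1L)),
                            c_first = c_first, c_last = c_last)
  structure(
    list(amplicon = amp, model = model, discrepancies = discrepancies,
         codons = data.frame(residue = residues, codon = chosen,
                             aa = vapply(chosen, translate_codon, "",
                                         code = code),
                             stringsAsFactors = FALSE)),
    class = "built_reference")
}

#' @export
print.built_reference <- function(x, ...) {
  cat(sprintf(
    "<built_reference> %d bp amplicon; %d discrepant event row(s)\n",
    nchar(x$amplicon$sequence), nrow(x$discrepancies)))
  invisible(x)
}

all_substitutions <- function(codon) {
  out <- expand.grid(offset = 1:3, alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  out$ref <- substring(codon, out$offset, out$offset)
  out[out$ref != out$alt, c("offset", "ref", "alt")]
}

#' Simulate a clone set with somatic and PCR-error substitution processes
#'
#' Each clone starts as a faithful copy of the reference amplicon. With
#' probability `somatic_prob` a somatic amino-acid-changing SNV is planted:
#' a residue is drawn uniformly from `region` (intersected with the full
#' codons of the model) and one of that codon's nonsynonymous single-base
#' changes is drawn uniformly. Independently, with probability
#' `pcr_error_prob` (default 0.001, the fidelity of the proofreading
#' polymerase used in the assay) a polymerase error plants one uniform
#' random substitution anywhere in the amplicon. At most one somatic event
#' per clone is planted, matching the event-counting convention of
#' [count_events()].
#'
#' @param reference A `built_reference` (or a list with `amplicon` and
#'   `model`).
#' @param n_clones Number of clones.
#' @param subject Subject id used in the read names (`"subject|clone"`).
#' @param somatic_prob Per-clone probability of a somatic SNV.
#' @param region Character vector of domain names defining where somatic
#'   SNVs are planted (default `"M9"`).
#' @param pcr_error_prob Per-clone probability of a polymerase error.
#' @param map A [domain_map()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param code Genetic code table.
#' @return A list of class `clone_set`: `reads` (named character vector of
#'   clone sequences) and `truth` (data.frame `clone_id`, `subject`,
#'   `kind` = somatic|pcr_error, `g_pos`, `c_pos`, `residue`, `ref`,
#'   `alt`).
#' @export
simulate_clone_set <- function(reference, n_clones, subject = "S1",
                               somatic_prob = 0, region = "M9",
                               pcr_error_prob = 0.001,
                               map = domain_map(), seed = 1L,
                               code = genetic_code()) {
  amp <- reference$amplicon
  model <- reference$model
  set.seed(as.integer(seed))
  region_res <- (model$aa_first_full:model$aa_last)
  region_res <- region_res[in_region(region_res, region, map)]
  if (somatic_prob > 0 && !length(region_res)) {
    stop("somatic region contains no full codon of the model", call. = FALSE)
  }
  ref_seq <- amp$sequence
  L <- nchar(ref_seq)
  clone_ids <- sprintf("%s|clone%04d", subject, seq_len(n_clones))
  reads <- rep(ref_seq, n_clones)
  names(reads) <- clone_ids
  truth <- list()
  is_somatic <- stats::runif(n_clones) < somatic_prob
  is_error <- stats::runif(n_clones) < pcr_error_prob
  for (i in seq_len(n_clones)) {
    s <- reads[i]
    if (is_somatic[i]) {
      r <- if (length(region_res) == 1L) region_res else sample(region_res, 1L)
      subs <- all_substitutions(ref_codon(model, r))
      subs <- subs[vapply(seq_len(nrow(subs)), function(k) {
        mut <- ref_codon(model, r)
        substr(mut, subs$offset[k], subs$offset[k]) <- subs$alt[k]
        translate_codon(mut, code) != translate_codon(ref_codon(model, r),
                                                      code)
      }, TRUE), , drop = FALSE]
      pick <- subs[sample(nrow(subs), 1L), ]
      c_pos <- 3L * r - 2L + pick$offset - 1L
      g_pos <- c_to_g(model, c_pos)
      off <- g_pos - amp$g_start + 1L
      substr(s, off, off) <- pick$alt
      truth[[length(truth) + 1L]] <- data.frame(
        clone_id = clone_ids[i], subject = subject, kind = "somatic",
        g_pos = g_pos, c_pos = c_pos, residue = r,
        ref = pick$ref, alt = pick$alt, stringsAsFactors = FALSE)
    }
    if (is_error[i]) {
      off <- sample(L, 1L)
      refb <- substr(ref_seq, off, off)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      g_pos <- amp$g_start + off - 1L
      c_pos <- tryCatch(g_to_c(model, g_pos), error = function(e) NA_integer_)
      if (substr(s, off, off) != alt) {  # may overwrite a somatic plant
        substr(s, off, off) <- alt
        truth[[length(truth) + 1L]] <- data.frame(
          clone_id = clone_ids[i], subject = subject, kind = "pcr_error",
          g_pos = g_pos, c_pos = c_pos,
          residue = if (is.na(c_pos)) NA_integer_ else (c_pos + 2L) %/% 3L,
          ref = refb, alt = alt, stringsAsFactors = FALSE)
      }
    }
    reads[i] <- s
  }
  truth <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(clone_id = character(), subject = character(),
               kind = character(), g_pos = integer(), c_pos = integer(),
               residue = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, truth = truth), class = "clone_set")
}

#' Write simulated clones as FASTA / truth table as TSV
#'
#' @param clone_set A [simulate_clone_set()] result.
#' @param fasta,truth_tsv Output paths (either may be `NULL` to skip).
#' @export
write_clone_set <- function(clone_set, fasta = NULL, truth_tsv = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(clone_set$reads)
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(truth_tsv)) {
    utils::write.table(clone_set$truth, truth_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(clone_set)
}

#' Generate known-variant catalog stand-ins
#'
#' Starts from the packaged catalog entries ([catalog_standin_entries()])
#' and appends seeded decoy records at cDNA positions upstream of the
#' modeled amplicon window (c.1-700), so decoys can never collide with a
#' study codon.
#'
#' @param n_decoys Number of decoy records.
#' @param seed Integer seed.
#' @return A catalog data.frame (`catalog_name`, `c_pos`, `ref`, `alt`,
#'   `protein_label`).
#' @export
make_catalog_standins <- function(n_decoys = 25L, seed = 1L) {
  base <- catalog_standin_entries()
  if (n_decoys > 0L) {
    set.seed(as.integer(seed))
    pos <- sample(1:700, n_decoys)
    ref <- sample(c("A", "C", "G", "T"), n_decoys, replace = TRUE)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    decoys <- data.frame(
      catalog_name = sample(unique(base$catalog_name), n_decoys,
                            replace = TRUE),
      c_pos = pos, ref = ref, alt = alt,
      protein_label = NA_character_, stringsAsFactors = FALSE)
    base <- rbind(base, decoys)
  }
  base <- base[!duplicated(base[c("c_pos", "ref", "alt")]), , drop = FALSE]
  rownames(base) <- NULL
  base
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic ortholog alignment fixture
#'
#' Builds a gap-free multi-species alignment of the modeled protein region
#' with the human row taken from the built reference's translation. Species
#' listed in `diff_spec` differ from human at exactly the given residue
#' positions (substituted deterministically); remaining listed species get
#' `n_diffs` seeded random differences each. The default emulates the
#' shape of the published cross-species comparison - mammals identical to
#' human except five rhesus differences, only one of which (residue 300)
#' coincides with an observed SNV position - without claiming the true
#' ortholog sequences.
#'
#' @param reference A `built_reference`.
#' @param region Residue interval (default 268:305, the M9 domain).
#' @param mammals Species labels copied verbatim from human.
#' @param diff_spec Named list: species -> residue positions that differ.
#' @param distant Named integer vector: species -> number of seeded random
#'   differences.
#' @param seed Integer seed.
#' @return Named character vector of equal-length aligned rows (class
#'   `ortholog_alignment`), with attributes `region_start` and
#'   `reference_species`.
#' @export
make_ortholog_fixture <- function(reference, region = 268:305,
                                  mammals = c("Homo sapiens",
                                              "Pan troglodytes",
                                              "Mus musculus", "Bos taurus"),
                                  diff_spec = list(
                                    "Macaca mulatta" = c(269, 271, 278,
                                                         300, 303)),
                                  distant = c("Gallus gallus" = 4L,
                                              "Danio rerio" = 6L,
                                              "Xenopus laevis" = 6L,
                                              "Drosophila melanogaster" = 8L),
                                  seed = 1L) {
  model <- reference$model
  human <- vapply(region, function(r) {
    translate_codon(ref_codon(model, r))
  }, "")
  set.seed(as.integer(seed))
  mutate_at <- function(row, idx) {
    for (i in idx) {
      cur <- row[i]
      row[i] <- AA20[(match(cur, AA20) %% length(AA20)) + 1L]
    }
    row
  }
  rows <- list()
  for (sp in mammals) rows[[sp]] <- human
  for (sp in names(diff_spec)) {
    idx <- match(diff_spec[[sp]], region)
    if (anyNA(idx)) {
      stop("diff_spec positions outside the aligned region", call. = FALSE)
    }
    rows[[sp]] <- mutate_at(human, idx)
  }
  for (sp in names(distant)) {
    idx <- sample(length(region), distant[[sp]])
    rows[[sp]] <- mutate_at(human, idx)
  }
  out <- vapply(rows, paste, "", collapse = "")
  structure(out, class = "ortholog_alignment",
            region_start = region[1], reference_species = mammals[1])
}

#' Build a circular cloning construct with two EcoRI sites
#'
#' Models the insert screen: a plasmid-plus-insert circle whose EcoRI
#' digestion yields two fragments with the nominal band sizes (611 and
#' 3900 by default, total 4511 nt). Fragment sizes are cut-to-cut
#' distances; the insert-derived fragment carries the amplicon sequence
#' between the site remnants. The insert must not itself contain the site.
#'
#' @param insert Insert sequence (default length 611).
#' @param vector_length Nominal length of the vector-derived fragment.
#' @param seed Seed for the synthetic vector backbone.
#' @return Character scalar, the circular construct sequence (linearized
#'   at an arbitrary origin).
#' @export
ecori_construct <- function(insert, vector_length = 3900L, seed = 1L) {
  site <- "GAATTC"
  if (grepl(site, insert, fixed = TRUE)) {
    stop("insert contains an internal EcoRI site", call. = FALSE)
  }
  n_ins <- nchar(insert)
  set.seed(as.integer(seed))
  backbone <- random_dna(vector_length - 6L)
  backbone <- scrub_site(backbone, seq_len(nchar(backbone)))
  # circle: [G][AATTC + insert core][G][AATTC + backbone core]
  core <- substr(insert, 1L, n_ins - 6L)
  construct <- paste0("G", "AATTC", core, "G", "AATTC", backbone)
  stopifnot(nchar(construct) == n_ins + vector_length)
  construct
}
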