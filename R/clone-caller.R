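#' Caller configuration
#'
#' Scoring and acceptance policy for per-clone alignment and SNV calling.
#' Defaults: match +1, mismatch -2, affine gaps costing
#' `gap_open + k * gap_extend` for a gap of length `k` (5 and 2), clone
#' acceptance at >= 98% identity over aligned columns, indel-bearing
#' clones kept in the denominator but excluded from substitution calls,
#' and automatic orientation detection (a reverse-complemented read is
#' flipped before calling; ties go to the forward orientation).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive affine gap penalties.
#' @param min_identity Minimum identity (matches / aligned columns) for a
#'   clone to be accepted.
#' @param indel_policy `"mask_calls"` (keep the clone, call no SNVs from
#'   it) or `"drop_clone"` (reject it entirely).
#' @param check_orientation Align both orientations and keep the better.
#' @param length_bounds Acceptable read length relative to the reference.
#' @param n_score Score of any column involving an N base.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(match = 1, mismatch = -2, gap_open = 5,
                          gap_extend = 2, min_identity = 0.98,
                          indel_policy = c("mask_calls", "drop_clone"),
                          check_orientation = TRUE,
                          length_bounds = c(0.5, 1.5), n_score = -1) {
  stopifnot(gap_open > 0, gap_extend > 0,
            min_identity > 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 indel_policy = match.arg(indel_policy),
                 check_orientation = isTRUE(check_orientation),
                 length_bounds = length_bounds, n_score = n_score),
            class = "caller_config")
}

caller_submat <- function(config) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(config$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- config$match
  mat["N", ] <- config$n_score
  mat[, "N"] <- config$n_score
  mat
}

#' Globally align clone reads to the reference amplicon
#'
#' Optimal global (Needleman-Wunsch, affine) alignment of each read to the
#' amplicon via [Biostrings::pairwiseAlignment]. Reads outside the length
#' bounds are rejected with reason `"length"` without aligning; when
#' orientation checking is on, each surviving read is also aligned
#' reverse-complemented and the higher-scoring orientation is kept.
#'
#' @param reads Named character vector (or `DNAStringSet`) of clone
#'   sequences, alphabet `{A,C,G,T,N}`.
#' @param amplicon A [genomic_amplicon()].
#' @param config A [caller_config()].
#' @return A list of class `clone_alignments`; one record per read with
#'   `clone_id`, `score`, `orientation`, `aligned_read`, `aligned_ref`,
#'   `identity`, `n_gap_cols`, `accepted`, `reason`.
#' @export
align_clones <- function(reads, amplicon, config = caller_config()) {
  if (inherits(reads, "DNAStringSet")) {
    r <- as.character(reads)
    names(r) <- names(reads)
    reads <- r
  }
  stopifnot(is.character(reads), length(reads) > 0)
  if (is.null(names(reads)) || anyNA(names(reads)) ||
      any(!nzchar(names(reads)))) {
    stop("reads must be named (clone ids)", call. = FALSE)
  }
  reads <- toupper(reads)
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    stop("read alphabet must be {A,C,G,T,N}: ",
         paste(names(reads)[bad], collapse = ", "), call. = FALSE)
  }
  ref_len <- nchar(amplicon$sequence)
  len_ok <- nchar(reads) >= config$length_bounds[1] * ref_len &
    nchar(reads) <= config$length_bounds[2] * ref_len

  recs <- vector("list", length(reads))
  names(recs) <- names(reads)
  for (i in which(!len_ok)) {
    recs[[i]] <- list(clone_id = names(reads)[i], score = NA_real_,
                      orientation = NA_character_,
                      aligned_read = NA_character_,
                      aligned_ref = NA_character_, identity = NA_real_,
                      n_gap_cols = NA_integer_, accepted = FALSE,
                      reason = "length")
  }
  idx <- which(len_ok)
  if (length(idx)) {
    pat <- Biostrings::DNAStringSet(reads[idx])
    subj <- Biostrings::DNAString(amplicon$sequence)
    mat <- caller_submat(config)
    aln_f <- Biostrings::pairwiseAlignment(
      pat, subj, type = "global", substitutionMatrix = mat,
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    sc_f <- Biostrings::score(aln_f)
    if (config$check_orientation) {
      aln_r <- Biostrings::pairwiseAlignment(
        Biostrings::reverseComplement(pat), subj, type = "global",
        substitutionMatrix = mat, gapOpening = config$gap_open,
        gapExtension = config$gap_extend)
      sc_r <- Biostrings::score(aln_r)
    } else {
      sc_r <- rep(-Inf, length(idx))
    }
    use_rev <- sc_r > sc_f  # ties broken toward forward
    ap_f <- as.character(Biostrings::alignedPattern(aln_f))
    as_f <- as.character(Biostrings::alignedSubject(aln_f))
    if (any(use_rev)) {
      ap_r <- as.character(Biostrings::alignedPattern(aln_r))
      as_r <- as.character(Biostrings::alignedSubject(aln_r))
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (use_rev[k]) {
        ar <- ap_r[k]; ab <- as_r[k]; sc <- sc_r[k]; ori <- "reverse"
      } else {
        ar <- ap_f[k]; ab <- as_f[k]; sc <- sc_f[k]; ori <- "forward"
      }
      rc <- strsplit(ar, "")[[1]]
      bc <- strsplit(ab, "")[[1]]
      n_gap <- sum(rc == "-" | bc == "-")
      ident <- sum(rc == bc) / length(rc)
      accepted <- ident >= config$min_identity
      reason <- if (!accepted) "identity" else NA_character_
      if (accepted && n_gap > 0L && config$indel_policy == "drop_clone") {
        accepted <- FALSE
        reason <- "indel"
      }
      recs[[i]] <- list(clone_id = names(reads)[i], score = sc,
                        orientation = ori, aligned_read = ar,
                        aligned_ref = ab, identity = ident,
                        n_gap_cols = n_gap, accepted = accepted,
                        reason = reason)
    }
  }
  structure(recs, class = "clone_alignments")
}

#' @rdname align_clones
#' @param read A single clone sequence.
#' @param clone_id Clone identifier.
#' @export
align_clone <- function(read, amplicon, config = caller_config(),
                        clone_id = "clone") {
  reads <- read
  names(reads) <- clone_id
  align_clones(reads, amplicon, config)[[1]]
}

#' Call SNVs from one clone alignment
#'
#' Emits one call per mismatch column whose reference position lies
#' outside the primer mask and whose read base is not `N`. Gap columns
#' never produce calls; under the default `"mask_calls"` policy an
#' indel-bearing clone contributes zero calls but remains accepted.
#'
#' @param aln One record from [align_clones()].
#' @param amplicon The [genomic_amplicon()] the clone was aligned to.
#' @param config A [caller_config()].
#' @return data.frame: `clone_id`, `g_pos`, `ref`, `alt`.
#' @export
call_snvs <- function(aln, amplicon, config = caller_config()) {
  empty <- data.frame(clone_id = character(), g_pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (!isTRUE(aln$accepted)) return(empty)
  if (aln$n_gap_cols > 0L && config$indel_policy == "mask_calls") {
    return(empty)
  }
  rc <- strsplit(aln$aligned_read, "")[[1]]
  bc <- strsplit(aln$aligned_ref, "")[[1]]
  g <- cumsum(bc != "-") + amplicon$g_start - 1L
  mask <- amplicon$primer_intervals
  in_mask <- (g >= mask$upstream[1] & g <= mask$upstream[2]) |
    (g >= mask$downstream[1] & g <= mask$downstream[2])
  hit <- which(bc != "-" & rc != "-" & rc != "N" & rc != bc & !in_mask)
  if (!length(hit)) return(empty)
  data.frame(clone_id = aln$clone_id, g_pos = g[hit], ref = bc[hit],
             alt = rc[hit], stringsAsFactors = FALSE)
}

#' Restriction digest fragment lengths
#'
#' Cuts at every occurrence of `site` (between the first and second base
#' for the default EcoRI site, i.e. G^AATTC). A circular molecule with k
#' sites yields k fragments; a linear one yields k+1 (including any
#' empty-adjacent pieces of length > 0 only).
#'
#' @param sequence DNA string.
#' @param site Recognition site (default `"GAATTC"`).
#' @param topology `"linear"` or `"circular"`.
#' @param cut_after Offset of the cut within the site (default 1: after
#'   the leading G).
#' @return Integer vector of fragment lengths (sorted increasing).
#' @export
digest_fragments <- function(sequence, site = "GAATTC",
                             topology = c("linear", "circular"),
                             cut_after = 1L) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (topology == "linear") {
    starts <- gregexpr(site, sequence, fixed = TRUE)[[1]]
    if (starts[1] == -1L) return(L)
    cuts <- sort(starts + cut_after - 1L)  # cut after this coordinate
    sort(diff(c(0L, cuts, L)))
  } else {
    doubled <- paste0(sequence, sequence)
    starts <- gregexpr(site, doubled, fixed = TRUE)[[1]]
    starts <- starts[starts != -1L & starts <= L]
    if (!length(starts)) return(L)
    cuts <- sort(unique((starts + cut_after - 1L - 1L) %% L + 1L))
    if (length(cuts) == 1L) return(L)
    sort(c(diff(cuts), L - cuts[length(cuts)] + cuts[1]))
  }
}

parse_read_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("read ids must be 'subject|clone': ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(subject = vapply(parts, `[`, "", 1L),
             clone = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' Align, call and annotate a whole clone set
#'
#' Drives align -> call -> annotate per clone. Read names must follow the
#' `"subject|clone"` convention; when a `cohort` is supplied every subject
#' must be declared in it. The QC report counts accepted and rejected
#' clones per subject with reasons; rejected clones are excluded from both
#' the call list and the denominator.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param reference A `built_reference` (or list with `amplicon`, `model`).
#' @param config A [caller_config()].
#' @param cohort Optional [cohort_config()]-style list; unknown subject
#'   ids raise a configuration error.
#' @param map Domain map for annotation.
#' @param code Genetic code table.
#' @return A list of class `clone_call_set`: `calls` (annotated per-clone
#'   variants; genomic and, where exonic, cDNA/protein annotation) and
#'   `qc` (per-subject clone accounting).
#' @export
call_clone_set <- function(reads, reference, config = caller_config(),
                           cohort = NULL, map = domain_map(),
                           code = genetic_code()) {
  amplicon <- reference$amplicon
  model <- reference$model
  if (inherits(reads, "DNAStringSet")) {
    r <- as.character(reads)
    names(r) <- names(reads)
    reads <- r
  }
  ids <- parse_read_ids(names(reads))
  if (!is.null(cohort)) {
    unknown <- setdiff(unique(ids$subject), cohort$subjects$subject)
    if (length(unknown)) {
      stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  alns <- align_clones(reads, amplicon, config)
  calls <- list()
  for (aln in alns) {
    cs <- call_snvs(aln, amplicon, config)
    if (nrow(cs)) calls[[length(calls) + 1L]] <- cs
  }
  calls <- if (length(calls)) {
    do.call(rbind, calls)
  } else {
    data.frame(clone_id = character(), g_pos = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  }
  if (nrow(calls)) {
    sub <- parse_read_ids(calls$clone_id)
    calls$subject <- sub$subject
    cp <- vapply(calls$g_pos, function(g) {
      tryCatch(g_to_c(model, g), error = function(e) NA_integer_)
    }, integer(1))
    calls$c_pos <- cp
    ann <- lapply(seq_len(nrow(calls)), function(i) {
      if (is.na(calls$c_pos[i])) {
        return(data.frame(hgvs_c = NA_character_, residue = NA_integer_,
                          cls = "non_coding", hgvs_p = NA_character_,
                          protein_label = NA_character_,
                          domains = NA_character_, stringsAsFactors = FALSE))
      }
      cod <- codon_of(calls$c_pos[i])
      full <- cod$residue >= model$aa_first_full &&
        3L * cod$residue <= model$c_last
      if (!full) {
        return(data.frame(hgvs_c = format_hgvs_c(calls$c_pos[i],
                                                 calls$ref[i], calls$alt[i]),
                          residue = cod$residue, cls = "partial_codon",
                          hgvs_p = NA_character_,
                          protein_label = NA_character_,
                          domains = NA_character_, stringsAsFactors = FALSE))
      }
      cq <- consequence(model, calls$c_pos[i], calls$ref[i], calls$alt[i],
                        code)
      data.frame(hgvs_c = cq$hgvs_c, residue = cq$aa_index, cls = cq$cls,
                 hgvs_p = cq$hgvs_p, protein_label = cq$protein_label,
                 domains = paste(domains_at(cq$aa_index, map),
                                 collapse = ","),
                 stringsAsFactors = FALSE)
    })
    calls <- cbind(calls, do.call(rbind, ann))
  }
  subj_all <- unique(ids$subject)
  qc <- do.call(rbind, lapply(subj_all, function(s) {
    k <- which(ids$subject == s)
    acc <- vapply(alns[k], function(a) isTRUE(a$accepted), TRUE)
    reasons <- vapply(alns[k], function(a) {
      if (isTRUE(a$accepted)) NA_character_ else a$reason
    }, "")
    data.frame(subject = s, n_reads = length(k), accepted = sum(acc),
               rejected_length = sum(reasons == "length", na.rm = TRUE),
               rejected_identity = sum(reasons == "identity", na.rm = TRUE),
               rejected_indel = sum(reasons == "indel", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(calls = calls, qc = qc, alignments = alns),
            class = "clone_call_set")
}
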