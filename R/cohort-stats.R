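round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Polymerase error model
#'
#' Per-clone probability that a clone carries a PCR-induced mutation. The
#' default 0.001 is the 0.10% per-clone mutation frequency of the
#' proofreading polymerase used in the assay.
#'
#' @param per_clone_error_prob Probability in `[0, 1)`.
#' @return A list of class `error_model`.
#' @export
error_model <- function(per_clone_error_prob = 0.001) {
  stopifnot(per_clone_error_prob >= 0, per_clone_error_prob < 1)
  structure(list(per_clone_error_prob = per_clone_error_prob),
            class = "error_model")
}

#' Count somatic SNV events in a cohort x region cell
#'
#' Counts variant events (one per table row / per-clone call) whose
#' residue lies in `region` and whose consequence class passes the
#' filter. The default filter keeps amino-acid-altering events (missense
#' and nonsense); synonymous and stop-retained events are excluded, since
#' the study's rates concern SNVs that changed the protein.
#'
#' @param events Event table carrying `group`, `residue` and a consequence
#'   class column `cls` (absent `cls` is treated as all-missense, which is
#'   the case for the packaged amino-acid-changing event table).
#' @param group Group label, or `NULL` for all groups.
#' @param region Character vector of domain names (union).
#' @param map A [domain_map()].
#' @param classes Consequence classes counted.
#' @return Integer event count.
#' @export
count_events <- function(events, group = NULL, region = "M9",
                         map = domain_map(),
                         classes = c("missense", "nonsense")) {
  df <- events
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  if (!nrow(df)) return(0L)
  keep <- in_region(df$residue, region, map)
  if ("cls" %in% names(df)) keep <- keep & df$cls %in% classes
  sum(keep)
}

#' Somatic SNV rate against the polymerase error model
#'
#' `rate_pct` is `100 * events / clones`, rounded half-up to two decimals
#' (the printing convention of the study's percentages).
#' `fold_over_error` is the ratio of the observed rate to the error rate;
#' `exceeds_one_log` formalizes "more than a log" as fold > 10.
#' `p_exceedance` is the exact one-sided binomial tail
#' P(X >= events | n = clones, p = error) - an extension beyond the
#' study's informal comparison, labeled as such.
#'
#' @param events Event count.
#' @param clones Denominator (clones sequenced), must be positive.
#' @param error An [error_model()].
#' @return One-row data.frame: `events`, `clones`, `rate_pct`,
#'   `fold_over_error`, `exceeds_one_log`, `p_exceedance`.
#' @export
region_rate <- function(events, clones, error = error_model()) {
  if (clones <= 0) stop("zero clone denominator", call. = FALSE)
  p <- error$per_clone_error_prob
  rate_pct <- round_half_up(100 * events / clones, 2L)
  fold <- if (p > 0) rate_pct / (100 * p) else Inf
  data.frame(
    events = as.integer(events), clones = as.integer(clones),
    rate_pct = rate_pct, fold_over_error = fold,
    exceeds_one_log = fold > 10,
    p_exceedance = stats::pbinom(events - 1L, clones, p,
                                 lower.tail = FALSE))
}

#' Per-group, per-region rate table
#'
#' One row per group x region preset. The default presets are the M9
#' domain and the PrLD-plus-M9 union reported by the study.
#'
#' @param events Event table (see [count_events()]).
#' @param cohort A [cohort_config()] (supplies the denominators).
#' @param regions Named list of region definitions (character vectors of
#'   domain names).
#' @param map A [domain_map()].
#' @param error An [error_model()].
#' @param classes Consequence classes counted.
#' @return data.frame with `region`, `group` and the [region_rate()]
#'   columns.
#' @export
rate_table <- function(events, cohort = cohort_config(),
                       regions = list(M9 = "M9",
                                      PrLD_M9 = c("PrLD", "M9")),
                       map = domain_map(), error = error_model(),
                       classes = c("missense", "nonsense")) {
  rows <- list()
  for (rn in names(regions)) {
    for (i in seq_len(nrow(cohort$groups))) {
      g <- cohort$groups$group[i]
      n <- count_events(events, g, regions[[rn]], map, classes)
      rr <- region_rate(n, cohort$groups$clones[i], error)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(region = rn, group = g, stringsAsFactors = FALSE), rr)
    }
  }
  do.call(rbind, rows)
}

#' Count amino-acid substitutions in a region
#'
#' The study reports the C-terminal burden as nine SNVs "occurring with
#' similar frequency" across groups; that figure matches the number of
#' distinct substitutions, of which there are fewer than events (S308P
#' appears in two subjects). Both countings are exposed.
#'
#' @param events Event table with `residue` and a protein label column.
#' @param region Character vector of domain names.
#' @param map A [domain_map()].
#' @param distinct Count distinct labels (`TRUE`) or events (`FALSE`).
#' @param label_col Which label column to count on (`"printed_p"` for the
#'   packaged table, `"protein_label"` for pipeline output).
#' @return Integer count.
#' @export
count_substitutions <- function(events, region = "C_terminal",
                                map = domain_map(), distinct = TRUE,
                                label_col = "printed_p") {
  df <- events[in_region(events$residue, region, map), , drop = FALSE]
  if (distinct) length(unique(df[[label_col]])) else nrow(df)
}

#' Render the subjects x residue-position event matrix
#'
#' A Table-1-style grid: one row per subject (including event-free ones),
#' one column per residue position carrying at least one event; cells
#' list the event as `"<pos> <ref>><alt> / <label>"`. Domain tags per
#' residue column are attached as the `"domains"` attribute.
#'
#' @param events Event table (`subject`, `c_pos`, `ref`, `alt`, `residue`
#'   and a label column).
#' @param cohort A [cohort_config()] (supplies the full subject list).
#' @param map A [domain_map()].
#' @param label_col Label column used in cells.
#' @return data.frame (subjects x `AA<residue>` columns) with attribute
#'   `domains`.
#' @export
render_matrix <- function(events, cohort = cohort_config(),
                          map = domain_map(), label_col = "printed_p") {
  res <- sort(unique(events$residue))
  subjects <- cohort$subjects$subject
  grid <- matrix("", nrow = length(subjects), ncol = length(res),
                 dimnames = list(subjects, paste0("AA", res)))
  for (i in seq_len(nrow(events))) {
    cell <- sprintf("%d %s>%s / %s", events$c_pos[i], events$ref[i],
                    events$alt[i], events[[label_col]][i])
    r <- paste0("AA", events$residue[i])
    s <- events$subject[i]
    grid[s, r] <- if (nzchar(grid[s, r])) {
      paste(grid[s, r], cell, sep = "; ")
    } else {
      cell
    }
  }
  out <- data.frame(subject = subjects, grid, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "domains") <- stats::setNames(
    vapply(res, function(r) paste(domains_at(r, map), collapse = ","), ""),
    paste0("AA", res))
  out
}
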