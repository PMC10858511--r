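#' Length-filter peptide identifications
#'
#' Keeps identifications whose bare peptide length lies in `[min, max]`
#' (8-14 residues by default, the HLA class I presentation range). Counts
#' conserve: `nrow(kept) + nrow(removed) = nrow(ids)`.
#'
#' @param ids PSM tibble ([read_psm_table()]) or any tibble with a
#'   `peptide` column.
#' @param min,max Inclusive length bounds.
#' @return List with `kept` and `removed` tibbles.
#' @export
filter_by_length <- function(ids, min = 8L, max = 14L) {
  stopifnot(is.data.frame(ids), "peptide" %in% names(ids), min <= max)
  len <- nchar(ids$peptide)
  keep <- len >= min & len <= max
  list(kept = ids[keep, , drop = FALSE], removed = ids[!keep, , drop = FALSE])
}

# All (possibly overlapping) occurrences of pattern in subject.
locate_all <- function(subject, pattern) {
  m <- stringi::stri_locate_all_fixed(subject, pattern, overlap = TRUE)[[1]]
  m[!is.na(m[, 1]), 1]
}

#' Map peptides onto mutant database entries
#'
#' Finds every occurrence (including overlapping ones) of each peptide in
#' each entry sequence and reports whether the matched span intersects the
#' entry's altered span. A peptide matching only flank residues yields
#' `covers_mutation = FALSE` and must not be counted as a mutant
#' identification.
#'
#' @param peptides Character vector of peptides, or a tibble with a
#'   `peptide` column.
#' @param entries Entry tibble from [build_entries()] /
#'   [deduplicate_entries()].
#' @return Tibble `peptide`, `entry_id`, `offset` (1-based start within
#'   the entry), `covers_mutation`.
#' @export
map_to_entries <- function(peptides, entries) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(toupper(peptides))
  stopifnot(is.data.frame(entries))
  out <- list()
  for (i in seq_len(nrow(entries))) {
    ent <- entries[i, ]
    found <- peptides[stringi::stri_detect_fixed(ent$sequence, peptides)]
    for (p in found) {
      offs <- locate_all(ent$sequence, p)
      if (length(offs)) {
        out[[length(out) + 1L]] <- tibble(
          peptide = p, entry_id = ent$entry_id, offset = as.integer(offs),
          covers_mutation = offs <= ent$span_end &
            offs + nchar(p) - 1L >= ent$span_start
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(peptide = character(), entry_id = character(),
                  offset = integer(), covers_mutation = logical())
  }
  res
}

#' Wild-type counterpart of a mutation-covering peptide
#'
#' For a missense hit, reverts the single altered residue inside the
#' peptide to its wild-type identity, yielding the positionally equivalent
#' wild peptide (the mutant/wild pair one expects to co-observe in an
#' immunopeptidome). Indel, frameshift, nonsense and stop-loss hits have
#' no positionally equivalent wild peptide and return `NA`.
#'
#' @param hits Hit tibble from [map_to_entries()] (rows with
#'   `covers_mutation = TRUE` get counterparts).
#' @param entries Entry tibble (for the altered span inside each entry).
#' @param consequences Consequence tibble (for class and wild residue).
#' @return `hits` with an added `wild_counterpart` character column.
#' @export
wild_counterpart <- function(hits, entries, consequences) {
  stopifnot(is.data.frame(hits))
  ent <- entries[match(hits$entry_id, entries$entry_id), ]
  key <- paste(consequences$gene_symbol, consequences$hgvs_c)
  cons <- consequences[match(paste(ent$gene_symbol, ent$hgvs_c), key), ]
  wc <- rep(NA_character_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!isTRUE(hits$covers_mutation[i])) next
    if (is.na(cons$mclass[i]) || cons$mclass[i] != "missense") next
    if (nchar(cons$ref_residues[i]) != 1L || nchar(cons$alt_residues[i]) != 1L) next
    pos_in_pep <- ent$span_start[i] - hits$offset[i] + 1L
    if (pos_in_pep < 1L || pos_in_pep > nchar(hits$peptide[i])) next
    p <- hits$peptide[i]
    substr(p, pos_in_pep, pos_in_pep) <- cons$ref_residues[i]
    wc[i] <- p
  }
  dplyr::mutate(hits, wild_counterpart = wc)
}

#' Classify binding-prediction ranks into binder levels
#'
#' Applies the standard elution percent-rank thresholds: strong binder
#' below `strong` (0.5 by default), weak binder from `strong` up to and
#' including `weak` (2.0), otherwise none. The boundaries themselves
#' (exactly 0.5 or 2.0) are weak.
#'
#' @param rows Rank tibble ([read_rank_table()]): `peptide`, `allele`,
#'   `percent_rank`.
#' @param strong,weak Thresholds in percent-rank units.
#' @return `rows` with an added `level` factor (`strong` < `weak` <
#'   `none`).
#' @export
call_binders <- function(rows, strong = 0.5, weak = 2.0) {
  stopifnot(is.data.frame(rows), "percent_rank" %in% names(rows),
            all(rows$percent_rank >= 0), strong <= weak)
  lev <- ifelse(rows$percent_rank < strong, "strong",
                ifelse(rows$percent_rank <= weak, "weak", "none"))
  dplyr::mutate(rows, level = factor(lev, levels = c("strong", "weak", "none")))
}

#' Best binder call per peptide
#'
#' Returns, for each peptide, the allele with the lowest percent rank (the
#' "lowest predicted rank" summary used when a peptide is scored against a
#' typed allele set).
#'
#' @param calls Output of [call_binders()].
#' @return One row per peptide: the minimum-rank allele and its level.
#' @export
best_call <- function(calls) {
  stopifnot(is.data.frame(calls))
  calls |>
    dplyr::group_by(.data$peptide) |>
    dplyr::slice_min(.data$percent_rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Mutant-peptide report
#'
#' Applies the full identification post-processing to a PSM table against
#' a mutant entry set: 8-14-residue length filter, substring mapping with
#' mutation coverage, wild-type counterpart pairing, demotion of peptides
#' that also occur in the reference proteome (a wild-type explanation
#' exists, so they are not credited as mutant), exclusion of exact I/L-swap
#' pairs (indistinguishable by mass spectrometry; retain with
#' `keep_il_swaps = TRUE` for audit), and annotation with the best binder
#' call when a rank table is supplied.
#'
#' @param psms PSM tibble ([read_psm_table()]).
#' @param entries Entry tibble.
#' @param consequences Consequence tibble the entries were built from.
#' @param rank_rows Optional rank tibble ([read_rank_table()]).
#' @param proteome Optional reference proteome tibble; peptides occurring
#'   in any reference sequence are demoted.
#' @param keep_il_swaps Keep I/L-swap peptides (default drops them).
#' @param min_length,max_length Length filter bounds.
#' @return Tibble with one row per retained mutant peptide: `peptide`,
#'   `gene_symbol`, `hgvs_c`, `hgvs_p`, `mclass`, `hyperscore`,
#'   `intensity`, `wild_counterpart`, `ambiguity`, and (with ranks)
#'   `allele`, `percent_rank`, `level`.
#' @export
mutant_peptide_report <- function(psms, entries, consequences,
                                  rank_rows = NULL, proteome = NULL,
                                  keep_il_swaps = FALSE,
                                  min_length = 8L, max_length = 14L) {
  kept <- filter_by_length(psms, min_length, max_length)$kept
  hits <- map_to_entries(kept, entries)
  hits <- hits[hits$covers_mutation, , drop = FALSE]
  if (!is.null(proteome) && nrow(hits)) {
    in_ref <- vapply(hits$peptide, function(p) {
      any(stringi::stri_detect_fixed(proteome$residues, p))
    }, logical(1), USE.NAMES = FALSE)
    hits <- hits[!in_ref, , drop = FALSE]
  }
  hits <- wild_counterpart(hits, entries, consequences)
  if (nrow(hits)) {
    amb <- rep("none", nrow(hits))
    has_wc <- !is.na(hits$wild_counterpart)
    if (any(has_wc)) {
      amb[has_wc] <- flag_indistinguishable(hits$peptide[has_wc],
                                            hits$wild_counterpart[has_wc])$kind
    }
    hits$ambiguity <- amb
    if (!keep_il_swaps) {
      hits <- hits[hits$ambiguity != "il_swap", , drop = FALSE]
    }
  } else {
    hits$ambiguity <- character(0)
  }
  ent <- entries[match(hits$entry_id, entries$entry_id), ]
  report <- dplyr::bind_cols(
    hits[, c("peptide", "wild_counterpart", "ambiguity")],
    ent[, c("gene_symbol", "hgvs_c", "hgvs_p", "mclass")]
  )
  report <- dplyr::distinct(report)
  scores <- kept |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(hyperscore = max(.data$hyperscore),
                     intensity = max(.data$intensity), .groups = "drop")
  report <- dplyr::left_join(report, scores, by = "peptide")
  if (!is.null(rank_rows)) {
    best <- best_call(call_binders(rank_rows))
    report <- dplyr::left_join(
      report, best[, c("peptide", "allele", "percent_rank", "level")],
      by = "peptide"
    )
  }
  dplyr::arrange(report, dplyr::desc(.data$hyperscore))
}

#' Plot binder-level composition
#'
#' Stacked bar of strong/weak/none calls by peptide length.
#'
#' @param calls Output of [call_binders()].
#' @return A ggplot object.
#' @export
plot_binder_levels <- function(calls) {
  stopifnot(is.data.frame(calls), "level" %in% names(calls))
  dat <- dplyr::mutate(calls, length = nchar(.data$peptide))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$length),
                                    fill = .data$level)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "peptide length (aa)", y = "peptides",
                  fill = "binder level") +
    ggplot2::theme_minimal()
}
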