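group_summary <- function(ids, group) {
  if (!nrow(ids)) {
    return(tibble(group = group, n = 0L,
                  hyperscore_median = NA_real_, hyperscore_q1 = NA_real_,
                  hyperscore_q3 = NA_real_, intensity_median = NA_real_,
                  intensity_q1 = NA_real_, intensity_q3 = NA_real_))
  }
  tibble(
    group = group, n = nrow(ids),
    hyperscore_median = median(ids$hyperscore),
    hyperscore_q1 = unname(quantile(ids$hyperscore, 0.25)),
    hyperscore_q3 = unname(quantile(ids$hyperscore, 0.75)),
    intensity_median = median(ids$intensity),
    intensity_q1 = unname(quantile(ids$intensity, 0.25)),
    intensity_q3 = unname(quantile(ids$intensity, 0.75))
  )
}

proteins_of <- function(ids) {
  if (!"protein_ids" %in% names(ids)) return(character())
  prot <- unique(unlist(ids$protein_ids))
  prot[!is.na(prot) & nzchar(prot)]
}

#' Compare peptide identifications from two database searches
#'
#' Set algebra and score summaries for the identifications produced by
#' searching the same spectra against two databases (e.g. a personal
#' WES-based and a cohort-based mutation database): common and
#' search-unique peptide sets, common and unique mapped-protein sets (all
#' mapped proteins, not razor proteins), and per-group hyperscore and
#' intensity summaries (n, median, quartiles). Peptides are compared as
#' bare uppercase sequences.
#'
#' @param ids_a,ids_b PSM tibbles ([read_psm_table()]).
#' @param names Length-2 labels for the two searches.
#' @return Object of class `search_comparison` with [tidy()], [glance()]
#'   and [autoplot()] methods; fields include `common_peptides`,
#'   `unique_a`, `unique_b`, `common_proteins`, `unique_proteins_a`,
#'   `unique_proteins_b` and `summaries`.
#' @export
compare_searches <- function(ids_a, ids_b, names = c("a", "b")) {
  stopifnot(is.data.frame(ids_a), is.data.frame(ids_b), length(names) == 2)
  pa <- unique(toupper(ids_a$peptide))
  pb <- unique(toupper(ids_b$peptide))
  common <- intersect(pa, pb)
  ua <- setdiff(pa, pb)
  ub <- setdiff(pb, pa)
  prot_a <- proteins_of(ids_a)
  prot_b <- proteins_of(ids_b)

  dedup_a <- ids_a[!duplicated(toupper(ids_a$peptide)), , drop = FALSE]
  dedup_b <- ids_b[!duplicated(toupper(ids_b$peptide)), , drop = FALSE]
  summaries <- dplyr::bind_rows(
    group_summary(dedup_a[toupper(dedup_a$peptide) %in% common, ],
                  paste0("common_", names[1])),
    group_summary(dedup_b[toupper(dedup_b$peptide) %in% common, ],
                  paste0("common_", names[2])),
    group_summary(dedup_a[toupper(dedup_a$peptide) %in% ua, ],
                  paste0("unique_", names[1])),
    group_summary(dedup_b[toupper(dedup_b$peptide) %in% ub, ],
                  paste0("unique_", names[2]))
  )
  structure(
    list(names = names,
         common_peptides = common, unique_a = ua, unique_b = ub,
         common_proteins = intersect(prot_a, prot_b),
         unique_proteins_a = setdiff(prot_a, prot_b),
         unique_proteins_b = setdiff(prot_b, prot_a),
         summaries = summaries,
         ids_a = dedup_a, ids_b = dedup_b),
    class = "search_comparison"
  )
}

#' @export
print.search_comparison <- function(x, ...) {
  cat("<search_comparison>\n")
  cat(sprintf("  peptides: %d common, %d unique to %s, %d unique to %s\n",
              length(x$common_peptides), length(x$unique_a), x$names[1],
              length(x$unique_b), x$names[2]))
  cat(sprintf("  proteins: %d common\n", length(x$common_proteins)))
  invisible(x)
}

#' @rdname compare_searches
#' @param x A `search_comparison`.
#' @param ... Unused.
#' @export
#' @method tidy search_comparison
tidy.search_comparison <- function(x, ...) x$summaries

#' @rdname compare_searches
#' @export
#' @method glance search_comparison
glance.search_comparison <- function(x, ...) {
  tibble(
    common_peptides = length(x$common_peptides),
    unique_peptides_a = length(x$unique_a),
    unique_peptides_b = length(x$unique_b),
    common_proteins = length(x$common_proteins),
    unique_proteins_a = length(x$unique_proteins_a),
    unique_proteins_b = length(x$unique_proteins_b)
  )
}

#' @rdname compare_searches
#' @param object A `search_comparison`.
#' @export
#' @method autoplot search_comparison
autoplot.search_comparison <- function(object, ...) {
  grp <- function(ids, common_set, label_common, label_unique) {
    dplyr::mutate(ids, group = ifelse(toupper(.data$peptide) %in% common_set,
                                      label_common, label_unique))
  }
  dat <- dplyr::bind_rows(
    grp(object$ids_a, object$common_peptides,
        paste0("common_", object$names[1]),
        paste0("unique_", object$names[1])),
    grp(object$ids_b, object$common_peptides,
        paste0("common_", object$names[2]),
        paste0("unique_", object$names[2]))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$hyperscore)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "hyperscore") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
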