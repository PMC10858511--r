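#' Build configuration for mutant database construction
#'
#' Bundles the tunables of the windowed database build: the flank width
#' (50 residues by default, i.e. up to 50 residues of context on each side
#' of the altered position), the minimum entry length (8, below which no
#' 8-14-mer can be contained), the FASTA wrap width and the mutant header
#' template.
#'
#' @param flank Residues of context on each side of the altered span.
#' @param min_entry_length Entries shorter than this are dropped (logged).
#' @param fasta_wrap FASTA line width.
#' @param header_template Mutant entry id template; `{gene}`, `{hgvs_c}`,
#'   `{hgvs_p}` and `{class}` are substituted.
#' @return A list of class `neodb_build_config`.
#' @export
build_config <- function(flank = 50L, min_entry_length = 8L,
                         fasta_wrap = 60L,
                         header_template = "mut|{gene}|{hgvs_c}|{hgvs_p}|{class}") {
  stopifnot(flank >= 0, min_entry_length >= 1)
  structure(
    list(flank = as.integer(flank),
         min_entry_length = as.integer(min_entry_length),
         fasta_wrap = as.integer(fasta_wrap),
         header_template = header_template),
    class = "neodb_build_config"
  )
}

render_header <- function(template, gene, hgvs_c, hgvs_p, class) {
  x <- gsub("{gene}", gene, template, fixed = TRUE)
  x <- gsub("{hgvs_c}", hgvs_c, x, fixed = TRUE)
  x <- gsub("{hgvs_p}", hgvs_p, x, fixed = TRUE)
  gsub("{class}", class, x, fixed = TRUE)
}

#' Excise windowed mutant entries from consequences
#'
#' Compresses each non-synonymous mutant protein into a compact database
#' entry carrying the altered residues plus up to `flank` residues of
#' context on each side; windows touching a terminus simply stop there.
#' Window rules by class:
#'
#' * substitutions and in-frame indels: mutant residues
#'   `[span_start - flank, span_end + flank]`, clipped to the protein;
#' * frameshift and stop-loss: the upstream flank plus the entire novel
#'   tail to the new terminus (every novel residue is informative);
#' * nonsense: the flank ending at the new C-terminus (nothing downstream
#'   of the premature stop exists to include).
#'
#' `altered_span` (`span_start`, `span_end`) records where the changed or
#' novel residues sit inside the entry. Start-loss consequences have no
#' modeled product and are dropped with reason `"no_product"`; entries
#' shorter than `min_entry_length` are dropped with reason `"too_short"`.
#'
#' @param consequences Non-synonymous consequence tibble (see
#'   [filter_nonsynonymous()]).
#' @param cfg A [build_config()].
#' @return List with `entries` (tibble: `entry_id`, `sequence`,
#'   `span_start`, `span_end`, `gene_symbol`, `hgvs_c`, `hgvs_p`, `mclass`,
#'   `source`) and `dropped` (tibble: `hgvs_c`, `gene_symbol`, `reason`).
#' @export
build_entries <- function(consequences, cfg = build_config()) {
  stopifnot(is.data.frame(consequences))
  if (any(consequences$mclass == "synonymous")) {
    stop_neodb("synonymous consequences must be filtered out before building",
               "neodb_domain_error")
  }
  flank <- cfg$flank
  rows <- vector("list", nrow(consequences))
  dropped <- vector("list", nrow(consequences))
  for (i in seq_len(nrow(consequences))) {
    cc <- consequences[i, ]
    mut <- cc$mutant_protein
    len_m <- nchar(mut)
    if (!nzchar(mut) || is.na(cc$mut_span_start)) {
      reason <- if (cc$mclass == "translation_start_site") "no_product"
                else "empty_mutant_protein"
      dropped[[i]] <- tibble(hgvs_c = cc$hgvs_c, gene_symbol = cc$gene_symbol,
                             reason = reason)
      next
    }
    ms <- min(cc$mut_span_start, len_m)
    me <- min(cc$mut_span_end, len_m)
    if (cc$mclass %in% c("frameshift_insertion", "frameshift_deletion",
                         "nonstop")) {
      lo <- max(1L, ms - flank); hi <- len_m
    } else if (cc$mclass == "nonsense") {
      lo <- max(1L, len_m - flank + 1L); hi <- len_m
      ms <- len_m; me <- len_m
    } else {
      lo <- max(1L, ms - flank); hi <- min(len_m, me + flank)
    }
    seq <- substr(mut, lo, hi)
    if (nchar(seq) < cfg$min_entry_length) {
      dropped[[i]] <- tibble(hgvs_c = cc$hgvs_c, gene_symbol = cc$gene_symbol,
                             reason = "too_short")
      next
    }
    rows[[i]] <- tibble(
      entry_id = render_header(cfg$header_template, cc$gene_symbol,
                               cc$hgvs_c, cc$hgvs_p, cc$mclass),
      sequence = seq,
      span_start = ms - lo + 1L,
      span_end = me - lo + 1L,
      gene_symbol = cc$gene_symbol, hgvs_c = cc$hgvs_c, hgvs_p = cc$hgvs_p,
      mclass = cc$mclass, source = cc$source
    )
  }
  entries <- dplyr::bind_rows(rows)
  if (!nrow(entries)) {
    entries <- tibble(entry_id = character(), sequence = character(),
                      span_start = integer(), span_end = integer(),
                      gene_symbol = character(), hgvs_c = character(),
                      hgvs_p = character(), mclass = character(),
                      source = character())
  }
  drop_tab <- dplyr::bind_rows(dropped)
  if (!nrow(drop_tab)) {
    drop_tab <- tibble(hgvs_c = character(), gene_symbol = character(),
                       reason = character())
  }
  list(entries = entries, dropped = drop_tab)
}

#' Remove redundant mutant entries
#'
#' COSMIC reports one row per tumor sample, so the same mutation recurs;
#' entries are unique on `(gene_symbol, hgvs_c, sequence)` and the first
#' occurrence wins. Idempotent, and count-conserving:
#' `nrow(unique) + duplicates_removed = nrow(input)`.
#'
#' @param entries Entry tibble from [build_entries()].
#' @return List with `entries` (unique) and `duplicates_removed` (count).
#' @export
deduplicate_entries <- function(entries) {
  stopifnot(is.data.frame(entries))
  key <- paste(entries$gene_symbol, entries$hgvs_c, entries$sequence,
               sep = "\r")
  keep <- !duplicated(key)
  list(entries = entries[keep, , drop = FALSE],
       duplicates_removed = sum(!keep))
}

#' Merge mutant entries with a reference proteome into a search FASTA
#'
#' Writes a single search-engine-ready FASTA: mutant entries first (ids
#' from the header template, embedding gene, HGVS c., HGVS p. and class),
#' then the reference proteome records unmodified. Any id shared between
#' entries and proteome is an error.
#'
#' @param entries Entry tibble ([deduplicate_entries()]).
#' @param proteome Sequence tibble ([read_fasta()]).
#' @param path Output FASTA path.
#' @param cfg A [build_config()] (controls wrap width).
#' @return Invisibly, the combined sequence tibble that was written.
#' @export
merge_with_proteome <- function(entries, proteome, path,
                                cfg = build_config()) {
  stopifnot(is.data.frame(entries), is.data.frame(proteome))
  clash <- intersect(entries$entry_id, proteome$id)
  if (length(clash)) {
    stop_neodb(sprintf("entry id(s) collide with proteome ids: %s",
                       paste(head(clash, 5), collapse = ", ")),
               "neodb_format_error")
  }
  combined <- dplyr::bind_rows(
    tibble(id = entries$entry_id, description = "",
           residues = entries$sequence),
    proteome[, c("id", "description", "residues")]
  )
  write_fasta(combined, path, wrap = cfg$fasta_wrap)
  invisible(combined)
}

#' Per-class consequence tally
#'
#' Counts consequences in each of the nine classes (all classes are always
#' present in the output, zero-filled), in the shape of a mutant
#' classification statistics table.
#'
#' @param consequences Consequence tibble.
#' @return Tibble `mclass` (factor over [mutation_classes()]), `n`.
#' @export
class_statistics <- function(consequences) {
  stopifnot(is.data.frame(consequences))
  cls <- factor(consequences$mclass, levels = MUTATION_CLASSES)
  tibble(mclass = factor(MUTATION_CLASSES, levels = MUTATION_CLASSES),
         n = as.integer(table(cls)))
}

#' Build a mutant search database end to end
#'
#' Pipeline wrapper: consequence calling on a variant table, synonymous
#' removal, windowed entry excision, deduplication, proteome merge and
#' class statistics, with stage counts that satisfy the conservation
#' identity `input = unparseable + synonymous + duplicates + dropped +
#' entries`.
#'
#' @param variants Coding-variant tibble ([read_cosmic_variants()] /
#'   [read_maf_variants()]).
#' @param cds_set CDS sequence tibble ([read_fasta()]).
#' @param proteome Reference proteome tibble, or `NULL` to build an
#'   entries-only database.
#' @param path Output FASTA path, or `NULL` to skip writing.
#' @param cfg A [build_config()].
#' @param codon_table Codon table.
#' @return Object of class `mutantdb_build`: list with `entries`,
#'   `class_counts`, `dropped`, and `counts` (stage-count tibble). Has
#'   [glance()] and [tidy()] methods.
#' @export
build_mutant_db <- function(variants, cds_set, proteome = NULL, path = NULL,
                            cfg = build_config(),
                            codon_table = default_codon_table()) {
  consequences <- call_consequences(variants, cds_set, codon_table)
  unparseable_upstream <- parse_report(variants)$unparseable
  flt <- filter_nonsynonymous(consequences)
  built <- build_entries(flt$retained, cfg)
  dd <- deduplicate_entries(built$entries)
  if (!is.null(proteome) && !is.null(path)) {
    merge_with_proteome(dd$entries, proteome, path, cfg)
  } else if (!is.null(path)) {
    write_fasta(
      tibble(id = dd$entries$entry_id, description = "",
             residues = dd$entries$sequence),
      path, wrap = cfg$fasta_wrap
    )
  }
  counts <- tibble(
    input_variants = nrow(variants) + unparseable_upstream,
    unparseable_rows = unparseable_upstream,
    consequence_failures = flt$unparseable_count,
    synonymous_removed = flt$removed_synonymous_count,
    dropped_entries = nrow(built$dropped),
    duplicates_removed = dd$duplicates_removed,
    entries = nrow(dd$entries)
  )
  structure(
    list(entries = dd$entries,
         class_counts = class_statistics(flt$retained),
         dropped = built$dropped,
         counts = counts,
         retained_total = nrow(flt$retained)),
    class = "mutantdb_build"
  )
}

#' @export
print.mutantdb_build <- function(x, ...) {
  cat("<mutantdb_build>\n")
  cat(sprintf("  %d mutant entries (%d duplicates removed, %d dropped)\n",
              nrow(x$entries), x$counts$duplicates_removed,
              x$counts$dropped_entries))
  cat(sprintf("  retained non-synonymous consequences: %d\n",
              x$retained_total))
  print(x$class_counts[x$class_counts$n > 0, ])
  invisible(x)
}

#' @export
#' @method glance mutantdb_build
glance.mutantdb_build <- function(x, ...) x$counts

#' @export
#' @method tidy mutantdb_build
tidy.mutantdb_build <- function(x, ...) x$class_counts

#' Plot a class-count table
#'
#' Bar chart of the per-class mutation tally from [class_statistics()] or
#' a `mutantdb_build`'s `class_counts`.
#'
#' @param class_counts Tibble `mclass`, `n`.
#' @return A ggplot object.
#' @export
plot_class_counts <- function(class_counts) {
  ggplot2::ggplot(class_counts,
                  ggplot2::aes(x = .data$mclass, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme_minimal()
}
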