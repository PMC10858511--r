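#' Read a FASTA file into a sequence tibble
#'
#' Reads nucleotide or protein FASTA into a tibble with one row per record.
#' Residues are normalized to uppercase and validated against the declared
#' alphabet. Header lines are split at the first whitespace into `id` and
#' `description`.
#'
#' @param path FASTA file path.
#' @param kind `"nucleotide"` or `"protein"`; controls alphabet validation.
#' @return Tibble with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_neodb(sprintf("FASTA file '%s' contains no records", path),
               "neodb_format_error")
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop_neodb(sprintf("duplicate FASTA id(s): %s",
                       paste(head(dup, 5), collapse = ", ")),
               "neodb_format_error")
  }
  residues <- toupper(as.character(set))
  bad_alpha <- if (kind == "nucleotide") {
    grepl("[^ACGTN]", residues)
  } else {
    grepl("[^A-Z*]", residues)
  }
  if (any(bad_alpha)) {
    stop_neodb(
      sprintf("record '%s' contains characters outside the %s alphabet",
              id[which(bad_alpha)[1]], kind),
      "neodb_format_error"
    )
  }
  if (any(!nzchar(residues))) {
    stop_neodb(sprintf("record '%s' is empty", id[which(!nzchar(residues))[1]]),
               "neodb_format_error")
  }
  tibble(id = unname(id), description = unname(description),
         residues = unname(residues))
}

#' Write a sequence tibble to FASTA
#'
#' Inverse of [read_fasta()]: writing then reading returns identical
#' `(id, description, residues)` triples. Duplicate ids are an error
#' because search engines key on them.
#'
#' @param records Tibble with `id`, `residues` and optionally `description`.
#' @param path Output path.
#' @param wrap Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop_neodb(sprintf("duplicate FASTA id(s): %s",
                       paste(head(dup, 5), collapse = ", ")),
               "neodb_format_error")
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc) | !nzchar(desc), "", paste0(" ", desc))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- paste0(records$id, desc)
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

write_rejects <- function(rejects, rejects_path) {
  if (!is.null(rejects_path)) {
    readr::write_tsv(rejects, rejects_path)
  }
  invisible(rejects)
}

attach_report <- function(x, total, rejects, rejects_path = NULL) {
  write_rejects(rejects, rejects_path)
  attr(x, "parse_report") <- tibble(
    total_rows = total, parsed = total - nrow(rejects),
    unparseable = nrow(rejects)
  )
  attr(x, "rejects") <- rejects
  x
}

#' Row-parse report of a table reader
#'
#' Readers in this package never fail on individual bad rows; they count
#' them. `parse_report()` returns the bookkeeping for a table returned by
#' [read_cosmic_variants()], [read_maf_variants()], [read_psm_table()] or
#' [read_rank_table()]; `parse_rejects()` returns the per-row reasons.
#'
#' @param x A tibble returned by one of the readers.
#' @return `parse_report()`: one-row tibble (`total_rows`, `parsed`,
#'   `unparseable`); `parse_rejects()`: tibble (`row`, ..., `reason`).
#' @export
parse_report <- function(x) {
  attr(x, "parse_report") %||%
    tibble(total_rows = nrow(x), parsed = nrow(x), unparseable = 0L)
}

#' @rdname parse_report
#' @export
parse_rejects <- function(x) {
  attr(x, "rejects") %||% tibble(row = integer(), reason = character())
}

#' Default COSMIC column mapping
#'
#' Field-to-column-name mapping for GenomeScreensMutant-style COSMIC TSV
#' exports (v98 defaults). Override any element, or load a mapping from a
#' JSON file with [read_column_map()], to follow a different release.
#'
#' @return Named character vector with elements `gene_symbol`,
#'   `transcript_id`, `hgvs_c`, `sample_id`, `primary_site`.
#' @export
cosmic_columns <- function() {
  c(gene_symbol = "GENE_SYMBOL", transcript_id = "TRANSCRIPT_ACCESSION",
    hgvs_c = "MUTATION_CDS", sample_id = "COSMIC_SAMPLE_ID",
    primary_site = "PRIMARY_SITE")
}

#' Default MAF column mapping
#'
#' @return Named character vector with elements `gene_symbol`,
#'   `transcript_id`, `hgvs_c`, `sample_id`.
#' @export
maf_columns <- function() {
  c(gene_symbol = "Hugo_Symbol", transcript_id = "Transcript_ID",
    hgvs_c = "HGVSc", sample_id = "Tumor_Sample_Barcode")
}

#' Load a column mapping from a JSON config file
#'
#' @param path JSON file of `{"field": "Column Name", ...}` pairs.
#' @return Named character vector usable as the `columns` argument of the
#'   table readers.
#' @export
read_column_map <- function(path) {
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(map) && all(vapply(map, is.character, TRUE))) {
    map <- unlist(map)
  }
  if (!is.character(map) || is.null(names(map)) || any(!nzchar(names(map)))) {
    stop_neodb("column map must be a JSON object of field: column pairs",
               "neodb_format_error")
  }
  map
}

require_columns <- function(tab, columns, required, path) {
  missing_cols <- setdiff(unname(columns[required]), names(tab))
  if (length(missing_cols)) {
    stop_neodb(
      sprintf("'%s' is missing required column(s): %s",
              path, paste(missing_cols, collapse = ", ")),
      "neodb_format_error"
    )
  }
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

col_or_blank <- function(tab, name) {
  if (!is.na(name) && name %in% names(tab)) tab[[name]] else rep("", nrow(tab))
}

#' Read somatic variants from a COSMIC-style TSV
#'
#' Reads a tab-separated per-sample somatic mutation export (COSMIC
#' GenomeScreensMutant dialect by default), parses the HGVS c. column and
#' returns a coding-variant tibble. Rows whose notation cannot be parsed
#' (blank, intronic, non-coding, malformed) are counted and reported via
#' [parse_report()] — they are never fatal.
#'
#' @param path TSV path with a header row.
#' @param site_filter Optional primary-site value; only matching rows
#'   (case-insensitive) are returned.
#' @param columns Field mapping, see [cosmic_columns()].
#' @param rejects_path Optional path for a sidecar TSV of rejected rows.
#' @return Coding-variant tibble (`source = "cosmic"`), with a
#'   [parse_report()] attribute. Site-filtered-out rows are excluded from
#'   the report's row total.
#' @export
read_cosmic_variants <- function(path, site_filter = NULL,
                                 columns = cosmic_columns(),
                                 rejects_path = NULL) {
  tab <- read_tsv_quiet(path)
  require_columns(tab, columns, c("gene_symbol", "hgvs_c"), path)
  if (!is.null(site_filter)) {
    require_columns(tab, columns, "primary_site", path)
    keep <- tolower(tab[[columns[["primary_site"]]]]) == tolower(site_filter)
    tab <- tab[keep, , drop = FALSE]
  }
  res <- parse_hgvs_c_many(
    tab[[columns[["hgvs_c"]]]],
    gene_symbol = tab[[columns[["gene_symbol"]]]],
    transcript_id = col_or_blank(tab, columns["transcript_id"]),
    sample_id = col_or_blank(tab, columns["sample_id"]),
    source = "cosmic"
  )
  attach_report(res$variants, nrow(tab), res$rejects, rejects_path)
}

#' Read somatic variants from a MAF-style TSV
#'
#' Same contract as [read_cosmic_variants()], for MAF-dialect whole-exome
#' exports: `Hugo_Symbol` plus an HGVSc-bearing column. A transcript prefix
#' in the notation (`ENST...:c.242T>C`) is stripped before parsing.
#' `source` is set to `"wes"`.
#'
#' @inheritParams read_cosmic_variants
#' @param columns Field mapping, see [maf_columns()].
#' @return Coding-variant tibble with a [parse_report()] attribute.
#' @export
read_maf_variants <- function(path, columns = maf_columns(),
                              rejects_path = NULL) {
  tab <- read_tsv_quiet(path)
  require_columns(tab, columns, c("gene_symbol", "hgvs_c"), path)
  hgvs <- sub("^[^:]+:", "", tab[[columns[["hgvs_c"]]]])
  res <- parse_hgvs_c_many(
    hgvs,
    gene_symbol = tab[[columns[["gene_symbol"]]]],
    transcript_id = col_or_blank(tab, columns["transcript_id"]),
    sample_id = col_or_blank(tab, columns["sample_id"]),
    source = "wes"
  )
  attach_report(res$variants, nrow(tab), res$rejects, rejects_path)
}

# Strip search-engine modification annotations and normalize case:
# "SLFDASHM[15.9949]L" or "n[42]SLFDASHML" -> "SLFDASHML".
strip_peptide_mods <- function(peptide) {
  x <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", peptide)
  toupper(gsub("[^A-Za-z]", "", x))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a peptide-spectrum-match table
#'
#' Reads an MSFragger-psm.tsv-like tab-separated table of peptide
#' identifications. Modification annotations are stripped from the peptide
#' string at parse time, so downstream comparisons operate on bare
#' sequences. Rows with non-numeric scores or residues outside the
#' 20-letter alphabet are rejected with their row numbers (see
#' [parse_report()]).
#'
#' @param path TSV path.
#' @param columns Named mapping for `peptide`, `hyperscore`, `intensity`,
#'   `protein_ids`, `spectrum_id`, `replicate`. Only `peptide` and
#'   `hyperscore` must exist in the file; the others default to blank/zero.
#' @param rejects_path Optional sidecar TSV of rejected rows.
#' @return Tibble `peptide`, `hyperscore`, `intensity`, `protein_ids`
#'   (list column, split on `;` or `,`), `spectrum_id`, `replicate`.
#' @export
read_psm_table <- function(path,
                           columns = c(peptide = "Peptide",
                                       hyperscore = "Hyperscore",
                                       intensity = "Intensity",
                                       protein_ids = "Mapped Proteins",
                                       spectrum_id = "Spectrum",
                                       replicate = "Replicate"),
                           rejects_path = NULL) {
  tab <- read_tsv_quiet(path)
  require_columns(tab, columns, c("peptide", "hyperscore"), path)
  peptide <- strip_peptide_mods(tab[[columns[["peptide"]]]])
  hyper <- suppressWarnings(as.numeric(tab[[columns[["hyperscore"]]]]))
  inten_raw <- col_or_blank(tab, columns["intensity"])
  inten <- suppressWarnings(as.numeric(ifelse(nzchar(inten_raw), inten_raw, "0")))
  bad_pep <- !nzchar(peptide) |
    !vapply(strsplit(peptide, ""), function(ch) all(ch %in% AA20), TRUE)
  bad_num <- is.na(hyper) | is.na(inten) | inten < 0
  bad <- bad_pep | bad_num
  rejects <- tibble(
    row = which(bad),
    peptide = tab[[columns[["peptide"]]]][bad],
    reason = ifelse(bad_pep[bad], "peptide outside 20-letter alphabet",
                    "non-numeric or negative score/intensity")
  )
  ids <- tibble(
    peptide = peptide[!bad],
    hyperscore = hyper[!bad],
    intensity = inten[!bad],
    protein_ids = strsplit(col_or_blank(tab, columns["protein_ids"])[!bad],
                           "\\s*[;,]\\s*"),
    spectrum_id = col_or_blank(tab, columns["spectrum_id"])[!bad],
    replicate = col_or_blank(tab, columns["replicate"])[!bad]
  )
  attach_report(ids, nrow(tab), rejects, rejects_path)
}

#' Read a binding-prediction rank table
#'
#' Reads a NetMHCpan-output-like tab-separated table of peptide/allele
#' elution percent ranks. Rows with non-numeric or negative ranks are
#' rejected with their row numbers.
#'
#' @param path TSV path.
#' @param columns Named mapping for `peptide`, `allele`, `percent_rank`.
#' @param rejects_path Optional sidecar TSV of rejected rows.
#' @return Tibble `peptide`, `allele`, `percent_rank`, with a
#'   [parse_report()] attribute.
#' @export
read_rank_table <- function(path,
                            columns = c(peptide = "Peptide",
                                        allele = "Allele",
                                        percent_rank = "Rank"),
                            rejects_path = NULL) {
  tab <- read_tsv_quiet(path)
  require_columns(tab, columns, c("peptide", "percent_rank"), path)
  pr <- suppressWarnings(as.numeric(tab[[columns[["percent_rank"]]]]))
  bad <- is.na(pr) | !is.finite(pr) | pr < 0
  rejects <- tibble(
    row = which(bad),
    peptide = tab[[columns[["peptide"]]]][bad],
    reason = "non-numeric or negative percent rank"
  )
  rows <- tibble(
    peptide = strip_peptide_mods(tab[[columns[["peptide"]]]])[!bad],
    allele = col_or_blank(tab, columns["allele"])[!bad],
    percent_rank = pr[!bad]
  )
  attach_report(rows, nrow(tab), rejects, rejects_path)
}
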