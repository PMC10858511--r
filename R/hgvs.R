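new_coding_variant <- function(kind, start, end, ref_allele, alt_allele,
                               hgvs_c, gene_symbol = "", transcript_id = "",
                               sample_id = "", source = "other") {
  tibble(
    gene_symbol = gene_symbol, transcript_id = transcript_id,
    kind = kind, start = as.integer(start), end = as.integer(end),
    ref_allele = ref_allele, alt_allele = alt_allele,
    hgvs_c = hgvs_c, sample_id = sample_id, source = source
  )
}

#' Parse HGVS coding (c.) notation
#'
#' Parses an HGVS coding-DNA description into a one-row coding-variant
#' tibble with 1-based inclusive coding coordinates. Whitespace inside the
#' notation (as in the common rendering `"c.242 T > C"`) is stripped before
#' parsing. Supported forms:
#'
#' * substitution `c.242T>C`
#' * deletion `c.5del`, `c.5delA`, `c.5_7del`, `c.5_7delACG`
#' * insertion `c.100_101insA` (between two flanking positions)
#' * deletion-insertion `c.100delinsTT`, `c.100_102delinsAT`
#'
#' Intronic or UTR coordinates (`c.88+1G>A`, `c.-12A>G`, `c.*52del`) are
#' outside the coding coordinate system used here and raise an
#' unsupported-coordinate error.
#'
#' @param notation HGVS c. string (scalar).
#' @param gene_symbol,transcript_id,sample_id,source Optional provenance
#'   carried into the returned row. `source` is one of `"cosmic"`, `"wes"`,
#'   `"other"`.
#' @return One-row tibble with columns `gene_symbol`, `transcript_id`,
#'   `kind` (`substitution`/`insertion`/`deletion`/`delins`), `start`,
#'   `end`, `ref_allele`, `alt_allele`, `hgvs_c`, `sample_id`, `source`.
#' @seealso [format_hgvs_c()] for the inverse.
#' @export
#' @examples
#' parse_hgvs_c("c.242 T > C")
#' parse_hgvs_c("c.100_101insA")
parse_hgvs_c <- function(notation, gene_symbol = "", transcript_id = "",
                         sample_id = "", source = "other") {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    stop_neodb("notation must be a single string", "neodb_parse_error")
  }
  raw <- notation
  x <- gsub("\\s+", "", notation)
  if (!startsWith(x, "c.")) {
    stop_neodb(sprintf("'%s' does not start with 'c.'", raw),
               "neodb_parse_error")
  }
  body <- substr(x, 3L, nchar(x))
  if (!nzchar(body)) {
    stop_neodb(sprintf("'%s' has an empty description after 'c.'", raw),
               "neodb_parse_error")
  }
  if (grepl("^[-*]", body) || grepl("[0-9][-+][0-9]", body) ||
      grepl("_[-*]", body)) {
    stop_neodb(
      sprintf("'%s' uses intronic/UTR offsets, which are outside coding coordinates", raw),
      "neodb_coordinate_error"
    )
  }

  m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(new_coding_variant("substitution", pos, pos, m[3], m[4], raw,
                              gene_symbol, transcript_id, sample_id, source))
  }
  m <- regmatches(body, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    if (e != s + 1L) {
      stop_neodb(
        sprintf("'%s': insertion positions must be the two flanking bases", raw),
        "neodb_parse_error"
      )
    }
    return(new_coding_variant("insertion", s, e, "", m[4], raw,
                              gene_symbol, transcript_id, sample_id, source))
  }
  m <- regmatches(body,
                  regexec("^([0-9]+)(?:_([0-9]+))?delins([ACGT]+)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    if (e < s) {
      stop_neodb(sprintf("'%s': end precedes start", raw), "neodb_parse_error")
    }
    return(new_coding_variant("delins", s, e, "", m[4], raw,
                              gene_symbol, transcript_id, sample_id, source))
  }
  m <- regmatches(body,
                  regexec("^([0-9]+)(?:_([0-9]+))?del([ACGT]*)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    if (e < s) {
      stop_neodb(sprintf("'%s': end precedes start", raw), "neodb_parse_error")
    }
    if (nzchar(m[4]) && nchar(m[4]) != e - s + 1L) {
      stop_neodb(
        sprintf("'%s': deleted sequence length does not match the range", raw),
        "neodb_parse_error"
      )
    }
    return(new_coding_variant("deletion", s, e, m[4], "", raw,
                              gene_symbol, transcript_id, sample_id, source))
  }
  stop_neodb(
    sprintf("cannot parse HGVS c. description '%s' (offending token '%s')",
            raw, body),
    "neodb_parse_error"
  )
}

#' Format a coding variant back to canonical HGVS c. notation
#'
#' Inverse of [parse_hgvs_c()] up to whitespace: `parse_hgvs_c(format_hgvs_c(v))`
#' reproduces `v`'s coordinates, alleles and kind.
#'
#' @param variants Coding-variant tibble (any number of rows).
#' @return Character vector of canonical notations, e.g. `"c.242T>C"`.
#' @export
format_hgvs_c <- function(variants) {
  stopifnot(is.data.frame(variants))
  purrr::pmap_chr(
    variants[c("kind", "start", "end", "ref_allele", "alt_allele")],
    function(kind, start, end, ref_allele, alt_allele) {
      switch(kind,
        substitution = sprintf("c.%d%s>%s", start, ref_allele, alt_allele),
        insertion = sprintf("c.%d_%dins%s", start, end, alt_allele),
        deletion = if (end == start) {
          sprintf("c.%ddel%s", start, ref_allele)
        } else {
          sprintf("c.%d_%ddel%s", start, end, ref_allele)
        },
        delins = if (end == start) {
          sprintf("c.%ddelins%s", start, alt_allele)
        } else {
          sprintf("c.%d_%ddelins%s", start, end, alt_allele)
        },
        stop_neodb(sprintf("unknown variant kind '%s'", kind),
                   "neodb_domain_error")
      )
    }
  )
}

# Parse a vector of notations, tolerating failures. Returns list(variants,
# rejects) where rejects is a tibble(row, notation, reason).
parse_hgvs_c_many <- function(notations, gene_symbol = "",
                              transcript_id = "", sample_id = "",
                              source = "other") {
  n <- length(notations)
  gene_symbol <- rep_len(gene_symbol, n)
  transcript_id <- rep_len(transcript_id, n)
  sample_id <- rep_len(sample_id, n)
  out <- vector("list", n)
  rej <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      parse_hgvs_c(notations[i], gene_symbol[i], transcript_id[i],
                   sample_id[i], source),
      neodb_error = function(e) e
    )
    if (inherits(res, "error")) {
      rej[[i]] <- tibble(row = i, notation = notations[i] %||% NA_character_,
                         reason = conditionMessage(res))
    } else {
      out[[i]] <- res
    }
  }
  list(
    variants = dplyr::bind_rows(out),
    rejects = dplyr::bind_rows(rej)
  )
}
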