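#' Standard codon table
#'
#' The standard genetic code (NCBI translation table 1) as a named character
#' vector mapping each of the 64 codons to a one-letter amino acid, with
#' `"*"` marking stop codons.
#'
#' @return Named character vector of length 64.
#' @seealso [read_codon_table()] to load an alternative table from file.
#' @export
#' @examples
#' default_codon_table()[["ATG"]]
default_codon_table <- function() {
  c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
}

#' Load a codon table from a plain-text file
#'
#' Reads a whitespace-separated two-column file (codon, one-letter amino
#' acid or `*` for stop) and validates that exactly the 64 codons are
#' present.
#'
#' @param path Path to the table file. Lines starting with `#` are ignored.
#' @return Named character vector of length 64, as [default_codon_table()].
#' @export
read_codon_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop_neodb(
      sprintf("codon table line %d is not '<codon> <aa>'", which(bad)[1]),
      "neodb_format_error"
    )
  }
  tab <- setNames(
    toupper(vapply(parts, `[[`, "", 2L)),
    toupper(vapply(parts, `[[`, "", 1L))
  )
  if (length(tab) != 64 || anyDuplicated(names(tab)) ||
      !all(grepl("^[ACGT]{3}$", names(tab)))) {
    stop_neodb("codon table must define each of the 64 ACGT codons once",
               "neodb_format_error")
  }
  tab
}

#' Codon index of a coding-nucleotide position
#'
#' Maps a 1-based coding-nucleotide position to the 1-based index of the
#' codon (equivalently, protein residue) it falls in:
#' `floor((pos - 1) / 3) + 1`. Position 242 of a CDS, for example, sits in
#' codon 81.
#'
#' @param coding_position Integer vector of 1-based coding positions.
#' @return Integer vector of codon indices.
#' @export
#' @examples
#' codon_index(242)  # 81
#' codon_index(c(1, 3, 4, 1795))
codon_index <- function(coding_position) {
  if (!is.numeric(coding_position) || any(!is.finite(coding_position)) ||
      any(coding_position < 1) || any(coding_position != floor(coding_position))) {
    stop_neodb("coding positions must be positive integers",
               "neodb_domain_error")
  }
  as.integer((coding_position - 1) %/% 3 + 1)
}

# Translate a coding nucleotide string codon-by-codon. Trailing partial
# codons are ignored. Returns the amino-acid string including any "*".
translate_nt <- function(nt, table = default_codon_table()) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(table[codons])
  if (anyNA(aa)) {
    stop_neodb(
      sprintf("untranslatable codon '%s' (ambiguity codes are not allowed)",
              codons[which(is.na(aa))[1]]),
      "neodb_malformed_cds"
    )
  }
  paste(aa, collapse = "")
}

# Translate until (and excluding) the first stop. Returns list(protein,
# stopped) where stopped says whether a stop codon was reached.
translate_to_stop <- function(nt, table = default_codon_table()) {
  aa <- translate_nt(nt, table)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1L, stop_at - 1L), stopped = TRUE)
  } else {
    list(protein = aa, stopped = FALSE)
  }
}

# Validate a CDS for consequence calling: ACGT only, multiple of 3, starts
# with an initiator (ATG under the active table), ends with a stop, and has
# no internal stop.
validate_cds <- function(nt, table = default_codon_table()) {
  if (!is.character(nt) || length(nt) != 1L || is.na(nt) || nchar(nt) < 9) {
    stop_neodb("CDS must be a single nucleotide string of >= 3 codons",
               "neodb_malformed_cds")
  }
  if (grepl("[^ACGT]", nt)) {
    stop_neodb("CDS contains non-ACGT characters", "neodb_malformed_cds")
  }
  if (nchar(nt) %% 3 != 0) {
    stop_neodb("CDS length is not a multiple of 3", "neodb_malformed_cds")
  }
  aa <- translate_nt(nt, table)
  n_cod <- nchar(aa)
  if (substr(aa, 1, 1) != "M") {
    stop_neodb("CDS does not begin with an initiator codon",
               "neodb_malformed_cds")
  }
  if (substr(aa, n_cod, n_cod) != "*") {
    stop_neodb("CDS does not end with a stop codon", "neodb_malformed_cds")
  }
  if (grepl("*", substr(aa, 1, n_cod - 1), fixed = TRUE)) {
    stop_neodb("CDS contains an internal stop codon", "neodb_malformed_cds")
  }
  invisible(aa)
}
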