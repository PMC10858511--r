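WATER_MONO <- 18.0105646863

#' Monoisotopic residue mass table
#'
#' Monoisotopic masses (Da) of the 20 canonical amino acid residues
#' (i.e. amino acids minus water, as incorporated in a peptide chain).
#' Isoleucine and leucine are exactly equal (both C6H11NO), which is the
#' root of the I/L indistinguishability problem in tandem MS. The water
#' mass used to close a peptide is attached as the `"water"` attribute.
#'
#' @return Named numeric vector over the 20 residues.
#' @export
residue_masses <- function() {
  structure(
    c(G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
      V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
      I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
      K = 128.09496300, E = 129.04259308, M = 131.04048508, H = 137.05891185,
      F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294),
    water = WATER_MONO
  )
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water. Vectorized over peptides.
#'
#' @param seq Character vector of peptides (20-letter alphabet).
#' @param table Residue mass table, [residue_masses()] by default.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' peptide_mass("SLFDASHML")
peptide_mass <- function(seq, table = residue_masses()) {
  water <- attr(table, "water") %||% WATER_MONO
  vapply(seq, function(s) {
    if (is.na(s) || !nzchar(s)) {
      stop_neodb("peptides must be non-empty", "neodb_alphabet_error")
    }
    ch <- strsplit(s, "")[[1]]
    m <- table[ch]
    if (anyNA(m)) {
      stop_neodb(
        sprintf("unknown residue '%s' in '%s'", ch[which(is.na(m))[1]], s),
        "neodb_alphabet_error"
      )
    }
    sum(m) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' Flag mass-indistinguishable mutant/wild peptide pairs
#'
#' Screens a mutant peptide against its wild-type counterpart for the two
#' ways a mutant call can be a mass-identical re-reading of a wild
#' sequence: an exact isoleucine/leucine swap (`il_swap` — the two differ
#' only at positions where one has I and the other L), or any other
#' combination of substitutions leaving the total mass within `tolerance`
#' (`equal_mass_recombination`, e.g. GG vs N). Vectorized over pairs; the
#' mass delta (mutant minus wild) is always reported.
#'
#' @param mutant_pep,wild_pep Character vectors of equal length.
#' @param table Residue mass table.
#' @param tolerance Mass tolerance in Da; the 1e-4 default captures exact
#'   isobars only.
#' @return Tibble `peptide`, `counterpart`, `mass_delta`, `kind`
#'   (`il_swap` / `equal_mass_recombination` / `none`).
#' @export
#' @examples
#' flag_indistinguishable("SLFDAIHML", "SLFDALHML")
flag_indistinguishable <- function(mutant_pep, wild_pep,
                                   table = residue_masses(),
                                   tolerance = 1e-4) {
  stopifnot(length(mutant_pep) == length(wild_pep))
  delta <- peptide_mass(mutant_pep, table) - peptide_mass(wild_pep, table)
  kind <- purrr::map2_chr(mutant_pep, wild_pep, function(m, w) {
    if (m == w) return("none")
    if (nchar(m) == nchar(w)) {
      cm <- strsplit(m, "")[[1]]
      cw <- strsplit(w, "")[[1]]
      d <- cm != cw
      if (all(cm[d] %in% c("I", "L")) && all(cw[d] %in% c("I", "L"))) {
        return("il_swap")
      }
    }
    "pending"
  })
  kind[kind == "pending"] <-
    ifelse(abs(delta[kind == "pending"]) <= tolerance,
           "equal_mass_recombination", "none")
  tibble(peptide = mutant_pep, counterpart = wild_pep,
         mass_delta = delta, kind = kind)
}

# Precompute the mass of every residue singleton and ordered pair.
residue_unit_masses <- function(table = residue_masses()) {
  singles <- setNames(as.numeric(table[AA20]), AA20)
  pairs <- expand.grid(a = AA20, b = AA20, stringsAsFactors = FALSE)
  pair_seq <- paste0(pairs$a, pairs$b)
  doubles <- setNames(singles[pairs$a] + singles[pairs$b], pair_seq)
  c(singles, doubles)
}

#' Enumerate equal-mass local rewrites of a peptide
#'
#' Lists every single-residue or residue-pair substring of the peptide
#' that can be replaced by a *different* residue or residue pair of equal
#' mass (within `tolerance`): I<->L, GG<->N, GA/AG<->Q, and so on. These
#' are the local re-readings that tandem MS cannot resolve from precursor
#' mass alone.
#'
#' @param peptide A single peptide string.
#' @param table Residue mass table.
#' @param tolerance Mass tolerance in Da.
#' @param max_window 1 (single residues only) or 2 (residues and pairs).
#' @return Tibble `position` (1-based start of the rewritten substring),
#'   `original`, `replacement`, `mass_delta`.
#' @export
#' @examples
#' equal_mass_rewrites("NGG")
equal_mass_rewrites <- function(peptide, table = residue_masses(),
                                tolerance = 1e-4, max_window = 2L) {
  stopifnot(length(peptide) == 1L, max_window %in% c(1L, 2L))
  units <- residue_unit_masses(table)
  n <- nchar(peptide)
  out <- list()
  for (w in seq_len(max_window)) {
    if (n < w) break
    for (pos in seq_len(n - w + 1L)) {
      sub <- substr(peptide, pos, pos + w - 1L)
      if (is.na(units[sub])) {
        stop_neodb(sprintf("unknown residue(s) in '%s'", sub),
                   "neodb_alphabet_error")
      }
      cand <- units[abs(units - units[[sub]]) <= tolerance]
      cand <- cand[names(cand) != sub]
      if (max_window == 1L) cand <- cand[nchar(names(cand)) == 1L]
      if (length(cand)) {
        out[[length(out) + 1L]] <- tibble(
          position = pos, original = sub, replacement = names(cand),
          mass_delta = unname(cand - units[[sub]])
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(position = integer(), original = character(),
                  replacement = character(), mass_delta = numeric())
  }
  res
}
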