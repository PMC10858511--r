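STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a synthetic CDS
#'
#' Builds a random coding sequence: an ATG initiator, `n_codons - 2`
#' internal codons drawn uniformly from the 61 sense codons (so the frame
#' contains no internal stop by construction), a terminal stop codon, and
#' a random 3' downstream context used for stop-loss read-through.
#' Deterministic per seed.
#'
#' @param n_codons Total codons including initiator and stop (>= 3).
#' @param seed Integer seed.
#' @param context_nt Length of the downstream nucleotide context.
#' @param id Record id.
#' @return One-row sequence tibble: `id`, `description`, `residues`,
#'   `downstream_context`.
#' @export
make_cds <- function(n_codons, seed, context_nt = 60L,
                     id = sprintf("cds_%d", seed)) {
  if (n_codons < 3) {
    stop_neodb("a CDS needs at least 3 codons (start, one sense, stop)",
               "neodb_domain_error")
  }
  with_seed(seed, {
    sense <- setdiff(names(default_codon_table()), STOP_CODONS)
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    ctx <- paste(sample(c("A", "C", "G", "T"), context_nt, replace = TRUE),
                 collapse = "")
    tibble(
      id = id,
      description = sprintf("synthetic CDS, %d codons, seed %d", n_codons, seed),
      residues = paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = ""),
      downstream_context = ctx
    )
  })
}

# ---- brute-force oracle ---------------------------------------------------
# The ledger's ground truth is computed by editing the CDS with plain
# character-vector surgery and re-translating the whole sequence with the
# genetic code shipped in Biostrings — a code path fully independent of the
# consequence engine.

oracle_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

oracle_chars <- function(nt) strsplit(nt, "")[[1]]

oracle_aa <- function(chars, map) {
  n <- length(chars) %/% 3L
  if (n == 0L) return(character())
  codons <- vapply(seq_len(n), function(i) {
    paste(chars[(3L * i - 2L):(3L * i)], collapse = "")
  }, "")
  unname(map[codons])
}

oracle_edit <- function(chars, kind, s, e, alt) {
  alt_ch <- if (nzchar(alt)) oracle_chars(alt) else character()
  switch(kind,
    substitution = { x <- chars; x[s:e] <- alt_ch; x },
    deletion = chars[-(s:e)],
    insertion = append(chars, alt_ch, after = s),
    delins = append(chars[-(s:e)], alt_ch, after = s - 1L)
  )
}

oracle_first_diff <- function(mut, wild) {
  n <- min(length(mut), length(wild))
  if (n > 0L) {
    d <- which(mut[seq_len(n)] != wild[seq_len(n)])
    if (length(d)) return(d[1])
  }
  n + 1L
}

oracle_trim <- function(mut, wild) {
  a <- oracle_first_diff(mut, wild) - 1L
  limit <- min(length(mut), length(wild)) - a
  b <- 0L
  while (b < limit &&
         mut[length(mut) - b] == wild[length(wild) - b]) {
    b <- b + 1L
  }
  list(a = a, b = b)
}

# Full re-translation consequence call; same declared conventions as the
# engine, computed from scratch.
oracle_consequence <- function(cds_nt, ctx, kind, s, e, ref, alt) {
  map <- oracle_code()
  ch <- oracle_chars(cds_nt)
  wild_aa <- oracle_aa(ch, map)
  wild <- wild_aa[seq_len(which(wild_aa == "*")[1] - 1L)]
  lw <- length(wild)

  done <- function(class, position, hgvs_p, mut, tail) {
    list(class = class, position = as.integer(position), hgvs_p = hgvs_p,
         mutant_protein = paste(mut, collapse = ""), novel_tail = as.integer(tail))
  }

  if (if (kind == "insertion") s <= 2L else s <= 3L) {
    return(done("translation_start_site", 1L, "p.M1?", character(), 0L))
  }
  edited <- oracle_edit(ch, kind, s, e, alt)
  net <- length(edited) - length(ch)

  if (net != 0L) {
    full <- oracle_aa(c(edited, oracle_chars(ctx)), map)
    stop_i <- which(full == "*")[1]
    stopped <- !is.na(stop_i)
    mut <- if (stopped) full[seq_len(stop_i - 1L)] else full
    lm <- length(mut)
    if (net %% 3L != 0L) {
      cls <- if (net > 0L) "frameshift_insertion" else "frameshift_deletion"
      p <- oracle_first_diff(mut, wild)
      if (p > lm) {
        r <- if (p <= lw) wild[p] else "*"
        return(done(cls, p, paste0("p.", r, p, "*"), mut, 0L))
      }
      r <- if (p <= lw) wild[p] else "*"
      n_fs <- if (stopped) as.character(lm - p + 2L) else "?"
      return(done(cls, p, paste0("p.", r, p, mut[p], "fs*", n_fs),
                  mut, lm - p + 1L))
    }
    cls <- if (net > 0L) "inframe_insertion" else "inframe_deletion"
    tr <- oracle_trim(mut, wild)
    w_s <- tr$a + 1L; w_e <- lw - tr$b
    m_s <- tr$a + 1L; m_e <- lm - tr$b
    ref_res <- if (w_e >= w_s) paste(wild[w_s:w_e], collapse = "") else ""
    alt_res <- if (m_e >= m_s) paste(mut[m_s:m_e], collapse = "") else ""
    at <- function(i) if (i <= lw) wild[i] else "*"
    hp <- if (cls == "inframe_deletion" && !nzchar(alt_res)) {
      if (w_e == w_s) paste0("p.", at(w_s), w_s, "del")
      else paste0("p.", at(w_s), w_s, "_", at(w_e), w_e, "del")
    } else if (cls == "inframe_insertion" && !nzchar(ref_res)) {
      paste0("p.", at(w_s - 1L), w_s - 1L, "_", at(w_s), w_s, "ins", alt_res)
    } else {
      paste0("p.", at(w_s), w_s, "_", at(max(w_s, w_e)), max(w_s, w_e),
             "delins", alt_res)
    }
    return(done(cls, w_s, hp, mut, 0L))
  }

  aa_full <- oracle_aa(edited, map)
  n_cod <- length(aa_full)
  stop_i <- which(aa_full == "*")[1]
  if (is.na(stop_i)) {
    ctx_aa <- oracle_aa(oracle_chars(ctx), map)
    ctx_stop <- which(ctx_aa == "*")[1]
    tail_aa <- if (is.na(ctx_stop)) ctx_aa else head(ctx_aa, ctx_stop - 1L)
    mut <- c(aa_full, tail_aa)
    ext <- if (is.na(ctx_stop)) "?" else as.character(length(tail_aa) + 1L)
    return(done("nonstop", n_cod,
                paste0("p.*", n_cod, aa_full[n_cod], "ext*", ext),
                mut, length(tail_aa)))
  }
  if (stop_i < n_cod) {
    return(done("nonsense", stop_i,
                paste0("p.", wild[stop_i], stop_i, "*"),
                aa_full[seq_len(stop_i - 1L)], 0L))
  }
  mut <- aa_full[seq_len(n_cod - 1L)]
  diffs <- which(mut != wild)
  if (!length(diffs)) {
    ci <- (s - 1L) %/% 3L + 1L
    hp <- if (kind == "substitution") paste0("p.", wild[ci], ci, "=") else "p.(=)"
    return(done("synonymous", ci, hp, mut, 0L))
  }
  p1 <- diffs[1]; p2 <- diffs[length(diffs)]
  hp <- if (p1 == p2) {
    paste0("p.", wild[p1], p1, mut[p1])
  } else {
    paste0("p.", wild[p1], p1, "_", wild[p2], p2, "delins",
           paste(mut[p1:p2], collapse = ""))
  }
  done("missense", p1, hp, mut, 0L)
}

# ---- variant injection ----------------------------------------------------

propose_variant <- function(ch, L, class) {
  bases <- c("A", "C", "G", "T")
  rand_alt <- function(refbase) sample(setdiff(bases, refbase), 1L)
  switch(class,
    translation_start_site = {
      pos <- sample(1:3, 1L)
      list(kind = "substitution", s = pos, e = pos, ref = ch[pos],
           alt = rand_alt(ch[pos]))
    },
    nonstop = {
      pos <- sample((L - 2L):L, 1L)
      list(kind = "substitution", s = pos, e = pos, ref = ch[pos],
           alt = rand_alt(ch[pos]))
    },
    synonymous = ,
    missense = ,
    nonsense = {
      pos <- sample(4:(L - 3L), 1L)
      list(kind = "substitution", s = pos, e = pos, ref = ch[pos],
           alt = rand_alt(ch[pos]))
    },
    inframe_insertion = {
      pos <- sample(3:(L - 3L), 1L)
      list(kind = "insertion", s = pos, e = pos + 1L, ref = "",
           alt = paste(sample(bases, 3L, replace = TRUE), collapse = ""))
    },
    frameshift_insertion = {
      pos <- sample(3:(L - 3L), 1L)
      n <- sample(1:2, 1L)
      list(kind = "insertion", s = pos, e = pos + 1L, ref = "",
           alt = paste(sample(bases, n, replace = TRUE), collapse = ""))
    },
    inframe_deletion = {
      s <- sample(4:(L - 5L), 1L)
      list(kind = "deletion", s = s, e = s + 2L,
           ref = paste(ch[s:(s + 2L)], collapse = ""), alt = "")
    },
    frameshift_deletion = {
      n <- sample(1:2, 1L)
      s <- sample(4:(L - 2L - n), 1L)
      list(kind = "deletion", s = s, e = s + n - 1L,
           ref = paste(ch[s:(s + n - 1L)], collapse = ""), alt = "")
    },
    stop_neodb(sprintf("unknown class '%s'", class), "neodb_domain_error")
  )
}

#' Inject variants of requested classes into a CDS
#'
#' Generates random coding variants whose true consequence classes match a
#' requested per-class mix, together with a ground-truth ledger computed
#' by the brute-force full-translation oracle (whole-CDS re-translation,
#' independent of the consequence engine). HGVS c. strings are emitted in
#' canonical form, so they round-trip through [parse_hgvs_c()].
#'
#' @param cds One-row sequence tibble from [make_cds()].
#' @param class_mix Named integer vector, e.g.
#'   `c(missense = 5, nonsense = 2)`; names from [mutation_classes()].
#' @param seed Integer seed.
#' @param gene_symbol,sample_id,source Provenance stamped on the variants.
#' @param max_tries Proposal attempts per requested variant.
#' @return List with `variants` (coding-variant tibble) and `ledger`
#'   (tibble: the variant fields plus `true_class`, `true_position`,
#'   `true_hgvs_p`, `true_mutant_protein`, `true_novel_tail`).
#' @export
inject_variants <- function(cds, class_mix, seed, gene_symbol = "GENE1",
                            sample_id = "S1", source = "cosmic",
                            max_tries = 2000L) {
  stopifnot(is.data.frame(cds), nrow(cds) == 1L)
  bad <- setdiff(names(class_mix), MUTATION_CLASSES)
  if (length(bad)) {
    stop_neodb(sprintf("unknown class(es) in mix: %s",
                       paste(bad, collapse = ", ")),
               "neodb_domain_error")
  }
  if (isTRUE(class_mix["nonstop"] > 1L)) {
    stop_neodb("at most one nonstop variant can be injected per CDS (one stop codon)",
               "neodb_domain_error")
  }
  nt <- cds$residues[[1]]
  ctx <- cds$downstream_context[[1]] %||% ""
  ch <- oracle_chars(nt)
  L <- length(ch)
  with_seed(seed, {
    rows <- list()
    ledger <- list()
    seen <- character()
    for (class in names(class_mix)) {
      for (k in seq_len(class_mix[[class]])) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          pr <- propose_variant(ch, L, class)
          v <- new_coding_variant(pr$kind, pr$s, pr$e, pr$ref, pr$alt, "",
                                  gene_symbol, cds$id[[1]], sample_id, source)
          v$hgvs_c <- format_hgvs_c(v)
          if (v$hgvs_c %in% seen) next
          truth <- oracle_consequence(nt, ctx, pr$kind, pr$s, pr$e,
                                      pr$ref, pr$alt)
          if (truth$class != class) next
          seen <- c(seen, v$hgvs_c)
          rows[[length(rows) + 1L]] <- v
          ledger[[length(ledger) + 1L]] <- dplyr::bind_cols(
            v,
            tibble(true_class = truth$class,
                   true_position = truth$position,
                   true_hgvs_p = truth$hgvs_p,
                   true_mutant_protein = truth$mutant_protein,
                   true_novel_tail = truth$novel_tail)
          )
          ok <- TRUE
          break
        }
        if (!ok) {
          stop_neodb(
            sprintf("could not realize a '%s' variant on this CDS in %d tries",
                    class, max_tries),
            "neodb_domain_error"
          )
        }
      }
    }
    list(variants = dplyr::bind_rows(rows), ledger = dplyr::bind_rows(ledger))
  })
}

#' Write a variant tibble as a COSMIC- or MAF-dialect TSV
#'
#' Emits fixture variant tables in the column layouts the readers expect
#' by default, for round-trip testing and CLI use.
#'
#' @param variants Coding-variant tibble.
#' @param path Output TSV path.
#' @param dialect `"cosmic"` or `"maf"`.
#' @param primary_site Site value for the COSMIC dialect.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path,
                                dialect = c("cosmic", "maf"),
                                primary_site = "liver") {
  dialect <- match.arg(dialect)
  tab <- if (dialect == "cosmic") {
    tibble(
      GENE_SYMBOL = variants$gene_symbol,
      TRANSCRIPT_ACCESSION = variants$transcript_id,
      MUTATION_CDS = variants$hgvs_c,
      COSMIC_SAMPLE_ID = variants$sample_id,
      PRIMARY_SITE = rep_len(primary_site, nrow(variants))
    )
  } else {
    tibble(
      Hugo_Symbol = variants$gene_symbol,
      Transcript_ID = variants$transcript_id,
      HGVSc = variants$hgvs_c,
      Tumor_Sample_Barcode = variants$sample_id
    )
  }
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write PSM / rank tibbles in the readers' default layouts
#'
#' @param psm,rank Tibbles shaped like [read_psm_table()] /
#'   [read_rank_table()] output.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  readr::write_tsv(tibble(
    Spectrum = psm$spectrum_id, Peptide = psm$peptide,
    Hyperscore = psm$hyperscore, Intensity = psm$intensity,
    `Mapped Proteins` = vapply(psm$protein_ids, paste, "", collapse = "; "),
    Replicate = psm$replicate
  ), path)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
write_rank_table <- function(rank, path) {
  readr::write_tsv(tibble(
    Peptide = rank$peptide, Allele = rank$allele, Rank = rank$percent_rank
  ), path)
  invisible(path)
}

sample_rank <- function(level) {
  switch(level,
    strong = runif(1, 0.002, 0.45),
    weak = runif(1, 0.5, 2.0),
    none = runif(1, 2.1, 40)
  )
}

#' Generate synthetic PSM and rank tables with a ground-truth ledger
#'
#' Samples 8-14-mer peptides from a built entry set and a reference
#' proteome: mutation-covering peptides (span intersecting the entry's
#' altered span, never an I/L-swap missense, never present in the
#' proteome), flank-only peptides, and plain reference peptides. Scores
#' are drawn from log-normal distributions in the range search engines
#' report (hyperscore ~ lnN(log 15, 0.25), intensity ~ lnN(log 1e6, 1)),
#' and each peptide gets an elution percent rank drawn inside the interval
#' of its declared binder level. The ledger records, per peptide, the
#' source entry, whether it covers a mutation, and the true binder level.
#'
#' @param entries Entry tibble ([deduplicate_entries()]).
#' @param consequences Consequence tibble the entries came from (used to
#'   avoid I/L-swap missense entries for covering peptides).
#' @param proteome Reference proteome tibble.
#' @param seed Integer seed.
#' @param n_cover,n_flank,n_ref Peptide counts per category.
#' @param out_dir Optional directory; when given, `psm.tsv` and `rank.tsv`
#'   are written there.
#' @return List with `psm`, `rank`, `ledger` tibbles.
#' @export
make_psm_and_rank_tables <- function(entries, consequences, proteome, seed,
                                     n_cover = 10L, n_flank = 5L,
                                     n_ref = 10L, out_dir = NULL) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0L)
  key <- paste(consequences$gene_symbol, consequences$hgvs_c)
  cons <- consequences[match(paste(entries$gene_symbol, entries$hgvs_c), key), ]
  il_swap_entry <- cons$mclass == "missense" &
    cons$ref_residues %in% c("I", "L") & cons$alt_residues %in% c("I", "L")
  cover_pool <- which(!is.na(il_swap_entry) & !il_swap_entry)
  if (!length(cover_pool)) {
    stop_neodb("no entries usable for mutation-covering peptides",
               "neodb_domain_error")
  }
  in_proteome <- function(p) {
    nrow(proteome) > 0 && any(stringi::stri_detect_fixed(proteome$residues, p))
  }
  with_seed(seed, {
    peps <- list()
    add <- function(peptide, entry_id, covers) {
      peps[[length(peps) + 1L]] <<-
        tibble(peptide = peptide, entry_id = entry_id,
               covers_mutation = covers)
    }
    taken <- character()
    draw <- function(n, fn) {
      got <- 0L
      tries <- 0L
      while (got < n && tries < 5000L) {
        tries <- tries + 1L
        res <- fn()
        if (is.null(res) || res$peptide %in% taken) next
        taken <<- c(taken, res$peptide)
        add(res$peptide, res$entry_id, res$covers)
        got <- got + 1L
      }
      if (got < n) {
        stop_neodb("could not sample the requested peptides from these entries",
                   "neodb_domain_error")
      }
    }
    draw(n_cover, function() {
      i <- sample(cover_pool, 1L)
      ent <- entries[i, ]
      len <- sample(8:14, 1L)
      if (nchar(ent$sequence) < len) return(NULL)
      lo <- max(1L, ent$span_start - len + 1L)
      hi <- min(ent$span_end, nchar(ent$sequence) - len + 1L)
      if (hi < lo) return(NULL)
      off <- sample(lo:hi, 1L)
      p <- substr(ent$sequence, off, off + len - 1L)
      if (in_proteome(p)) return(NULL)
      list(peptide = p, entry_id = ent$entry_id, covers = TRUE)
    })
    draw(n_flank, function() {
      i <- sample(nrow(entries), 1L)
      ent <- entries[i, ]
      len <- sample(8:14, 1L)
      hi <- ent$span_start - len
      if (hi < 1L) return(NULL)
      off <- sample(seq_len(hi), 1L)
      p <- substr(ent$sequence, off, off + len - 1L)
      list(peptide = p, entry_id = ent$entry_id, covers = FALSE)
    })
    if (n_ref > 0L && nrow(proteome) > 0L) {
      draw(n_ref, function() {
        i <- sample(nrow(proteome), 1L)
        resid <- proteome$residues[i]
        len <- sample(8:14, 1L)
        if (nchar(resid) < len) return(NULL)
        off <- sample(nchar(resid) - len + 1L, 1L)
        list(peptide = substr(resid, off, off + len - 1L),
             entry_id = NA_character_, covers = FALSE)
      })
    }
    led <- dplyr::bind_rows(peps)
    n <- nrow(led)
    psm <- tibble(
      peptide = led$peptide,
      hyperscore = round(rlnorm(n, log(15), 0.25), 2),
      intensity = round(rlnorm(n, log(1e6), 1), 1),
      protein_ids = as.list(ifelse(is.na(led$entry_id), "sp|REF|UNKNOWN",
                                   led$entry_id)),
      spectrum_id = sprintf("spec_%04d", seq_len(n)),
      replicate = sample(c("R1", "R2", "R3"), n, replace = TRUE)
    )
    alleles <- c("HLA-A*02:01", "HLA-A*24:02", "HLA-B*51:08", "HLA-C*16:02")
    level <- sample(c("strong", "weak", "none"), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
    rank <- tibble(
      peptide = led$peptide,
      allele = sample(alleles, n, replace = TRUE),
      percent_rank = round(vapply(level, sample_rank, 0), 3)
    )
    led$true_level <- level
    if (!is.null(out_dir)) {
      write_psm_table(psm, file.path(out_dir, "psm.tsv"))
      write_rank_table(rank, file.path(out_dir, "rank.tsv"))
      readr::write_tsv(led, file.path(out_dir, "ledger.tsv"))
    }
    list(psm = psm, rank = rank, ledger = led)
  })
}
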