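net_length_change <- function(kind, start, end, ref_allele, alt_allele) {
  switch(kind,
    substitution = 0L,
    insertion = nchar(alt_allele),
    deletion = -(end - start + 1L),
    delins = nchar(alt_allele) - (end - start + 1L),
    stop_neodb(sprintf("unknown variant kind '%s'", kind), "neodb_domain_error")
  )
}

resolve_cds <- function(cds) {
  if (is.data.frame(cds)) {
    stopifnot(nrow(cds) == 1L, "residues" %in% names(cds))
    ctx <- if ("downstream_context" %in% names(cds)) {
      cds$downstream_context[[1]] %||% ""
    } else ""
    list(residues = cds$residues[[1]], context = ifelse(is.na(ctx), "", ctx))
  } else {
    list(residues = cds, context = "")
  }
}

#' Apply a coding variant to a CDS
#'
#' Edits the coding nucleotide sequence according to the variant:
#' substitutions and deletion-insertions replace the `[start, end]` bases,
#' deletions remove them, and insertions place the alternate allele after
#' `start` (between the two flanking bases of `c.s_(s+1)ins`). When the
#' variant carries a reference allele, the CDS is checked against it and a
#' mismatch is a hard error reporting observed vs expected.
#'
#' @param cds CDS as a nucleotide string or a one-row sequence tibble (see
#'   [read_fasta()]).
#' @param variant One-row coding-variant tibble (see [parse_hgvs_c()]).
#' @return The mutated coding sequence (character scalar).
#' @export
apply_variant <- function(cds, variant) {
  stopifnot(is.data.frame(variant), nrow(variant) == 1L)
  nt <- resolve_cds(cds)$residues
  L <- nchar(nt)
  s <- variant$start; e <- variant$end
  kind <- variant$kind
  if (e > L || s > L) {
    stop_neodb(
      sprintf("variant %s lies beyond the CDS end (%d nt)",
              variant$hgvs_c, L),
      "neodb_coordinate_error"
    )
  }
  ref <- variant$ref_allele
  if (kind %in% c("substitution", "deletion") && nzchar(ref)) {
    observed <- substr(nt, s, e)
    if (observed != ref) {
      stop_neodb(
        sprintf("reference allele mismatch at c.%d: observed '%s', expected '%s'",
                s, observed, ref),
        "neodb_ref_mismatch",
        observed = observed, expected = ref
      )
    }
  }
  alt <- variant$alt_allele
  switch(kind,
    substitution = ,
    delins = paste0(substr(nt, 1L, s - 1L), alt, substr(nt, e + 1L, L)),
    deletion = paste0(substr(nt, 1L, s - 1L), substr(nt, e + 1L, L)),
    insertion = paste0(substr(nt, 1L, s), alt, substr(nt, s + 1L, L))
  )
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ca <- strsplit(substr(a, 1, n), "")[[1]]
  cb <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(ca != cb)
  if (length(d)) d[1] - 1L else n
}

common_suffix_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n == 0) return(0L)
  ca <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  cb <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  d <- which(ca != cb)
  if (length(d)) d[1] - 1L else n
}

consequence_row <- function(variant, mclass, protein_start, protein_end,
                            ref_residues, alt_residues, hgvs_p,
                            mutant_protein, novel_tail_length,
                            mut_span_start, mut_span_end) {
  tibble(
    gene_symbol = variant$gene_symbol, transcript_id = variant$transcript_id,
    hgvs_c = variant$hgvs_c, kind = variant$kind, mclass = mclass,
    protein_start = as.integer(protein_start),
    protein_end = as.integer(protein_end),
    ref_residues = ref_residues, alt_residues = alt_residues,
    hgvs_p = hgvs_p, mutant_protein = mutant_protein,
    novel_tail_length = as.integer(novel_tail_length),
    mut_span_start = as.integer(mut_span_start),
    mut_span_end = as.integer(mut_span_end),
    sample_id = variant$sample_id, source = variant$source
  )
}

#' Call the protein-level consequence of a coding variant
#'
#' Applies the variant to the CDS, translates, and classifies the effect
#' into one of the nine consequence classes (see [mutation_classes()]),
#' emitting HGVS p. notation, the full (stop-trimmed) mutant protein, and
#' the altered span in mutant-protein coordinates used downstream for
#' windowed database entries.
#'
#' Classification rules:
#' * any variant altering the initiator codon -> `translation_start_site`
#'   (no product is modeled; downstream re-initiation is not);
#' * a substitution creating an internal stop -> `nonsense`;
#' * a substitution abolishing the terminal stop -> `nonstop`; translation
#'   continues into `downstream_context` when available, and
#'   `novel_tail_length` counts the context residues actually appended;
#' * an indel with net length change divisible by 3 -> in-frame
#'   insertion/deletion; otherwise frameshift, translating the shifted
#'   frame to its first stop;
#' * a substitution changing exactly one residue -> `missense`; changing
#'   none -> `synonymous`.
#'
#' The CDS must begin with an initiator codon, end with a stop, contain no
#' internal stop and no ambiguity codes; violations raise a malformed-CDS
#' error.
#'
#' @param cds CDS string or one-row sequence tibble; a `downstream_context`
#'   column supplies 3' context for stop-loss read-through.
#' @param variant One-row coding-variant tibble.
#' @param codon_table Codon table, [default_codon_table()] by default.
#' @param downstream_context Optional 3' nucleotide context, overriding the
#'   tibble column.
#' @return One-row tibble with `mclass`, `protein_start`, `protein_end`,
#'   `ref_residues`, `alt_residues`, `hgvs_p`, `mutant_protein`,
#'   `novel_tail_length`, the altered span in mutant coordinates
#'   (`mut_span_start`, `mut_span_end`) and the variant's provenance
#'   columns.
#' @export
call_consequence <- function(cds, variant, codon_table = default_codon_table(),
                             downstream_context = NULL) {
  stopifnot(is.data.frame(variant), nrow(variant) == 1L)
  res <- resolve_cds(cds)
  nt <- res$residues
  ctx <- downstream_context %||% res$context
  if (is.na(ctx)) ctx <- ""
  wild_aa <- validate_cds(nt, codon_table)
  n_cod <- nchar(wild_aa)
  wild_prot <- substr(wild_aa, 1L, n_cod - 1L)
  len_w <- n_cod - 1L

  mut_cds <- apply_variant(nt, variant)
  kind <- variant$kind
  net <- net_length_change(kind, variant$start, variant$end,
                           variant$ref_allele, variant$alt_allele)
  overlaps_codon1 <- if (kind == "insertion") variant$start <= 2L
                     else variant$start <= 3L

  # Start-loss: the initiator can no longer be translated as such. ATG is
  # the unique Met codon, so any edit touching codon 1 qualifies.
  if (overlaps_codon1) {
    return(consequence_row(variant, "translation_start_site", 1L, 1L,
                           "M", "", "p.M1?", "", 0L, NA_integer_, NA_integer_))
  }

  if (kind != "substitution" && net != 0L) {
    if (net %% 3L != 0L) {
      mclass <- if (net > 0L) "frameshift_insertion" else "frameshift_deletion"
      tr <- translate_to_stop(paste0(mut_cds, ctx), codon_table)
      mut_prot <- tr$protein
      len_m <- nchar(mut_prot)
      p <- common_prefix_len(mut_prot, wild_prot) + 1L
      if (p > len_m) {
        # shifted frame hit a stop immediately: nonsense-style notation,
        # frameshift class retained
        ref <- if (p <= len_w) substr(wild_prot, p, p) else "*"
        anchor <- max(1L, len_m)
        return(consequence_row(variant, mclass, p, p, ref, "*",
                               sprintf("p.%s%d*", ref, p), mut_prot, 0L,
                               anchor, anchor))
      }
      ref <- if (p <= len_w) substr(wild_prot, p, p) else "*"
      alt <- substr(mut_prot, p, p)
      fs_n <- if (tr$stopped) as.character(len_m - p + 2L) else "?"
      return(consequence_row(variant, mclass, p, p, ref, alt,
                             sprintf("p.%s%d%sfs*%s", ref, p, alt, fs_n),
                             mut_prot, len_m - p + 1L, p, len_m))
    }
    # in-frame indel
    mclass <- if (net > 0L) "inframe_insertion" else "inframe_deletion"
    tr <- translate_to_stop(paste0(mut_cds, ctx), codon_table)
    mut_prot <- tr$protein
    len_m <- nchar(mut_prot)
    a <- common_prefix_len(mut_prot, wild_prot)
    b <- common_suffix_len(mut_prot, wild_prot, min(len_m, len_w) - a)
    w_s <- a + 1L; w_e <- len_w - b
    m_s <- a + 1L; m_e <- len_m - b
    ref_res <- if (w_e >= w_s) substr(wild_prot, w_s, w_e) else ""
    alt_res <- if (m_e >= m_s) substr(mut_prot, m_s, m_e) else ""
    hgvs_p <- inframe_hgvs_p(mclass, wild_prot, len_w, w_s, w_e,
                             ref_res, alt_res)
    span <- if (m_e >= m_s) c(m_s, m_e) else rep(max(1L, min(m_s, len_m)), 2L)
    return(consequence_row(variant, mclass, w_s, max(w_s, w_e),
                           ref_res, alt_res, hgvs_p, mut_prot, 0L,
                           span[1], span[2]))
  }

  # substitution, or a balanced delins: codon count is preserved
  mut_aa <- translate_nt(mut_cds, codon_table)
  stop_at <- regexpr("*", mut_aa, fixed = TRUE)
  if (stop_at < 0) {
    # terminal stop lost: read through into downstream context
    ctx_tr <- if (nzchar(ctx)) translate_to_stop(ctx, codon_table)
              else list(protein = "", stopped = FALSE)
    mut_prot <- paste0(mut_aa, ctx_tr$protein)
    tail_len <- nchar(ctx_tr$protein)
    new_res <- substr(mut_aa, n_cod, n_cod)
    ext_n <- if (ctx_tr$stopped) as.character(tail_len + 1L) else "?"
    return(consequence_row(variant, "nonstop", n_cod, n_cod, "*", new_res,
                           sprintf("p.*%d%sext*%s", n_cod, new_res, ext_n),
                           mut_prot, tail_len, n_cod, nchar(mut_prot)))
  }
  if (stop_at < n_cod) {
    p <- as.integer(stop_at)
    ref <- substr(wild_prot, p, p)
    anchor <- max(1L, p - 1L)
    return(consequence_row(variant, "nonsense", p, p, ref, "*",
                           sprintf("p.%s%d*", ref, p),
                           substr(mut_aa, 1L, p - 1L), 0L, anchor, anchor))
  }
  mut_prot <- substr(mut_aa, 1L, n_cod - 1L)
  if (mut_prot == wild_prot) {
    ci <- if (kind == "substitution") codon_index(variant$start)
          else codon_index(variant$start)
    res_i <- if (ci <= len_w) substr(wild_prot, ci, ci) else "*"
    hgvs_p <- if (kind == "substitution") sprintf("p.%s%d=", res_i, ci)
              else "p.(=)"
    return(consequence_row(variant, "synonymous", ci, ci, res_i, res_i,
                           hgvs_p, mut_prot, 0L, ci, ci))
  }
  a <- common_prefix_len(mut_prot, wild_prot)
  b <- common_suffix_len(mut_prot, wild_prot, len_w - a)
  w_s <- a + 1L; w_e <- len_w - b
  ref_res <- substr(wild_prot, w_s, w_e)
  alt_res <- substr(mut_prot, w_s, w_e)
  hgvs_p <- if (nchar(ref_res) == 1L) {
    sprintf("p.%s%d%s", ref_res, w_s, alt_res)
  } else {
    sprintf("p.%s%d_%s%ddelins%s", substr(ref_res, 1, 1), w_s,
            substr(ref_res, nchar(ref_res), nchar(ref_res)), w_e, alt_res)
  }
  consequence_row(variant, "missense", w_s, w_e, ref_res, alt_res,
                  hgvs_p, mut_prot, 0L, w_s, w_e)
}

inframe_hgvs_p <- function(mclass, wild_prot, len_w, w_s, w_e,
                           ref_res, alt_res) {
  one <- function(i) {
    if (i <= len_w) substr(wild_prot, i, i) else "*"
  }
  if (mclass == "inframe_deletion") {
    if (!nzchar(alt_res)) {
      if (w_e == w_s) sprintf("p.%s%ddel", one(w_s), w_s)
      else sprintf("p.%s%d_%s%ddel", one(w_s), w_s, one(w_e), w_e)
    } else {
      sprintf("p.%s%d_%s%ddelins%s", one(w_s), w_s, one(max(w_s, w_e)),
              max(w_s, w_e), alt_res)
    }
  } else {
    if (!nzchar(ref_res)) {
      # pure insertion between residues w_s - 1 and w_s
      left <- w_s - 1L
      sprintf("p.%s%d_%s%dins%s", one(left), left, one(w_s), w_s, alt_res)
    } else {
      sprintf("p.%s%d_%s%ddelins%s", one(w_s), w_s, one(max(w_s, w_e)),
              max(w_s, w_e), alt_res)
    }
  }
}

#' Call consequences for a variant table against a CDS set
#'
#' Vectorized driver for [call_consequence()]: joins each variant to its
#' CDS by `transcript_id`, calls the consequence, and collects failures
#' (missing CDS, reference mismatch, coordinates beyond the CDS, malformed
#' CDS) as counted rejects rather than errors, mirroring the table readers.
#'
#' @param variants Coding-variant tibble.
#' @param cds_set Sequence tibble from [read_fasta()] (ids matched against
#'   `transcript_id`), optionally with a `downstream_context` column.
#' @param codon_table Codon table.
#' @return Consequence tibble (one row per successfully called variant)
#'   with [parse_report()] / [parse_rejects()] attributes.
#' @export
call_consequences <- function(variants, cds_set,
                              codon_table = default_codon_table()) {
  stopifnot(is.data.frame(variants), is.data.frame(cds_set))
  idx <- match(variants$transcript_id, cds_set$id)
  out <- vector("list", nrow(variants))
  rej <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (is.na(idx[i])) {
      rej[[i]] <- tibble(row = i, hgvs_c = v$hgvs_c,
                         reason = sprintf("no CDS for transcript '%s'",
                                          v$transcript_id))
      next
    }
    res <- tryCatch(
      call_consequence(cds_set[idx[i], ], v, codon_table),
      neodb_error = function(e) e
    )
    if (inherits(res, "error")) {
      rej[[i]] <- tibble(row = i, hgvs_c = v$hgvs_c,
                         reason = conditionMessage(res))
    } else {
      out[[i]] <- res
    }
  }
  rejects <- dplyr::bind_rows(rej)
  if (!nrow(rejects)) {
    rejects <- tibble(row = integer(), hgvs_c = character(),
                      reason = character())
  }
  attach_report(dplyr::bind_rows(out), nrow(variants), rejects)
}

#' Remove synonymous consequences
#'
#' Splits a consequence table into the retained non-synonymous calls and
#' the counts needed for pipeline bookkeeping. The conservation identity
#' `retained + removed_synonymous + unparseable = input variants` holds,
#' with the unparseable count taken from the table's [parse_report()]
#' attribute when present.
#'
#' @param consequences Consequence tibble from [call_consequences()].
#' @return List with `retained` (tibble), `removed_synonymous_count`,
#'   `unparseable_count`.
#' @export
filter_nonsynonymous <- function(consequences) {
  stopifnot(is.data.frame(consequences))
  syn <- consequences$mclass == "synonymous"
  list(
    retained = consequences[!syn, , drop = FALSE],
    removed_synonymous_count = sum(syn),
    unparseable_count = parse_report(consequences)$unparseable
  )
}
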