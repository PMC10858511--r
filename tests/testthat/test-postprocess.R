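psm_of <- function(peptides) {
  tibble::tibble(
    peptide = peptides,
    hyperscore = seq_along(peptides) + 10,
    intensity = 1000 * seq_along(peptides),
    protein_ids = as.list(paste0("prot", seq_along(peptides))),
    spectrum_id = paste0("s", seq_along(peptides)),
    replicate = "R1"
  )
}

test_that("length filter keeps 8-14-mers and conserves counts", {
  peps <- vapply(c(7, 8, 9, 14, 15), function(n) {
    paste(rep("A", n), collapse = "")
  }, "")
  res <- filter_by_length(psm_of(c(peps, "SLFDASHML")))
  expect_equal(sort(unique(nchar(res$kept$peptide))), c(8, 9, 14))
  expect_true("SLFDASHML" %in% res$kept$peptide)
  expect_equal(nrow(res$kept) + nrow(res$removed), 6)
  empty <- filter_by_length(psm_of(character()))
  expect_equal(nrow(empty$kept), 0)
})

# A missense entry built by the real pipeline around the codon-81 example.
amt_entry_world <- function() {
  cds <- amt_like_cds()
  cons <- call_consequence(tibble::tibble(id = "T1", residues = cds),
                           parse_hgvs_c("c.242T>C", gene_symbol = "AMT",
                                        transcript_id = "T1"))
  entries <- build_entries(cons)$entries
  list(cds = cds, cons = cons, entries = entries)
}

test_that("peptides map onto entries with correct offsets and coverage", {
  w <- amt_entry_world()
  # entry covers mutant residues 31..131; SLFDASHML sits at protein 77..85
  hits <- map_to_entries("SLFDASHML", w$entries)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 77L - 30L)
  expect_true(hits$covers_mutation)
  expect_equal(substr(w$entries$sequence, hits$offset, hits$offset + 8),
               "SLFDASHML")

  # flank-only 9-mer: matches, but does not cover the mutation
  flank_pep <- substr(w$entries$sequence, 1, 9)
  fh <- map_to_entries(flank_pep, w$entries)
  expect_equal(nrow(fh), 1)
  expect_false(fh$covers_mutation)

  expect_equal(nrow(map_to_entries("WWWWWWWW", w$entries)), 0)
})

test_that("overlapping occurrences are all reported", {
  entries <- tibble::tibble(entry_id = "e", sequence = "AAAAAAAAAAAA",
                            span_start = 6L, span_end = 6L)
  hits <- map_to_entries("AAAAAAAA", entries)
  expect_equal(hits$offset, 1:5)
  for (i in seq_len(nrow(hits))) {
    expect_equal(substr(entries$sequence, hits$offset[i], hits$offset[i] + 7),
                 hits$peptide[i])
  }
})

test_that("wild counterparts revert the mutated residue (and only missense)", {
  w <- amt_entry_world()
  hits <- wild_counterpart(map_to_entries("SLFDASHML", w$entries),
                           w$entries, w$cons)
  expect_equal(hits$wild_counterpart, "SLFDVSHML")

  # involution: reverting the counterpart's residue returns the original
  back <- hits$wild_counterpart
  pos <- w$entries$span_start - hits$offset + 1
  substr(back, pos, pos) <- w$cons$alt_residues
  expect_equal(back, hits$peptide)

  # frameshift-covering peptides have no positional wild counterpart
  fs_cds <- make_cds(200, seed = 77, id = "T2")
  v <- parse_hgvs_c("c.300delA", gene_symbol = "G2", transcript_id = "T2")
  v$ref_allele <- substr(fs_cds$residues, 300, 300)
  v$hgvs_c <- format_hgvs_c(v)
  fs_cons <- call_consequence(fs_cds, v)
  fs_entries <- build_entries(fs_cons)$entries
  pep <- substr(fs_entries$sequence, fs_entries$span_start,
                fs_entries$span_start + 8)
  fs_hits <- wild_counterpart(map_to_entries(pep, fs_entries),
                              fs_entries, fs_cons)
  expect_true(any(fs_hits$covers_mutation))
  expect_true(all(is.na(fs_hits$wild_counterpart)))
})

test_that("binder levels follow the rank thresholds, boundaries weak", {
  rows <- tibble::tibble(
    peptide = c("A", "B", "C", "D", "E"),
    allele = "HLA-A*02:01",
    percent_rank = c(0.003, 1.487, 2.5, 0.5, 2.0)
  )
  calls <- call_binders(rows)
  expect_equal(as.character(calls$level),
               c("strong", "weak", "none", "weak", "weak"))
  # monotone non-increasing in rank
  ranks <- sort(runif(200, 0, 5))
  lv <- call_binders(tibble::tibble(peptide = "P", allele = "X",
                                    percent_rank = ranks))$level
  expect_true(all(diff(as.integer(lv)) >= 0))
  expect_error(call_binders(tibble::tibble(peptide = "P", allele = "X",
                                           percent_rank = -1)))
})

test_that("best_call picks the minimum-rank allele per peptide", {
  rows <- tibble::tibble(
    peptide = c("PEP1", "PEP1", "PEP2"),
    allele = c("HLA-A*02:01", "HLA-A*24:02", "HLA-B*51:08"),
    percent_rank = c(1.2, 0.1, 3.0)
  )
  best <- best_call(call_binders(rows))
  expect_equal(nrow(best), 2)
  expect_equal(best$allele[best$peptide == "PEP1"], "HLA-A*24:02")
  expect_equal(as.character(best$level), c("strong", "none"))
})

test_that("search comparison partitions peptides and summarizes groups", {
  a <- psm_of(c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD"))
  same <- compare_searches(a, a)
  expect_equal(length(same$common_peptides), 3)
  expect_equal(length(same$unique_a), 0)
  expect_equal(length(same$unique_b), 0)

  b <- psm_of(c("EEEEEEEE", "FFFFFFFF"))
  disjoint <- compare_searches(a, b)
  expect_equal(length(disjoint$common_peptides), 0)

  # constructed 60 common / 25 unique-a / 15 unique-b split
  common <- sprintf("PEPTIDEC%03d", 1:60)
  ua <- sprintf("PEPTIDEA%03d", 1:25)
  ub <- sprintf("PEPTIDEB%03d", 1:15)
  cmp <- compare_searches(psm_of(c(common, ua)), psm_of(c(common, ub)))
  g <- glance(cmp)
  expect_equal(g$common_peptides, 60)
  expect_equal(g$unique_peptides_a, 25)
  expect_equal(g$unique_peptides_b, 15)
  # partition invariants
  expect_equal(g$common_peptides + g$unique_peptides_a, 85)
  expect_length(intersect(cmp$unique_a, cmp$common_peptides), 0)
  td <- tidy(cmp)
  expect_equal(td$n[td$group == "common_a"], 60)
  expect_true(all(c("hyperscore_median", "intensity_q3") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})

test_that("mutant report recovers covering peptides and drops I/L swaps", {
  w <- make_world(n_genes = 2, n_codons = 220, seed = 15,
                  mix = c(missense = 6, nonsense = 1, frameshift_deletion = 2))
  cons <- call_consequences(w$variants, w$cds)
  db <- build_mutant_db(w$variants, w$cds)
  tabs <- make_psm_and_rank_tables(db$entries, cons, w$proteome, seed = 3,
                                   n_cover = 8, n_flank = 4, n_ref = 6)
  rep <- mutant_peptide_report(tabs$psm, db$entries, cons,
                               rank_rows = tabs$rank, proteome = w$proteome)
  expect_setequal(rep$peptide, tabs$ledger$peptide[tabs$ledger$covers_mutation])
  expect_true(all(c("hgvs_p", "level", "percent_rank") %in% names(rep)))
  lvl <- tabs$ledger[tabs$ledger$covers_mutation, ]
  got <- rep[match(lvl$peptide, rep$peptide), ]
  expect_equal(as.character(got$level), lvl$true_level)

  # an injected I/L missense pair is excluded unless asked for
  ent <- tibble::tibble(
    entry_id = "mut|ILG|c.1A>T|p.I5L|missense",
    sequence = "KKKKLRRRR", span_start = 5L, span_end = 5L,
    gene_symbol = "ILG", hgvs_c = "c.1A>T", hgvs_p = "p.I5L",
    mclass = "missense", source = "cosmic"
  )
  il_cons <- tibble::tibble(gene_symbol = "ILG", hgvs_c = "c.1A>T",
                            mclass = "missense", ref_residues = "I",
                            alt_residues = "L")
  psm <- psm_of("KKKKLRRRR")
  expect_equal(nrow(mutant_peptide_report(psm, ent, il_cons)), 0)
  kept <- mutant_peptide_report(psm, ent, il_cons, keep_il_swaps = TRUE)
  expect_equal(kept$ambiguity, "il_swap")
})
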