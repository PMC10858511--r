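# Hand-built consequence rows isolate the windowing rules from the engine.
cons_row <- function(mclass, mutant_protein, span_start, span_end,
                     gene = "G", hgvs_c = "c.1A>T", hgvs_p = "p.X1Y") {
  tibble::tibble(
    gene_symbol = gene, transcript_id = "T", hgvs_c = hgvs_c,
    kind = "substitution", mclass = mclass,
    protein_start = span_start, protein_end = span_end,
    ref_residues = "A", alt_residues = "V", hgvs_p = hgvs_p,
    mutant_protein = mutant_protein, novel_tail_length = 0L,
    mut_span_start = span_start, mut_span_end = span_end,
    sample_id = "S", source = "cosmic"
  )
}

make_prot <- function(n) {
  set.seed(123)
  paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

test_that("windowing: interior missense gets 50+1+50 residues", {
  prot <- make_prot(600)
  built <- build_entries(cons_row("missense", prot, 200L, 200L))
  e <- built$entries
  expect_equal(nchar(e$sequence), 101L)
  expect_equal(e$sequence, substr(prot, 150, 250))
  expect_equal(c(e$span_start, e$span_end), c(51L, 51L))
})

test_that("windowing: near-terminus missense truncates at the end", {
  prot <- make_prot(600)
  built <- build_entries(cons_row("missense", prot, 10L, 10L))
  e <- built$entries
  expect_equal(e$sequence, substr(prot, 1, 60))
  expect_equal(nchar(e$sequence), 60L)
  expect_equal(c(e$span_start, e$span_end), c(10L, 10L))
})

test_that("windowing: frameshift keeps the flank plus the whole novel tail", {
  # mutant protein: 99 wild-matching residues then a 23-residue novel tail
  prot <- make_prot(122)
  row <- cons_row("frameshift_deletion", prot, 100L, 122L)
  e <- build_entries(row)$entries
  expect_equal(nchar(e$sequence), 73L)  # 50 upstream + 23 novel
  expect_equal(e$sequence, substr(prot, 50, 122))
  expect_equal(c(e$span_start, e$span_end), c(51L, 73L))
})

test_that("windowing: nonsense keeps the flank ending at the new C-terminus", {
  prot <- make_prot(200)  # already-truncated mutant protein
  row <- cons_row("nonsense", prot, 201L, 201L)
  e <- build_entries(row)$entries
  expect_equal(e$sequence, substr(prot, 151, 200))
  expect_equal(c(e$span_start, e$span_end), c(50L, 50L))
})

test_that("short and productless entries are dropped with reasons", {
  short <- cons_row("nonsense", "MKT", 4L, 4L)
  tss <- cons_row("translation_start_site", "", NA_integer_, NA_integer_)
  built <- build_entries(dplyr::bind_rows(short, tss))
  expect_equal(nrow(built$entries), 0)
  expect_setequal(built$dropped$reason, c("too_short", "no_product"))
  expect_error(build_entries(cons_row("synonymous", "MKT", 1L, 1L)),
               class = "neodb_domain_error")
})

test_that("deduplication is keyed, first-wins, idempotent and conserving", {
  prot <- make_prot(300)
  a <- build_entries(cons_row("missense", prot, 100L, 100L,
                              gene = "TP53", hgvs_c = "c.215C>G"))$entries
  entries <- dplyr::bind_rows(a, a, a)
  entries$sample <- c("S1", "S2", "S3")
  dd <- deduplicate_entries(entries)
  expect_equal(nrow(dd$entries), 1)
  expect_equal(dd$duplicates_removed, 2)
  expect_equal(nrow(dd$entries) + dd$duplicates_removed, nrow(entries))
  expect_identical(deduplicate_entries(dd$entries)$entries, dd$entries)
  expect_equal(dd$entries$sample, "S1")

  # same window sequence under different hgvs_c: both kept
  b <- a
  b$hgvs_c <- "c.216A>T"
  expect_equal(nrow(deduplicate_entries(dplyr::bind_rows(a, b))$entries), 2)
})

test_that("proteome merge conserves records and embeds provenance headers", {
  prot <- make_prot(300)
  entries <- build_entries(cons_row("missense", prot, 100L, 100L,
                                    gene = "AMT", hgvs_c = "c.242T>C",
                                    hgvs_p = "p.V81A"))$entries
  proteome <- tibble::tibble(id = c("sp|P1|X", "sp|P2|Y", "sp|P3|Z"),
                             description = "", residues = c("MAAA", "MCCC", "MDDD"))
  f <- withr::local_tempfile(fileext = ".fasta")
  merge_with_proteome(entries, proteome, f)
  back <- read_fasta(f, "protein")
  expect_equal(nrow(back), 4)
  expect_match(back$id[1], "AMT")
  expect_match(back$id[1], "c.242T>C", fixed = TRUE)
  expect_match(back$id[1], "p.V81A", fixed = TRUE)
  expect_equal(back$residues[2:4], proteome$residues)

  clash <- entries
  clash$entry_id <- "sp|P1|X"
  expect_error(merge_with_proteome(clash, proteome, f),
               class = "neodb_format_error")

  # empty entry set: output identical to the reference proteome
  f2 <- withr::local_tempfile(fileext = ".fasta")
  merge_with_proteome(entries[0, ], proteome, f2)
  expect_equal(read_fasta(f2, "protein"), proteome)
})

test_that("class statistics tally the fixture ledger exactly", {
  mix <- c(missense = 6, nonsense = 2, synonymous = 3,
           frameshift_insertion = 2, inframe_deletion = 1)
  w <- make_world(n_genes = 2, n_codons = 160, seed = 41, mix = mix)
  cons <- call_consequences(w$variants, w$cds)
  stats <- class_statistics(cons)
  expect_equal(nrow(stats), 9)
  truth <- table(factor(w$ledger$true_class, levels = mutation_classes()))
  expect_equal(stats$n, as.integer(truth))
  empty <- class_statistics(cons[0, ])
  expect_true(all(empty$n == 0))
})

test_that("pipeline counts satisfy the conservation identity", {
  w <- make_world(n_genes = 3, n_codons = 180, seed = 8,
                  mix = c(missense = 4, synonymous = 2, nonsense = 1,
                          frameshift_deletion = 1, translation_start_site = 1))
  # duplicate some rows to exercise deduplication
  variants <- dplyr::bind_rows(w$variants, w$variants[1:5, ])
  db <- build_mutant_db(variants, w$cds, w$proteome,
                        withr::local_tempfile(fileext = ".fasta"))
  g <- glance(db)
  expect_equal(
    g$input_variants,
    g$unparseable_rows + g$consequence_failures + g$synonymous_removed +
      g$dropped_entries + g$duplicates_removed + g$entries
  )
  dup_classes <- w$ledger$true_class[1:5]
  expect_equal(g$duplicates_removed,
               sum(!dup_classes %in% c("synonymous", "translation_start_site")))
  expect_equal(sum(tidy(db)$n), db$retained_total)
})
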