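test_that("codon_index maps coding positions to residues", {
  expect_equal(codon_index(242), 81L)
  expect_equal(codon_index(1795), 599L)
  expect_equal(codon_index(215), 72L)
  expect_equal(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(codon_index(0), class = "neodb_domain_error")
  expect_error(codon_index(-5), class = "neodb_domain_error")
  # 3(c-1) < pos <= 3c for a range of positions
  pos <- 1:3000
  ci <- codon_index(pos)
  expect_true(all(3 * (ci - 1) < pos & pos <= 3 * ci))
})

test_that("apply_variant edits the CDS and validates the reference allele", {
  cds <- "ATGGTTAAATAA"
  expect_equal(apply_variant(cds, parse_hgvs_c("c.5T>A")), "ATGGATAAATAA")
  expect_equal(nchar(apply_variant(cds, parse_hgvs_c("c.5T>A"))), nchar(cds))
  expect_equal(apply_variant(cds, parse_hgvs_c("c.4_5insCC")), "ATGGCCTTAAATAA")
  expect_equal(apply_variant(cds, parse_hgvs_c("c.4_6delGTT")), "ATGAAATAA")
  err <- expect_error(apply_variant(cds, parse_hgvs_c("c.5T>G") |>
                                      transform(ref_allele = "G")),
                      class = "neodb_ref_mismatch")
  expect_match(conditionMessage(err), "observed 'T', expected 'G'")
  expect_error(apply_variant(cds, parse_hgvs_c("c.99A>T")),
               class = "neodb_coordinate_error")
})

test_that("the AMT-style codon-81 substitution is a missense p.V81A", {
  cds <- amt_like_cds()
  expect_equal(substr(cds, 241, 243), "GTG")
  cc <- call_consequence(cds, parse_hgvs_c("c.242T>C", gene_symbol = "AMT"))
  expect_equal(cc$mclass, "missense")
  expect_equal(cc$hgvs_p, "p.V81A")
  expect_equal(cc$protein_start, 81L)
  expect_equal(substr(cc$mutant_protein, 77, 85), "SLFDASHML")
  # wobble-position edit of the same codon is synonymous (GTG -> GTA, Val)
  syn <- call_consequence(cds, parse_hgvs_c("c.243G>A"))
  expect_equal(syn$mclass, "synonymous")
  expect_equal(syn$mutant_protein, bs_translate(cds))
})

test_that("frameshift deletion matches brute-force re-translation", {
  cds <- make_cds(100, seed = 17, id = "fs")$residues
  v <- parse_hgvs_c("c.14delA") |> transform(ref_allele = substr(cds, 14, 14))
  v$hgvs_c <- format_hgvs_c(v)
  cc <- call_consequence(cds, v)
  expect_equal(cc$mclass, "frameshift_deletion")
  # oracle: edit by hand, translate from scratch
  edited <- paste0(substr(cds, 1, 13), substr(cds, 15, nchar(cds)))
  expect_equal(cc$mutant_protein, bs_translate(edited))
  wild <- bs_translate(cds)
  expect_equal(substr(cc$mutant_protein, 1, 4), substr(wild, 1, 4))
  expect_equal(cc$novel_tail_length,
               nchar(cc$mutant_protein) - cc$protein_start + 1L)
})

test_that("stop-loss reads through into downstream context", {
  prot <- paste(rep("A", 49), collapse = "")
  cds <- protein_to_cds(paste0("M", prot), stop_codon = "TAA")
  # context: 4 sense codons then a stop
  ctx <- "GGTGGTGGTGGTTAAGGG"
  v <- parse_hgvs_c(sprintf("c.%dT>C", nchar(cds) - 2))
  cc <- call_consequence(cds, v, downstream_context = ctx)
  expect_equal(cc$mclass, "nonstop")
  expect_equal(cc$novel_tail_length, 4L)  # codons before the context stop
  expect_equal(cc$hgvs_p, sprintf("p.*%dQext*5", nchar(cds) / 3))
  expect_equal(cc$mutant_protein, bs_translate(paste0(
    substr(cds, 1, nchar(cds) - 3), "CAA", ctx)))
  # without context the protein ends at the last complete codon
  cc0 <- call_consequence(cds, v, downstream_context = "")
  expect_equal(cc0$novel_tail_length, 0L)
  expect_equal(nchar(cc0$mutant_protein), nchar(cds) / 3)
})

test_that("initiator-codon edits are start-loss, malformed CDS is an error", {
  cds <- make_cds(50, seed = 2)$residues
  tss <- call_consequence(cds, parse_hgvs_c("c.2T>C"))
  expect_equal(tss$mclass, "translation_start_site")
  expect_equal(tss$mutant_protein, "")
  expect_error(call_consequence("ATGNNNTAA", parse_hgvs_c("c.4N>A")),
               class = "neodb_parse_error")  # N never parses as an allele
  expect_error(call_consequence("GTGAAATAA", parse_hgvs_c("c.4A>T")),
               class = "neodb_malformed_cds")
  expect_error(call_consequence("ATGAAATAAAAATAA", parse_hgvs_c("c.4A>T")),
               class = "neodb_malformed_cds")  # internal stop
})

test_that("consequence properties hold over a mixed fixture", {
  w <- make_world(n_genes = 2, n_codons = 150, seed = 7,
                  mix = c(missense = 5, synonymous = 3, nonsense = 2,
                          inframe_insertion = 2, inframe_deletion = 2,
                          frameshift_insertion = 2, frameshift_deletion = 2))
  cons <- call_consequences(w$variants, w$cds)
  expect_equal(parse_report(cons)$unparseable, 0)
  joined <- dplyr::inner_join(cons, w$ledger,
                              by = c("hgvs_c", "gene_symbol"))
  expect_equal(nrow(joined), nrow(w$variants))
  expect_equal(joined$mclass, joined$true_class)
  expect_equal(joined$mutant_protein, joined$true_mutant_protein)
  expect_equal(joined$hgvs_p, joined$true_hgvs_p)

  wild_of <- setNames(w$proteome$residues, sub("^sp\\|", "", sub("\\|REF$", "", w$proteome$id)))
  for (i in seq_len(nrow(joined))) {
    r <- joined[i, ]
    wild <- wild_of[[r$transcript_id.x]]
    if (r$mclass == "missense") {
      # exactly one residue differs
      a <- strsplit(r$mutant_protein, "")[[1]]
      b <- strsplit(wild, "")[[1]]
      expect_equal(sum(a != b), 1L)
      expect_equal(r$protein_start, codon_index(r$start))
    }
    if (r$mclass %in% c("inframe_insertion", "inframe_deletion")) {
      net <- nchar(r$alt_allele) - ifelse(r$kind.x == "insertion", 0L,
                                          r$end - r$start + 1L)
      expect_equal(nchar(r$mutant_protein) - nchar(wild), net / 3)
    }
  }
})

test_that("applying a substitution then its reverse restores the wild CDS", {
  cds <- make_cds(80, seed = 5)$residues
  v <- parse_hgvs_c("c.50A>G") |>
    transform(ref_allele = substr(cds, 50, 50), alt_allele = "G")
  if (v$ref_allele == "G") v$alt_allele <- "C"
  v$hgvs_c <- format_hgvs_c(v)
  mut <- apply_variant(cds, v)
  back <- new_v <- v
  back$ref_allele <- v$alt_allele
  back$alt_allele <- v$ref_allele
  back$hgvs_c <- format_hgvs_c(back)
  expect_equal(apply_variant(mut, back), cds)
  cc <- call_consequence(cds, v)
  if (cc$mclass == "synonymous") {
    expect_equal(cc$mutant_protein, bs_translate(cds))
  }
})

test_that("filter_nonsynonymous splits and conserves counts", {
  w <- make_world(n_genes = 1, n_codons = 150, seed = 13,
                  mix = c(missense = 3, synonymous = 2, nonsense = 1))
  cons <- call_consequences(w$variants, w$cds)
  flt <- filter_nonsynonymous(cons)
  expect_equal(nrow(flt$retained), 4)
  expect_equal(flt$removed_synonymous_count, 2)
  expect_equal(nrow(flt$retained) + flt$removed_synonymous_count +
                 flt$unparseable_count, nrow(w$variants))
  expect_false(any(flt$retained$mclass == "synonymous"))

  all_syn <- cons[cons$mclass == "synonymous", ]
  expect_equal(nrow(filter_nonsynonymous(all_syn)$retained), 0)
})
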