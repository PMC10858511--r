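# Shared fixture builders. Everything is generated in code; no data files.

# Reverse-translate a protein to a CDS using one fixed codon per residue,
# with optional codon overrides at given residue positions.
protein_to_cds <- function(protein, overrides = list(), stop_codon = "TAA") {
  tab <- default_codon_table()
  rev_map <- vapply(setdiff(unique(tab), "*"), function(aa) {
    names(tab)[tab == aa][1]
  }, "")
  res <- strsplit(protein, "")[[1]]
  codons <- unname(rev_map[res])
  for (pos in names(overrides)) {
    codons[as.integer(pos)] <- overrides[[pos]]
  }
  paste(c(codons, stop_codon), collapse = "")
}

# A CDS whose protein carries SLFDVSHML at residues 77-85 with codon 81 =
# GTG, so that c.242T>C produces the A81 missense and the SLFDASHML 9-mer.
amt_like_cds <- function(n_res = 599) {
  set.seed(4242)
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M")
  prot <- c("M", sample(aa_pool, n_res - 1, replace = TRUE))
  prot[77:85] <- strsplit("SLFDVSHML", "")[[1]]
  protein_to_cds(paste(prot, collapse = ""), overrides = list("81" = "GTG"))
}

# Independent re-translation through Biostrings, for spot checks in tests.
bs_translate <- function(nt) {
  nt <- substr(nt, 1, 3 * (nchar(nt) %/% 3))  # whole codons only
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "error"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
}

# A multi-gene fixture: CDS set, injected variants with oracle ledger,
# wild-protein reference proteome.
make_world <- function(n_genes = 2, n_codons = 200, seed = 99,
                       mix = c(missense = 5, synonymous = 2, nonsense = 1,
                               frameshift_deletion = 1)) {
  cds <- dplyr::bind_rows(lapply(seq_len(n_genes), function(g) {
    make_cds(n_codons, seed + g, id = sprintf("ENST%03d", g))
  }))
  inj <- lapply(seq_len(n_genes), function(g) {
    inject_variants(cds[g, ], mix, seed + 50 + g,
                    gene_symbol = sprintf("GENE%d", g),
                    sample_id = sprintf("S%d", g))
  })
  proteome <- tibble::tibble(
    id = paste0("sp|", cds$id, "|REF"),
    description = "wild-type protein",
    residues = vapply(cds$residues, bs_translate, "", USE.NAMES = FALSE)
  )
  list(
    cds = cds,
    variants = dplyr::bind_rows(lapply(inj, `[[`, "variants")),
    ledger = dplyr::bind_rows(lapply(inj, `[[`, "ledger")),
    proteome = proteome
  )
}
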