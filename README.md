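# neodb

Proteogenomic mutant-peptide search databases for HLA class I
immunopeptidomics, in R.

## The problem

Tumor cells present mutant peptides (neoantigen candidates) on HLA class I
molecules, but a standard reference proteome cannot match the spectra of
peptides that carry somatic mutations. For low-mutational-burden cancers
such as hepatocellular carcinoma, a single sample's exome yields only a
handful of coding mutations, so cohort-scale mutation registries (COSMIC)
are an attractive alternative source of candidate mutant sequences — if the
resulting database is kept small enough to search.

`neodb` implements that database-construction strategy and the matching
identification post-processing:

1. **Variant parsing** — HGVS coding notation (`c.242T>C`,
   `c.100_101insA`, `c.5_7del`, `c.10delinsTT`) from COSMIC-style and
   MAF-style tab-separated exports, with per-row reject accounting.
2. **Consequence calling** — apply the variant to the coding sequence,
   translate, and classify into the eight non-synonymous classes
   (missense, nonsense, nonstop, translation start site, in-frame
   insertion/deletion, frameshift insertion/deletion) plus synonymous;
   synonymous variants are removed. For a substitution at coding position
   `p` the affected residue is `floor((p - 1)/3) + 1`, so `c.242T>C` in a
   Val codon gives `p.V81A`.
3. **Windowed database entries** — each mutant protein is compressed to
   the altered residues ±50 aa of flanking context (windows stop at the
   termini; frameshift and stop-loss entries keep their entire novel
   tail; nonsense entries keep the flank ending at the new C-terminus),
   deduplicated, and merged with a reference proteome into one
   search-ready FASTA.
4. **Post-processing** — 8–14 aa length filter, peptide-to-entry mapping
   with mutation coverage, mutant/wild-type pairing for missense hits,
   exclusion of I/L-swap peptides and flagging of equal-mass residue
   recombinations (GG↔N, GA/AG↔Q) that mass spectrometry cannot
   distinguish, elution %rank binder calls (strong < 0.5, weak 0.5–2.0),
   and two-search overlap/score comparisons.
5. **Synthetic fixtures** — a seeded generator for CDS, variant tables,
   PSM and %rank tables whose ground-truth ledger is computed by
   brute-force whole-CDS re-translation, so the entire pipeline is
   testable offline.

## Worked example

```r
library(neodb)

v <- parse_hgvs_c("c.242 T > C", gene_symbol = "AMT", transcript_id = "AMT-201")
v[, c("gene_symbol", "kind", "start", "end", "ref_allele", "alt_allele")]
#> # A tibble: 1 × 6
#>   gene_symbol kind         start   end ref_allele alt_allele
#>   <chr>       <chr>        <int> <int> <chr>      <chr>
#> 1 AMT         substitution   242   242 T          C
codon_index(v$start)
#> [1] 81
```

Position 242 sits in codon 81: a T>C at the second codon position turns a
Val codon (GTx) into Ala (GCx), the `p.V81A` missense. On a CDS carrying
that codon the full path — consequence call, 50-aa windowing, peptide
mapping — reproduces the mutant/wild 9-mer pair:

```r
cc <- call_consequence(cds, v)        # cds: coding sequence with GTG at codon 81
cc$hgvs_p                             #> "p.V81A"
entries <- build_entries(cc)$entries  # 101 aa window, altered span (51, 51)
hits <- wild_counterpart(map_to_entries("SLFDASHML", entries), entries, cc)
hits$covers_mutation                  #> TRUE
hits$wild_counterpart                 #> "SLFDVSHML"
```

The pair differs by Ala vs Val (−28.0313 Da), so it is genuinely
distinguishable; `flag_indistinguishable()` returns `kind = "none"`,
whereas an I↔L mutant/wild pair returns `il_swap` and is excluded from
mutant reports by default.

A shell front end wires the same steps together
(`simulate`, `build-db`, `filter-peptides`, `map-mutants`, `call-binders`,
`compare`, `flag-ambiguous`); see
`system.file("cli", "neodb.R", package = "neodb")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs a seeded synthetic cohort through the CLI pipeline and then recomputes
the worked-example residue indices (the protein positions implied by the
published coding substitutions at nucleotides 242, 1795 and 215) by parsing
the printed HGVS notation and applying `codon_index()`, writing the values
as JSON.

## Vignette

`vignettes/mutant-database-construction.Rmd` documents the model, the
windowing and classification conventions, the synthetic-data generator and
its limits, and the numerical choices (tolerances, boundaries, tie-breaks).
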