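---
title: "Building and screening mutant-peptide databases for HLA-I immunopeptidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and screening mutant-peptide databases for HLA-I immunopeptidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neodb)
```

## The model

HLA class I molecules present 8–14-residue peptides sampled from the
cellular proteome. A tumor's somatic coding mutations change that proteome,
and the changed peptides — neoantigen candidates — can only be identified
from immunopeptidome LC–MS/MS data if the search database contains the
mutant sequences. `neodb` turns a table of somatic coding variants into
such a database and post-processes the resulting identifications.

The pipeline is deliberately transcript-centric: variants arrive in HGVS
coding notation (`c.242T>C`) against a coding sequence (CDS) supplied by
the caller, and all coordinates are 1-based inclusive coding-nucleotide
positions. No genome coordinates, strand arithmetic or splice models are
involved; that keeps the consequence calculus exact and testable. The
residue affected by coding position $p$ is

$$\mathrm{codon}(p) = \left\lfloor \frac{p-1}{3} \right\rfloor + 1 .$$

### Consequence classification

`call_consequence()` applies the edit, re-translates, and assigns exactly
one of nine classes. The declared conventions, where the choice was open:

* **Initiator edits.** Any variant touching codon 1 is
  `translation_start_site`. ATG is the unique Met codon of the standard
  code, so every such substitution changes the initiator. No downstream
  re-initiation is modeled, so the consequence carries an *empty* mutant
  protein and the database builder drops it with a logged `no_product`
  reason (the class is still tallied in the statistics). Start-loss counts
  in real cohorts are tiny, and fabricating an N-truncated product would
  claim mechanism the data does not support.
* **Stop codon gained already at the stop.** A substitution that rewrites
  the terminal stop into another stop changes nothing and is synonymous.
* **Stop lost (`nonstop`).** Translation reads through into the 3'
  `downstream_context` when one is supplied; `novel_tail_length` counts
  the context residues actually appended (the re-coded stop position
  itself is reported via `p.*<pos><aa>ext*<n>`). Without context the
  protein ends at the last complete codon and the tail length is 0.
* **Indels.** Net length change divisible by 3 gives the in-frame
  classes; otherwise the shifted frame is translated to its first stop
  (continuing into the context if none occurs in the CDS). Frameshift
  notation anchors on the first residue that actually differs from the
  wild protein — which can lie downstream of the edit when the shifted
  frame initially reproduces wild residues — with `fs*n` counting from
  that residue to the new stop inclusive. For substitutions and in-frame
  classes the reported start equals `codon_index(start)`.
* **Balanced delins.** A deletion-insertion with net length change 0 has
  no class of its own in the taxonomy; following common annotation
  practice it is classified by protein diff (synonymous / missense /
  nonsense / nonstop), with multi-residue changes reported in
  `delins` p-notation.
* **Alphabet strictness.** Ambiguity codes or selenocysteine in a CDS are
  a malformed-CDS error rather than a silent translation: the downstream
  mass arithmetic requires the 20-letter alphabet.

No HGVS 3'-normalization (rightmost shifting) of indels is performed;
variants are interpreted at the positions given.

## Windowed database entries

A full mutant proteome is far too large to search efficiently, so each
non-synonymous consequence is excised into a compact entry: the altered
residues plus up to `flank = 50` residues of context on each side, the
window simply stopping at a terminus it reaches. Conventions for the
classes the flank rule does not fully determine:

* windows are cut in *mutant-protein* coordinates, anchored on the first
  and last altered residues, so multi-residue changes are always wholly
  inside the entry;
* frameshift and stop-loss entries keep the upstream flank plus the
  **entire** novel tail — every residue of the shifted-frame or
  read-through sequence is informative and has no other source;
* nonsense entries keep the flank ending at the premature C-terminus;
  nothing downstream exists to include, and the novel terminus is the
  searchable feature;
* entries shorter than `min_entry_length = 8` cannot contain any
  8–14-mer and are dropped with a logged reason.

An interior missense entry is therefore exactly $2 \times 50 + 1 = 101$
residues with the altered residue at position 51. Entries are
deduplicated on `(gene, hgvs_c, sequence)` — cohort registries report one
row per tumor sample, so the same mutation recurs thousands of times —
and merged unmodified-reference-last into a single FASTA whose mutant
headers embed gene, HGVS c., HGVS p. and class. Stage counts satisfy

```
input = unparseable + synonymous + dropped + duplicates + entries,
```

checked on every build.

## Mass-indistinguishability screen

Isoleucine and leucine have identical monoisotopic residue masses, and
some residue combinations tie as well (GG = N = 114.04293 Da;
GA/AG = Q). A "mutant" peptide whose only difference from a wild peptide
is such a swap cannot be distinguished by mass spectrometry and must not
be credited as a mutant identification. `flag_indistinguishable()`
classifies a mutant/wild pair as `il_swap` (differs only at I/L
positions) or `equal_mass_recombination` (total mass within tolerance by
other substitutions); `equal_mass_rewrites()` enumerates all single- and
pair-substring re-readings of a peptide within tolerance.

The default tolerance is $10^{-4}$ Da — the exact-isobar regime. A looser
user-set tolerance (e.g. 0.01 Da) would admit near-isobars such as K/Q
(0.0364 Da apart); that is deliberately off by default because the screen
concerns true indistinguishability, not instrument resolution. Modified
residues are outside the ambiguity alphabet: peptides are compared as
bare sequences, with search-engine modification annotations stripped at
parse time.

## Identification post-processing

* Length filter 8–14 aa (HLA-I presentation range).
* Substring mapping of peptides onto entries, including overlapping
  occurrences; a peptide matching only flank residues is **not** a mutant
  identification (`covers_mutation = FALSE`).
* A mutation-covering peptide that also occurs anywhere in the reference
  proteome is demoted — a wild-type explanation exists.
* Missense hits get their positional wild counterpart by reverting the
  altered residue; indel/frameshift/nonsense hits have none.
* Binder levels from elution %rank: strong $< 0.5$, weak $0.5$–$2.0$
  inclusive on both boundaries (the published wording "less than 0.5" and
  "range of 0.5 to 2.0" makes the boundary weak), configurable via
  `call_binders(strong=, weak=)`. `best_call()` keeps the minimum-rank
  allele per peptide.
* `compare_searches()` partitions peptides of two searches into
  common/unique sets with per-group hyperscore and intensity summaries;
  the protein-level overlap uses **all** mapped proteins per peptide, not
  razor proteins — the less assumption-laden convention.

## The synthetic world

The fixture generator states a small but complete world, used by all
tests:

* `make_cds()`: ATG + uniformly sampled sense codons + one stop, plus a
  random 60-nt downstream context; no internal stops by construction.
* `inject_variants()`: proposes class-targeted edits (e.g. single-base
  substitutions at internal codons for missense/nonsense, 1–2-nt
  deletions for frameshifts) and accepts a proposal only when the
  **brute-force oracle** — plain character-vector editing plus whole-CDS
  re-translation through the genetic code shipped with Biostrings, a code
  path sharing nothing with the consequence engine — confirms the
  requested class. The oracle's class, position, p-notation and full
  mutant protein are recorded as the ledger's ground truth.
* `make_psm_and_rank_tables()`: samples 8–14-mers that cover mutations
  (never from I/L-swap missense entries, never present in the reference
  proteome), flank-only peptides, and reference peptides; hyperscores are
  log-normal around 15 (sdlog 0.25) and intensities log-normal around
  $10^6$ (sdlog 1) — placeholder realism in the range search engines
  report, not a claim about any real dataset; %ranks are drawn inside the
  interval of each peptide's declared binder level.

All randomness flows from one explicit seed, and the generators restore
the caller's RNG state.

**What a green test establishes — and what it does not.** The synthetic
world exercises the full logic (all nine classes, windowing at termini,
flank-only decoys, isobar exclusion, count conservation) with exact
ground truth, so recovery there is a strong correctness check of the
*computation*. It does not emulate search-engine score calibration,
chimeric spectra, co-eluting isobars beyond sequence identity, modified
peptides, or the mutation spectrum of any real cohort; no claim about
real-data sensitivity follows from it.

## Numerical and degenerate-input choices

* Mass tolerance $10^{-4}$ Da (see above); residue masses are standard
  monoisotopic values, water 18.0105646863 Da.
* %rank boundaries: 0.5 and 2.0 are both weak.
* Deduplication is first-wins in input order, making rebuilds
  bit-stable; FASTA output order is entries-then-reference.
* Duplicate FASTA ids are an error, never silently suffixed — search
  engines key on ids.
* Readers never fail on a bad row: rows are rejected with row numbers
  and reasons, reported via `parse_report()`/`parse_rejects()` and
  optionally a sidecar TSV, and every reader satisfies
  parsed + rejected = total.
* Empty inputs produce empty, correctly-typed tibbles, not errors
  (except an empty FASTA, which is an explicit format error).

## Limitations

* Transcript coordinates only: no genome liftover, splice-site effects,
  UTR/intronic offsets (rejected with a dedicated error class), or
  multi-variant phasing within a transcript.
* Start-loss products are not modeled (no re-initiation scanning).
* The ambiguity screen is sequence-level; it does not rescore spectra or
  compute fragment-ion coverage.
* Binding prediction is consumed (%rank tables), never computed.
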