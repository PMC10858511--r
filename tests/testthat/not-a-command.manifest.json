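{
  "command": "not-a-command",
  "config": [],
  "inputs": [],
  "counts": [],
  "status": "error",
  "error": "unknown command 'not-a-command'\nusage: neodb <command> [--flag value ...]\n\ncommands:\n  simulate        --out DIR [--codons 500] [--genes 5] [--seed 1]\n                  [--mix missense=5,nonsense=2,...]\n  build-db        --variants TSV --dialect cosmic|maf --cds FASTA\n                  [--proteome FASTA] --out FASTA [--stats TSV]\n                  [--entries TSV] [--flank 50] [--site SITE]\n  filter-peptides --psm TSV --out TSV [--min 8] [--max 14]\n  map-mutants     --psm TSV --entries TSV --out TSV [--rank TSV]\n                  [--proteome FASTA] [--keep-il-swaps]\n  call-binders    --rank TSV --out TSV [--strong 0.5] [--weak 2.0]\n  compare         --psm-a TSV --psm-b TSV --out PREFIX\n  flag-ambiguous  --pairs TSV --out TSV [--tolerance 1e-4]\n\nglobal: --config FILE (JSON defaults), --manifest FILE, --version",
  "timestamp": "2026-09-18T05:43:05+0000"
}
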