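{
  "command": "build-db",
  "config": {
    "out": "x.fasta"
  },
  "inputs": [],
  "counts": [],
  "status": "error",
  "error": "missing required flag --variants",
  "timestamp": "2026-09-18T05:43:05+0000"
}
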