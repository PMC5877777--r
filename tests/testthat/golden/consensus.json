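{
  "md_vs_eam": {
    "percent": 57.1428571428571,
    "jaccard": 0.258064516129032,
    "recovered": 8,
    "reference_size": 14,
    "query_size": 25
  }
}
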