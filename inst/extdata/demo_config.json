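{
  "stages": ["simulate", "sociogen", "popgen", "spatial", "mtdna"],
  "outdir": "demo_output",
  "simulate": {
    "seed": 1,
    "n_loci": 7,
    "allele_count_range": [4, 13],
    "n_nests": 10,
    "n_workers": 12,
    "contributions": [6, 4, 2],
    "side_length": 34,
    "placement": "random",
    "transect": {
      "n_sites": 14,
      "site_spacing": 10,
      "samples_per_site": 2,
      "steps_within": 1,
      "steps_between": 14
    }
  },
  "sociogen": { "min_workers": 8 },
  "popgen": { "seed": 11, "n_replicates": 5, "n_perm": 999 },
  "spatial": { "seed": 12, "n_perms": 9999 },
  "mtdna": { "seed": 13, "n_perm": 999 }
}
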