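{
  "functional_weight": {
    "stop_gained": 100,
    "frameshift_variant": 100,
    "splice_donor_variant": 100,
    "splice_acceptor_variant": 100,
    "missense_variant": 5,
    "inframe_insertion": 5,
    "inframe_deletion": 5,
    "splice_region_variant": 3,
    "synonymous_variant": 1,
    "intron_variant": 1,
    "5_prime_UTR_variant": 1,
    "3_prime_UTR_variant": 1
  },
  "category_of": {
    "stop_gained": "LOF",
    "frameshift_variant": "LOF",
    "splice_donor_variant": "LOF",
    "splice_acceptor_variant": "LOF",
    "missense_variant": "protein_altering",
    "inframe_insertion": "protein_altering",
    "inframe_deletion": "protein_altering",
    "splice_region_variant": "splice_site",
    "synonymous_variant": "synonymous",
    "intron_variant": "intronic",
    "5_prime_UTR_variant": "intronic",
    "3_prime_UTR_variant": "intronic"
  },
  "maf_cap": 0.01,
  "maf_weight_max": 10,
  "maf_weight_min": 1
}
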