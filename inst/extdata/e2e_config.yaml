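# reduced-size configuration for the end-to-end command-line walkthrough:
# a complete simulate -> select -> train -> ablate -> explain -> correlate
# pass on a desk-scale cohort. Enrichment is flagged on raw p here: with a
# 40-gene universe the BH correction over 10 terms has essentially no
# power, and the walkthrough needs a connected GO-term layer.
simulate:
  n_samples: 250
  n_snps: 40
  n_cpgs: 60
  n_genes: 40
  n_go_terms: 10
  n_causal_cascades: 5
  n_enriched_terms: 2
select:
  enrichment_adjustment: none
train:
  max_epochs: 150
  patience: 20
explain:
  top_k: 10
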