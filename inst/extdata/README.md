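# extdata

- `published_benchmark_metrics.csv` — the 60 published classifier-evaluation
  columns (recall, specificity, accuracy, precision, F-measure) for the
  reference 40 HC + 40 PD clinical cohort, per dataset (PS, PS_B, PC, PC_B),
  condition (FEET, HANDS, FULL) and classifier (RF, SVM_L, SVM_G, SVM_P, NB).
  Used as a fixture to cross-check the confusion-matrix metric identities;
  note that not every published column is internally consistent with a
  single confusion matrix at this cohort size.
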