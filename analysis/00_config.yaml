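# Desk-scale study conditions shared by the numbered analysis scripts.
# Matrix: endothelial-style imbalance scaled to 1,500 cells x 2,000 genes,
# 15 planted markers at a 3-noise-sd shift. IFS sweeps the top 50 genes of
# each list in steps of 5 under 10-fold SMOTE-balanced cross-validation.
top_n: 50
step: 5
cv_folds: 10
smote_k: 5
relative_delta: 0.015
relative_k_threshold: 100
selection_classifier: RF
seed: 7
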