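# Frozen threshold profile: the printed parameters of the published
# mycobacteriophage annotation workflow this package follows.
min_identity: 0.5          # --min-seq-id 0.5
cluster_coverage: 0.9      # -c 0.9, --cov-mode 0 (bidirectional)
cluster_coverage_mode: bidirectional
hit_tm: 0.5                # --tmscore-threshold 0.5
hit_coverage: 0.8          # -c 0.8, --cov-mode 0
hit_coverage_mode: bidirectional
counter_defense_tm: 0.6    # strict: TM score above 0.6
plddt_high: 70             # mean pLDDT >= 70 -> High_pLDDT
plddt_gate: 90             # function predictions kept only above 90
deepfri_score: 0.8         # high-confidence EC predictions: score > 0.8
interaction_thresholds: [0.5, 0.7]
interaction_score_mode: weighted   # 0.8*ipTM + 0.2*pTM
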