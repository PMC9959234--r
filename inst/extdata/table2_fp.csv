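condition,fp,fp_note
c11_baseline_a1,0.031,baseline free fraction (printed 3.1%)
c11_baseline_a2,0.032,baseline free fraction (printed 3.2%)
c11_block_0.03_a1,,range 0.07-0.10 (per-scan value not printed)
c11_block_0.1_a2,,range 0.07-0.10 (per-scan value not printed)
c11_block_0.25_a1,,range 0.07-0.10 (per-scan value not printed)
f18_baseline_a3,0.006,baseline free fraction (printed 0.6%)
f18_block_0.1_a3,0.014,blocking free fraction (printed 1.4%)
f18_block_0.1_a4,0.015,blocking free fraction (printed 1.5%)
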