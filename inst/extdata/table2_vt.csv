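region,c11_baseline_a1,c11_baseline_a2,c11_block_0.03_a1,c11_block_0.1_a2,c11_block_0.25_a1,f18_baseline_a3,f18_block_0.1_a3,f18_block_0.1_a4
frontal_cortex,2.60,2.09,2.34,1.15,4.43,0.87,0.94,0.96
temporal_cortex,2.10,1.68,2.08,7.33,2.61,0.72,0.44,0.62
occipital_cortex,2.26,1.57,1.98,1.02,2.54,0.84,0.70,0.79
cingulate,2.92,1.87,2.71,1.29,2.74,0.71,0.80,1.01
insula,2.25,1.65,2.38,0.98,2.78,0.39,0.53,0.68
caudate,2.31,1.54,1.96,1.03,2.19,0.39,0.64,0.76
putamen,2.16,1.61,2.01,1.01,2.25,0.54,0.70,0.84
pallidum,2.19,1.39,2.23,1.14,1.95,0.49,0.67,0.78
hippocampus,2.29,1.61,1.75,1.50,2.47,0.65,0.50,0.58
amygdala,1.87,1.71,1.71,n.d.,3.40,0.45,0.19,0.37
thalamus,2.03,1.56,1.91,1.03,2.16,0.52,0.44,0.71
pons,1.88,1.48,1.94,2.31,2.34,0.75,0.68,0.76
cerebellum,2.08,1.59,1.84,0.94,2.53,0.63,0.59,0.69
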