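class,tp,fp,fn,tn,accuracy_pct,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,kappa
lipid,100,18,2,98,90.8,98.0,84.5,84.7,98.0,0.817
lipid_rich_plaque,73,13,3,129,92.7,96.1,90.8,84.9,97.7,0.843
calcium,47,11,6,154,92.2,88.7,93.3,81.0,96.3,0.795
side_branch,36,9,10,163,91.3,78.3,94.8,80.0,94.2,0.736
thrombus,19,3,2,194,97.7,90.5,98.5,86.4,99.0,0.871
plaque_rupture,5,9,1,203,95.4,83.3,95.8,35.7,99.5,0.480
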