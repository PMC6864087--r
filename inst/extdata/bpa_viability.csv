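# LN229 glioblastoma cell viability (MTT, % of vehicle control) transcribed
# from running text and figure captions. sd_cv is blank where only a mean is
# printed in the text.
compound_id,concentration_um,mean_cv,sd_cv
PP1,25,1.04,
PP1,10,43.67,1.88
PP1,5,70.03,2.04
PP1,1,98.36,1.61
HR4,25,58.5,
HR5,25,90.47,
HR9,25,35.55,
HR32,25,0.17,
HR32,10,41.49,7.94
HR32,5,77.76,7.24
HR32,1,96.80,6.51
HR35,10,56.26,0.59
HR35,5,79.34,1.70
HR35,1,93.64,2.08
HR36,25,98,
HR46,10,51.97,10.27
HR46,5,86.15,8.50
HR46,1,103.00,2.98
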