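# Calibration table for the synthetic ground-truth generator: per-region
# standardized coefficients of the final norm model (published multi-ethnic
# elderly volumetric norms), with model RMSE (cm3; log10 units for
# ventricular rows) and R2. Columns follow the final-model design order.
region,rmse,r2,ethnicity,age,sex,icv,icv2,icv3,mfs,manuf_ge,manuf_philips,eth_age,eth_sex,sex_age,mfs_ge,mfs_philips,mfs_icv,icv_ge,icv_philips
brain,44.42,0.78,-0.32,-0.29,-0.08,0.94,0.03,-0.09,-0.26,0.08,0.02,-0.01,0.07,-0.03,0.03,0.04,0.00,-0.01,-0.03
cortical_gm,22.14,0.71,-0.41,-0.23,-0.06,0.83,0.03,-0.10,-0.45,0.09,-0.02,-0.02,0.05,-0.02,0.03,0.07,0.00,-0.03,-0.04
frontal_l,4.45,0.61,-0.29,-0.18,-0.06,0.83,0.03,-0.10,-0.36,0.09,-0.03,-0.03,0.04,-0.02,-0.03,0.05,-0.01,-0.03,-0.03
frontal_r,4.51,0.62,-0.33,-0.19,-0.05,0.83,0.02,-0.10,-0.37,0.10,-0.02,-0.01,0.04,-0.03,-0.01,0.05,-0.01,-0.03,-0.03
temporal_l,3.31,0.63,-0.45,-0.33,-0.05,0.73,0.02,-0.08,-0.38,0.12,0.00,0.03,0.08,-0.02,0.03,0.06,0.01,-0.03,-0.04
temporal_r,3.22,0.63,-0.41,-0.30,-0.05,0.76,0.02,-0.08,-0.39,0.11,-0.01,0.01,0.07,-0.01,0.01,0.06,0.00,-0.03,-0.02
parietal_l,3.28,0.64,-0.44,-0.19,-0.10,0.76,0.03,-0.11,-0.51,0.05,-0.04,-0.03,0.04,-0.01,0.07,0.09,0.00,-0.03,-0.04
parietal_r,3.33,0.65,-0.44,-0.19,-0.09,0.76,0.03,-0.10,-0.51,0.06,-0.05,-0.04,0.05,-0.01,0.05,0.08,-0.01,-0.03,-0.04
occipital_l,1.98,0.50,-0.31,-0.25,-0.03,0.59,0.03,-0.08,-0.50,0.07,-0.03,-0.01,0.06,-0.01,0.06,0.09,0.01,-0.03,-0.05
occipital_r,2.01,0.51,-0.26,-0.24,0.00,0.63,0.02,-0.09,-0.48,0.04,-0.04,-0.02,0.05,-0.01,0.04,0.09,0.00,-0.03,-0.04
cingulate_l,1.02,0.46,-0.20,-0.17,-0.03,0.74,0.04,-0.09,-0.30,0.03,-0.02,-0.01,0.03,0.01,0.03,0.05,-0.03,-0.01,-0.03
cingulate_r,1.00,0.36,-0.31,-0.16,-0.03,0.65,0.01,-0.11,-0.25,0.09,0.05,0.00,0.02,0.01,-0.02,0.00,0.01,-0.02,-0.04
insular_l,0.45,0.41,-0.31,-0.05,0.00,0.68,0.01,-0.07,-0.14,0.11,0.02,-0.01,0.03,-0.01,-0.02,0.01,0.01,-0.01,-0.03
insular_r,0.47,0.44,-0.38,-0.07,0.05,0.61,0.01,-0.05,-0.19,0.06,0.01,0.01,0.03,-0.01,0.00,0.02,0.04,-0.01,-0.02
subcortical_gm,3.10,0.53,-0.25,-0.32,-0.03,0.68,0.01,-0.05,-0.32,0.01,0.01,0.03,0.06,-0.02,0.04,0.05,0.03,-0.01,-0.02
thalamus_l,0.80,0.38,-0.47,-0.13,-0.08,0.53,0.01,-0.06,-0.32,0.02,0.03,-0.01,0.06,-0.02,0.10,0.04,0.01,0.00,-0.01
thalamus_r,0.53,0.46,-0.44,-0.17,-0.05,0.60,0.03,-0.04,-0.17,-0.12,0.01,-0.03,0.04,-0.02,0.15,0.02,0.02,-0.03,-0.01
putamen_l,0.64,0.19,0.13,-0.24,0.01,0.33,-0.02,0.01,-0.17,-0.05,-0.04,0.06,0.01,-0.02,0.04,0.04,0.00,0.00,-0.02
putamen_r,0.54,0.20,0.08,-0.28,0.06,0.30,-0.01,0.01,-0.14,0.05,-0.03,0.08,0.01,-0.02,-0.07,0.02,0.03,0.01,-0.05
hippocampus_l,0.39,0.34,-0.28,-0.43,-0.05,0.33,0.00,-0.06,-0.33,0.06,0.05,0.02,0.05,0.00,0.03,0.00,0.04,0.00,-0.02
hippocampus_r,0.41,0.40,-0.34,-0.43,-0.06,0.34,-0.02,-0.03,-0.40,0.01,0.06,0.04,0.07,0.00,0.08,0.03,0.03,-0.02,-0.02
caudate_l,0.39,0.20,-0.08,-0.04,-0.13,0.54,0.00,-0.03,0.00,0.01,-0.04,0.04,0.00,0.00,-0.04,0.04,0.01,0.00,0.02
caudate_r,0.40,0.27,0.20,-0.07,-0.07,0.48,-0.01,0.00,0.07,0.05,-0.06,0.07,-0.01,-0.03,-0.11,0.02,0.04,-0.03,0.01
amygdala_l,0.19,0.40,-0.18,-0.31,0.06,0.28,-0.01,-0.03,-0.54,-0.04,0.02,0.04,0.04,-0.01,0.10,0.05,0.04,-0.02,-0.02
amygdala_r,0.20,0.38,-0.20,-0.28,0.10,0.33,-0.01,-0.04,-0.50,0.10,0.06,0.04,0.06,-0.01,0.03,0.04,0.02,-0.02,-0.03
pallidus_l,0.22,0.13,-0.04,0.07,0.05,0.30,0.02,0.03,0.00,-0.09,0.01,-0.06,-0.03,0.00,0.11,0.02,0.03,-0.03,-0.01
pallidus_r,0.18,0.22,-0.22,0.01,-0.06,0.43,-0.01,-0.02,-0.35,0.05,-0.02,-0.07,0.06,0.02,0.12,0.10,0.01,0.00,-0.02
accumbens_l,0.09,0.26,0.26,-0.38,-0.01,0.14,-0.02,-0.04,-0.14,0.16,-0.05,0.02,0.05,0.01,-0.14,0.02,0.06,-0.04,-0.04
accumbens_r,0.08,0.38,0.29,-0.32,0.07,0.20,-0.02,-0.04,-0.41,0.02,-0.02,0.01,0.02,0.00,-0.05,0.06,-0.02,0.00,-0.04
ventral_dc_l,0.29,0.44,-0.22,-0.11,0.01,0.66,0.02,-0.06,-0.28,0.00,0.00,0.00,0.08,-0.03,0.06,0.07,-0.01,-0.01,-0.03
ventral_dc_r,0.26,0.45,-0.14,-0.22,0.04,0.65,0.05,-0.08,-0.25,0.00,0.00,0.01,0.06,0.00,0.03,0.04,0.02,0.00,-0.02
stem,1.61,0.42,-0.12,-0.16,-0.06,0.70,0.02,-0.06,-0.06,-0.07,0.03,0.01,0.11,-0.03,0.11,0.02,0.01,-0.02,-0.03
corpus_callosum,0.36,0.20,-0.17,-0.28,-0.15,0.36,-0.04,-0.03,-0.27,-0.01,0.02,-0.02,0.06,0.00,0.06,0.04,0.02,0.00,-0.02
ventricle,0.15,0.45,0.00,0.49,0.02,0.47,0.00,0.01,-0.04,0.03,0.00,-0.05,-0.01,-0.04,0.01,0.00,0.02,0.01,0.00
lateral_l,0.16,0.42,-0.01,0.48,0.00,0.47,0.00,0.01,-0.04,0.02,0.00,-0.05,-0.01,-0.04,0.01,0.01,0.01,0.01,0.00
lateral_r,0.17,0.42,0.04,0.49,0.00,0.46,-0.01,0.01,-0.03,0.03,0.00,-0.06,-0.01,-0.04,0.00,0.00,0.03,0.00,0.01
inferior_lateral_l,0.23,0.39,-0.04,0.49,0.17,0.21,0.02,0.04,-0.02,0.02,-0.02,-0.02,-0.02,-0.02,0.06,0.04,0.03,-0.04,0.00
inferior_lateral_r,0.26,0.36,0.02,0.48,0.16,0.23,0.00,0.00,0.02,0.06,-0.06,-0.07,-0.01,0.00,0.03,0.02,0.05,-0.05,0.00
third_ventricle,0.12,0.44,-0.18,0.41,0.19,0.39,0.01,-0.01,-0.06,0.07,0.02,-0.01,-0.04,-0.04,0.04,0.00,0.02,-0.03,0.00
fourth_ventricle,0.12,0.14,-0.12,0.14,0.05,0.25,-0.01,0.07,-0.05,0.05,-0.01,-0.01,0.05,0.00,-0.06,-0.01,-0.02,0.03,0.02
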