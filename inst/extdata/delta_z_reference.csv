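# Reference delta-z values (mean z difference, AD minus CN) for the four
# race-by-diagnosis contrasts, before and after ethnicity adjustment, from
# published multi-ethnic elderly volumetric norms. Used to calibrate the
# default synthetic AD atrophy effects (after-adjustment Kor.AD vs Kor.CN
# column) and to exercise the discriminative-region selection rule.
# Contrast key: kk = Kor.AD vs Kor.CN, ck = Cau.AD vs Kor.CN,
#               kc = Kor.AD vs Cau.CN, cc = Cau.AD vs Cau.CN.
region,before_kk,before_ck,before_kc,before_cc,after_kk,after_ck,after_kc,after_cc
brain,-0.92,-1.75,-0.16,-0.99,-1.03,-1.20,-1.12,-1.28
cortical_gm,-0.88,-1.92,-0.12,-1.17,-1.02,-1.33,-1.27,-1.58
frontal_l,-0.62,-1.17,-0.17,-0.71,-0.65,-0.67,-0.87,-0.88
frontal_r,-0.60,-1.21,-0.03,-0.64,-0.64,-0.67,-0.81,-0.84
temporal_l,-1.22,-2.24,-0.56,-1.58,-1.42,-1.74,-1.69,-2.02
temporal_r,-1.02,-2.20,-0.38,-1.57,-1.15,-1.71,-1.40,-1.96
parietal_l,-0.64,-1.75,0.16,-0.95,-0.73,-1.12,-0.95,-1.33
parietal_r,-0.61,-1.78,0.20,-0.97,-0.71,-1.15,-0.90,-1.35
occipital_l,-0.39,-0.99,0.06,-0.54,-0.41,-0.53,-0.56,-0.68
occipital_r,-0.46,-1.02,-0.05,-0.60,-0.47,-0.62,-0.57,-0.72
cingulate_l,-0.58,-1.01,-0.18,-0.61,-0.59,-0.70,-0.59,-0.69
cingulate_r,-0.33,-0.87,0.12,-0.42,-0.34,-0.42,-0.47,-0.55
insular_l,-0.65,-1.10,-0.08,-0.54,-0.67,-0.65,-0.70,-0.68
insular_r,-0.61,-1.16,0.12,-0.43,-0.65,-0.62,-0.63,-0.60
subcortical_gm,-1.03,-1.78,-0.51,-1.25,-1.07,-1.46,-0.98,-1.37
thalamus_l,-0.37,-0.88,0.48,-0.03,-0.40,-0.25,-0.34,-0.19
thalamus_r,-0.41,-1.06,0.50,-0.15,-0.44,-0.42,-0.36,-0.33
putamen_l,-0.38,-0.38,-0.60,-0.60,-0.39,-0.60,-0.34,-0.55
putamen_r,-0.52,-0.72,-0.63,-0.83,-0.53,-0.89,-0.43,-0.79
hippocampus_l,-1.69,-2.46,-1.24,-2.01,-1.75,-2.15,-1.76,-2.17
hippocampus_r,-1.59,-2.37,-1.05,-1.82,-1.68,-2.02,-1.69,-2.02
caudate_l,0.02,-0.40,0.18,-0.24,0.02,-0.29,0.05,-0.26
caudate_r,-0.13,-0.13,-0.45,-0.44,-0.15,-0.46,-0.07,-0.38
amygdala_l,-1.16,-1.97,-0.93,-1.74,-1.18,-1.75,-1.25,-1.82
amygdala_r,-0.97,-1.80,-0.79,-1.62,-0.99,-1.57,-1.11,-1.69
pallidus_l,0.14,-0.06,0.34,0.15,0.15,0.04,0.22,0.11
pallidus_r,-0.13,-0.47,0.25,-0.10,-0.12,-0.18,-0.10,-0.16
accumbens_l,-0.77,-0.45,-1.38,-1.05,-0.81,-0.93,-0.87,-0.98
accumbens_r,-0.57,-0.44,-1.16,-1.03,-0.61,-0.99,-0.58,-0.96
ventral_dc_l,-0.26,-0.59,0.06,-0.28,-0.26,-0.31,-0.28,-0.33
ventral_dc_r,-0.46,-0.65,-0.20,-0.39,-0.46,-0.47,-0.41,-0.42
stem,-0.47,-0.48,-0.40,-0.41,-0.47,-0.40,-0.49,-0.41
corpus_callosum,-0.77,-0.67,-0.58,-0.47,-0.77,-0.47,-0.82,-0.52
ventricle,1.02,0.97,0.90,0.86,1.02,1.00,0.86,0.84
lateral_l,0.93,0.87,0.87,0.81,0.93,0.92,0.80,0.79
lateral_r,0.90,0.91,0.69,0.70,0.90,0.88,0.72,0.70
inferior_lateral_l,1.35,1.42,1.35,1.42,1.35,1.53,1.22,1.39
inferior_lateral_r,1.30,1.43,1.25,1.38,1.31,1.43,1.24,1.37
third_ventricle,0.75,0.28,1.17,0.70,0.78,0.65,0.76,0.63
fourth_ventricle,0.32,-0.17,0.42,-0.07,0.32,-0.04,0.26,-0.10
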