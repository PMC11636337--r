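disease_site,fractions,dose_per_fraction_gy,n_patients
adrenal_gland,5,8,1
adrenal_gland,5,4,1
prostate,5,7.25,11
prostate,5,8,1
pancreas,5,10,1
pancreas,5,7,1
pancreas,5,8,3
liver,3,15,1
oligometastases,3,10,1
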