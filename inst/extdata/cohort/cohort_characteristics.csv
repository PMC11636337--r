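characteristic,level,n
sex,male,19
sex,female,2
cied_type,pacemaker,12
cied_type,icd,6
cied_type,pacemaker_icd,3
cied_type,monitor,0
pacing_dependence,dependent,9
pacing_dependence,independent,6
pacing_dependence,not_applicable,6
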