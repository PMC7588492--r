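channel,default,unit
creatinine,1.0,mg/dl
urea,35,mg/dl
urine_flow,80,ml/h
map,75,mmHg
heart_rate,80,bpm
lactate,1.3,mmol/l
hemoglobin,11,g/dl
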