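label,anterior_mm,lateral_mm,scalp
FL1,4.5,-1.5,TRUE
FR1,4.5,1.5,TRUE
FL2,1.5,-4.5,TRUE
FR2,1.5,4.5,TRUE
PL1,-1.5,-4.5,TRUE
PR1,-1.5,4.5,TRUE
PL2,0.0,-4.5,TRUE
PR2,0.0,4.5,TRUE
LFL,-4.5,-1.5,TRUE
RFR,-4.5,1.5,TRUE
LPL,-3.0,-4.5,TRUE
RPR,-3.0,4.5,TRUE
REF,NA,NA,FALSE
GND,NA,NA,FALSE
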