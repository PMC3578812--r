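patient_id,diagnosis,day,quadratic,one_sided,n_hours
NOpC_001,NOpC,day1,0.07614473387,0.08695652174,23
NOpC_002,NOpC,day1,0.07493690652,0.1739130435,23
OpC_001,OpC,day1,0.06205659969,0.04347826087,23
OpC_002,OpC,day1,0.05698506259,0.08695652174,23
OpC_002,OpC,day2,0.03657650149,0,24
NOpG_001,NOpG,day1,0.03253015487,0,23
NOpG_001,NOpG,day2,0.02112504445,0,24
NOpG_002,NOpG,day1,0.05145040197,0.04347826087,23
OpG_001,OpG,day1,0.04654091045,0,23
OpG_001,OpG,day2,0.02498643524,0,24
OpG_001,OpG,day3,0.02032302992,0,24
OpG_001,OpG,day4plus,0.0262151526,0,14
OpG_002,OpG,day1,0.03474526693,0,23
NOpO_001,NOpO,day1,0.03420087187,0,23
NOpO_002,NOpO,day1,0.05800228164,0.08695652174,23
OpO_001,OpO,day1,0.03814786673,0,23
OpO_002,OpO,day1,0.06075732282,0.04347826087,23
OpO_002,OpO,day2,0.03425264723,0,24
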