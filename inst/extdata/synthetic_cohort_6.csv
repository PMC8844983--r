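patient_id,source,rank,code,label,probability,less_probable
P1,therapist,,F40.01,,,FALSE
P1,therapist,,F40.2,,,FALSE
P1,checker,1,,Panic disorder,7,FALSE
P1,checker,2,F45.0,,5,FALSE
P1,checker,3,F17.2,,3,FALSE
P2,therapist,,F32.2,,,FALSE
P2,checker,1,F33.2,,8,FALSE
P2,checker,2,,Burnout,6,FALSE
P3,therapist,,F45.1,,,FALSE
P3,checker,1,F41.1,,6,FALSE
P3,checker,2,F45.1,,4,FALSE
P4,therapist,,F10.2,,,FALSE
P4,therapist,,F32.0,,,FALSE
P4,checker,1,F10.1,,7,FALSE
P4,checker,2,F32.8,,5,FALSE
P5,therapist,,F41.1,,,FALSE
P5,checker,1,F43.1,,6,FALSE
P5,checker,2,F50.0,,5,FALSE
P5,checker,3,F45.0,,4,FALSE
P5,checker,4,F40.1,,2,TRUE
P5,checker,5,F41.1,,1,TRUE
P6,therapist,,F60.31,,,FALSE
P6,checker,1,F32.1,,5,FALSE
P6,checker,2,F41.0,,3,FALSE
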