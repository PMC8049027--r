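>Ptm_salmine_A1 protamine (salmine A1), 32 aa, 21 Arg, net charge +21 e
PRRRRSSSRPVRRRRRPRVSRRRRRRGGRRRR
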