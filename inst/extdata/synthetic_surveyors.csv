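surveyor_id,experience
E1,expert
E2,expert
E3,expert
E4,expert
E5,expert
E6,expert
V1,novice
V2,novice
V3,novice
V4,novice
V5,novice
V6,novice
V7,novice
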