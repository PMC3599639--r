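cd4_range,annual_care_cost_usd,utility
<50,33007,0.853
50-199,14964,0.861
200-349,8216,0.889
350-499,5758,0.913
>=500,4535,0.934
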