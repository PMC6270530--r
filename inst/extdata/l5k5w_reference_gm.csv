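# Tabulated (rounded to one decimal) geometric-mean MICs, ug/mL, as
# published for the L5K5W panel.  The W6 row is internally inconsistent
# with its published MICs (see package documentation).
# schema: reference_gm v1
peptide_id,gm_gram_positive,gm_gram_negative,gm_all
W1,2.4,3.0,2.7
W2,2.4,2.3,2.3
W3,2.8,3.5,3.2
W4,2.4,3.5,2.9
W5,2.0,2.6,2.3
W6,2.8,3.5,3.2
W7,2.4,3.0,2.7
W8,3.4,4.6,4.0
W9,2.4,2.3,2.3
W10,1.2,1.7,1.5
W11,2.4,3.5,2.9
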