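# Tabulated minimal hemolytic concentrations (ug/mL) and pseudo-therapeutic
# indices TI' = MHC / GM (one decimal) for the L5K5W panel, as published.
# schema: reference_mhc_ti v1
peptide_id,mhc,ti_prime_positive,ti_prime_negative,ti_prime_all
W1,32,13.5,10.6,11.8
W2,16,6.7,7.0,6.9
W3,64,22.6,18.4,20.2
W4,128,53.8,36.8,43.5
W5,64,32.0,24.3,27.4
W6,32,11.3,9.2,10.1
W7,128,53.8,42.2,47.0
W8,128,38.1,27.9,32.0
W9,64,26.9,27.9,27.4
W10,32,26.9,18.4,21.8
W11,128,53.8,36.8,43.5
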