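# Canonical gestational eGFR parameter set (version 1)
# bsc: pre-implantation baseline serum creatinine, umol/L
# normal_gfr: absolute normal GFR of non-pregnant women, mL/min
#   (110.1 mL/min/1.73 m2 de-indexed to a 1.62 m2 body surface area)
# median_curve: gestational median SCr polynomial, ascending powers of GW
version: 1
bsc: 55.25
normal_gfr: 103.1
median_curve:
  coefficients: [56.7, -0.223, -0.113, 0.00545, -0.0000653]
  domain: [4, 41]
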