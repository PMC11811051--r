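name: miR-2022
loop: GUUGUCA
arm_order: STAR_5PRIME_GUIDE_3PRIME
star_mismatch_positions: [1, 8, 9, 17]
fixed_guide_bases:
  "19": C
guide_5prime_base: U
guide_length: 21
overhang: 2
star_overhang: UG
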