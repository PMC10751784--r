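# Example metal parameter overrides for molybdenum complexes.
# Mo compounds in protein pockets interact mostly with cysteines and
# tyrosines; the covalent-like Mo-HD 12-6 term dominates, the Mo-SA well
# is shallow. Format: TYPE_I TYPE_J EPS(kcal/mol) RMIN(A) EXPONENTS
Mo HD 5.62 1.00 12-6
Mo SA 0.17 2.30 12-10
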