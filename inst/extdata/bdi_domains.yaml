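# Default assignment of the 21 BDI-II items to three symptom domains
# (one published three-factor solution; editable — the instrument itself
# does not fix a unique partition).
cognitive: [2, 3, 5, 6, 7, 8, 9, 13, 14]
affective: [1, 4, 10, 11, 12, 17]
somatic: [15, 16, 18, 19, 20, 21]
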