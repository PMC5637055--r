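# miRNAs associated with hair-follicle development and cycling,
# retained by the ceRNA screen's rule (ii).
miR-148b
miR-183
miR-184
miR-196a
miR-199a
miR-21
miR-24
miR-200
miR-200b
miR-203
miR-205
miR-214-3p
miR-221
miR-222
miR-31
miR-34a
miR-34c
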