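gene	variant_class
DNMT3A	any
TET2	any
ASXL1	any
JAK2	missense_hotspot
SRSF2	missense_hotspot
SF3B1	missense_hotspot
TP53	any
PPM1D	truncating
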