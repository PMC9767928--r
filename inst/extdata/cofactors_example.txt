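# Example cofactor/nucleotide class list for filter_network() /
# `metafoot filter --cofactors`. One identifier per line; species ids
# (compartment-tagged) and base names both match.
atp
adp
amp
gtp
gdp
nad
nadh
nadp
nadph
fad
fadh2
coa
h2o
h
pi
ppi
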