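# Example triage configuration: the package defaults, written out.
maf_threshold: 0.01
vaf_low: 0.35
vaf_high: 0.65
gq_min_exclusive: 30
insilico_vote_min: 3
splice_vote_min: 2
cadd_min: 20
revel_min: 0.5
eigen_min: 0
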