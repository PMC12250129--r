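# Toy 5-organ S-matrix fixture, mGy/(MBq h); synthetic values for testing
# the MIRD dose sum, not phantom Monte-Carlo output.
target,source,S_mGy_per_MBq_h
kidney,kidney,0.2575
liver,liver,0.0403
spleen,spleen,0.4207
lung,lung,0.0770
remainder,remainder,0.0012
kidney,liver,0.0004
liver,kidney,0.0004
spleen,kidney,0.0006
kidney,spleen,0.0006
remainder,kidney,0.0001
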