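# Desk-scale "European-like" two-epoch demographic model.
# Columns: epoch start (generations, backwards from present), Ne
# (pairwise-coalescent scale: a pair coalesces at rate 1/Ne per
# generation). Recent growth: Ne 10000 for the last 300 generations,
# ancestral Ne 2500.
0 10000
300 2500
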