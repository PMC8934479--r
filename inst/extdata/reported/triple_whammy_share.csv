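year,triple_whammy,total_alerts,printed_share
2016,9767,11035,89
2017,4123,5153,80
2018,3260,4460,73
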