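year,mrp_count,active_prescriptions,printed_pct
2016,210916,9500000,2.2
2017,227856,9600000,2.4
2018,230959,9700000,2.4
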