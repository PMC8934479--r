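year,duplicate_therapy,aemps_alert,polymedication,printed_total
2016,5413,6815,5130,17358
2017,4892,2160,603,7655
2018,3485,1735,2915,8135
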