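year,alert,baseline,final,printed_variation,printed_pct
2016,triple_whammy,9767,3356,-6411,-66
2017,triple_whammy,4123,2242,-1881,-46
2018,triple_whammy,3260,1850,-1410,-43
2016,coxibs,407,282,-125,-31
2017,coxibs,349,240,-109,-31
2018,coxibs,384,283,-101,-26
2016,diclofenac,325,144,-181,-56
2017,diclofenac,189,109,-80,-42
2018,diclofenac,189,96,-93,-49
2016,aceclofenac,82,60,-22,-27
2017,aceclofenac,69,43,-26,-38
2018,aceclofenac,51,28,-23,-45
2016,cilostazol,115,105,-10,-9
2017,cilostazol,107,82,-25,-23
2018,cilostazol,101,78,-23,-23
2016,ivabradine,102,88,-14,-14
2017,ivabradine,87,73,-14,-16
2016,agomelatine,74,62,-12,-16
2017,agomelatine,78,69,-9,-12
2016,escitalopram,55,51,-4,-7
2016,citalopram,41,34,-7,-17
2017,citalopram,48,47,-1,-2
2016,trimetazidine,40,27,-13,-33
2017,trimetazidine,34,24,-10,-29
2016,raloxifene_bazedoxifene,14,9,-5,-36
2017,raloxifene_bazedoxifene,10,7,-3,-30
2016,aliskiren,5,4,-1,-20
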