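year,category,baseline,final,printed_variation,printed_pct
2016,duplicate_therapy,46242,41589,-4653,-10
2016,aemps_alert,13521,6849,-6672,-49
2016,contraindication_clinical,37359,37421,62,0
2016,duration_bisphosphonate,8246,7434,-812,-10
2016,duration_dapt,4805,4332,-473,-10
2016,geriatric_inadvisable,88393,83638,-4755,-5
2016,anticholinergic_combination,2913,2320,-593,-20
2016,avoidable_medication,30984,27333,-3651,-12
2016,total,232463,210916,-21547,-9
2017,duplicate_therapy,65679,59536,-6143,-9
2017,aemps_alert,11212,9935,-1277,-11
2017,contraindication_clinical,44687,44000,-687,-2
2017,duration_bisphosphonate,6386,4964,-1422,-22
2017,duration_dapt,4394,4508,114,3
2017,geriatric_inadvisable,82252,79187,-3065,-4
2017,anticholinergic_combination,2184,1819,-365,-17
2017,avoidable_medication,26986,23907,-3079,-11
2017,total,243780,227856,-15924,-7
2018,duplicate_therapy,65377,64650,-727,-1
2018,aemps_alert,7046,5441,-1605,-23
2018,contraindication_clinical,45175,46469,1294,3
2018,duration_bisphosphonate,4552,4123,-429,-9
2018,duration_dapt,4631,4630,-1,0
2018,geriatric_inadvisable,79225,79384,159,0
2018,anticholinergic_combination,1854,1736,-118,-6
2018,avoidable_medication,25491,24526,-965,-4
2018,total,233351,230959,-2392,-1
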