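drug_code,name,component_principles,group_tags
N06AB04,citalopram,citalopram,qt_prolonging
N06AB10,escitalopram,escitalopram,qt_prolonging
C01BD01,amiodarone,amiodarone,qt_prolonging
N05AD01,haloperidol,haloperidol,qt_prolonging
C09XA02,aliskiren,aliskiren,ras_inhibitor
C09AA02,enalapril,enalapril,ace_inhibitor|ras_inhibitor|dup:ras_inhibitors
C09AA03,lisinopril,lisinopril,ace_inhibitor|ras_inhibitor|dup:ras_inhibitors
C09CA01,losartan,losartan,ras_inhibitor|dup:ras_inhibitors
B01AC23,cilostazol,cilostazol,antiplatelet
B01AC06,acetylsalicylic acid,acetylsalicylic_acid,antiplatelet
B01AC04,clopidogrel,clopidogrel,antiplatelet
B01AA07,acenocoumarol,acenocoumarol,oral_anticoagulant
C01EB15,trimetazidine,trimetazidine,
G03XC01,raloxifene,raloxifene,
G03XC02,bazedoxifene,bazedoxifene,
M01AH01,celecoxib,celecoxib,coxib|nsaid|dup:anti_inflammatories
M01AH05,etoricoxib,etoricoxib,coxib|nsaid|dup:anti_inflammatories
M01AB05,diclofenac,diclofenac,nsaid|dup:anti_inflammatories
M01AB16,aceclofenac,aceclofenac,nsaid|dup:anti_inflammatories
M01AE01,ibuprofen,ibuprofen,nsaid|dup:anti_inflammatories
M01AE02,naproxen,naproxen,nsaid|dup:anti_inflammatories
N06AX22,agomelatine,agomelatine,
C01EB17,ivabradine,ivabradine,
C08DA01,verapamil,verapamil,
A10BK02,canagliflozin,canagliflozin,antidiabetic
A10BA02,metformin,metformin,antidiabetic
A10AB01,insulin human,insulin_human,antidiabetic|dup:insulins
A10AB05,insulin aspart,insulin_aspart,antidiabetic|dup:insulins
M05BX03,strontium ranelate,strontium_ranelate,
C03CA01,furosemide,furosemide,diuretic
C03AA03,hydrochlorothiazide,hydrochlorothiazide,diuretic|dup:thiazide_diuretics
C03BA11,indapamide,indapamide,diuretic|dup:thiazide_diuretics
M05BA04,alendronic acid,alendronic_acid,bisphosphonate
M05BA07,risedronic acid,risedronic_acid,bisphosphonate
A02BC01,omeprazole,omeprazole,dup:gastric_protectors
A02BC02,pantoprazole,pantoprazole,dup:gastric_protectors
N06AA09,amitriptyline,amitriptyline,anticholinergic|dup:antidepressants
N06AB05,paroxetine,paroxetine,dup:antidepressants
G04BD04,oxybutynin,oxybutynin,anticholinergic|dup:urinary_antispasmodics
G04BD08,solifenacin,solifenacin,dup:urinary_antispasmodics
N05BA01,diazepam,diazepam,dup:benzodiazepines_long
N05BA05,potassium clorazepate,clorazepate,dup:benzodiazepines_long
R03BA01,beclometasone,beclometasone,dup:inhaled_glucocorticoids
R03BA02,budesonide,budesonide,dup:inhaled_glucocorticoids
G04CA01,alfuzosin,alfuzosin,dup:alpha_blockers
G04CA02,tamsulosin,tamsulosin,dup:alpha_blockers
N02BE01,paracetamol,paracetamol,dup:paracetamol
N02BE05,propacetamol,propacetamol,dup:paracetamol
N02BE51,paracetamol combination,paracetamol|caffeine,dup:paracetamol
N05CF02,zolpidem,zolpidem,geriatric_inadvisable
N06BX06,citicoline,citicoline,avoidable
M01AX05,glucosamine,glucosamine,avoidable
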