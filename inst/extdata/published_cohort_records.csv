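id,site,sex,age_class,acd,period,enamel_tooth,enamel_sr,bone_sr,bone_d13c,bone_d15n,dentine_bulk_d13c,dentine_bulk_d15n
STB_228,STB,female,mature,TRUE,around_500AD,unknown,-,0.70883,-18.7,9.0,-,-
STB_300,STB,female,mature,FALSE,around_500AD,unknown,0.71135,0.70921,-19.9,8.8,-18.9,9.5
STB_328,STB,female,mature,TRUE,around_500AD,unknown,0.70960,-,-19.6,8.8,-,-
STB_361,STB,female,mature,TRUE,around_500AD,unknown,0.70953,0.70921,-19.6,9.2,-15.3,10.0
STB_395,STB,male,senile,FALSE,around_500AD,unknown,0.71372,-,-20.0,10.2,-,-
STB_535,STB,female,mature,TRUE,around_500AD,unknown,0.70923,0.70919,-20.1,9.1,-16.0,9.2
AED_94,AED,female,mature,FALSE,around_500AD,unknown,0.71211,-,-20.0,8.7,-,-
AED_125,AED,female,mature,TRUE,around_500AD,unknown,0.70908,0.70913,-19.3,9.3,-16.8,10.3
AED_160,AED,female,senile,FALSE,around_500AD,unknown,0.71481,-,-20.4,9.6,-,-
AED_201,AED,female,mature,FALSE,around_500AD,unknown,0.71475,0.70937,-20.0,9.0,-,-
AED_211,AED,female,mature,FALSE,around_500AD,unknown,0.71308,0.71090,-19.3,9.3,-19.4,11.7
AED_321,AED,male,mature,FALSE,around_500AD,unknown,0.71238,-,-19.9,8.8,-,-
AED_343,AED,female,mature,FALSE,around_500AD,unknown,0.71345,-,-19.1,7.9,-17.3,9.6
AED_344,AED,male,mature,FALSE,around_500AD,unknown,0.71130,-,-19.3,9.6,-19.7,9.7
AED_421,AED,female,senile,FALSE,around_500AD,unknown,0.71092,-,-20.0,11.2,-,-
AED_487,AED,male,mature,FALSE,around_500AD,unknown,0.71150,0.70935,-19.5,9.7,-,-
AED_492,AED,male,mature,FALSE,around_500AD,unknown,0.71161,-,-19.5,8.9,-19.8,9.6
AED_501,AED,male,mature,FALSE,around_500AD,unknown,0.71358,0.71041,-19.4,9.9,-19.8,9.8
AED_513,AED,female,mature,TRUE,around_500AD,unknown,0.71006,0.70910,-16.8,9.1,-15.9,11.2
AED_521,AED,female,mature,FALSE,around_500AD,unknown,0.71320,-,-18.8,9.8,-,-
AED_1108,AED,female,senile,TRUE,around_500AD,unknown,0.70982,0.70950,-18.2,10.4,-,-
AED_1123,AED,male,senile,FALSE,around_500AD,unknown,0.71212,-,-19.8,9.6,-,-
AED_1135,AED,female,adult,FALSE,around_500AD,unknown,0.71183,0.70965,-20.3,10.1,-,-
AED_1143,AED,male,adult,FALSE,around_500AD,unknown,0.71309,-,-19.7,10.0,-19.6,9.0
AED_1350,AED,female,mature_senile,TRUE,around_500AD,unknown,0.71076,0.71019,-18.9,9.6,-,-
IRM_20,IRM,female,juvenile,FALSE,around_500AD,unknown,0.70750,-,-20.0,8.9,-,-
IRM_21,IRM,female,mature,FALSE,around_500AD,unknown,0.70714,0.70870,-19.9,9.0,-,-
IRM_33,IRM,female,mature,TRUE,around_500AD,unknown,-,-,-19.8,9.5,-,-
BWB_3734,BWB,male,adult,FALSE,around_500AD,unknown,0.71247,-,-21.0,9.2,-,-
BWB_3735,BWB,female,mature,FALSE,around_500AD,unknown,0.71426,-,-20.2,9.5,-,-
BWB_3739,BWB,female,mature,FALSE,around_500AD,unknown,0.71340,-,-19.8,8.7,-,-
BWB_3740,BWB,female,adult,FALSE,around_500AD,unknown,0.71373,-,-20.7,9.2,-,-
BWB_3741,BWB,female,mature,FALSE,around_500AD,unknown,0.71278,-,-20.9,9.0,-,-
BWA_10071,BWA,female,adult,FALSE,around_500AD,unknown,0.71076,-,-15.0,7.7,-14.2,8.4
BWA_10077,BWA,female,adult,FALSE,around_500AD,unknown,0.71297,0.70936,-20.2,9.7,-,-
BWA_10253,BWA,male,mature,FALSE,around_500AD,unknown,0.71309,0.70941,-19.7,9.3,-,-
BWA_10254,BWA,female,senile,TRUE,around_500AD,unknown,0.70873,0.70956,-19.5,10.0,-16.8,11.9
AEH_145,AEH,female,mature,TRUE,around_500AD,unknown,0.70979,0.70941,-19.4,10.0,-,-
PEL_12,PEL,female,adult,FALSE,around_500AD,unknown,0.70658,-,-19.1,8.2,-18.2,9.9
PEL_18,PEL,female,senile,FALSE,around_500AD,unknown,0.70866,-,-18.1,8.9,-,-
PEL_19,PEL,probable_female,infans_II,FALSE,around_500AD,unknown,0.70699,-,-19.1,8.2,-,-
PEL_22,PEL,male,adult_mature,FALSE,around_500AD,unknown,0.71247,-,-19.7,9.0,-,-
PEL_27,PEL,male,mature,FALSE,around_500AD,unknown,0.71300,-,-19.2,9.0,-,-
UTH_1,UTH,female,mature,FALSE,around_500AD,unknown,0.71156,-,-19.2,9.3,-,-
UTH_2,UTH,female,mature,FALSE,around_500AD,unknown,0.71214,-,-,-,-,-
UTH_6,UTH,male,mature_senile,FALSE,around_500AD,unknown,0.71068,0.70897,-19.5,9.0,-,-
UTH_7,UTH,male,mature,FALSE,around_500AD,unknown,0.71175,-,-19.7,9.3,-,-
UTH_8,UTH,female,mature,FALSE,around_500AD,unknown,0.71096,0.70863,-,-,-,-
UTH_9,UTH,female,adult_mature,FALSE,around_500AD,unknown,0.71195,-,-19.2,8.7,-,-
UTH_10,UTH,female,adult,FALSE,around_500AD,unknown,0.71241,-,-,-,-,-
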