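# Endometrial-cancer cohort cross-tabulations by race (WNH = non-Hispanic
# White reference group, BNH = non-Hispanic Black focus group), one row per
# cell of the published descriptive tables.
# NOTE: the 'surgery' BNH row (348 / 1210) duplicates the 'chemo' BNH row in
# the source table and is inconsistent with the published surgery log odds
# ratio (0.69756); the surgery table should not be used for coefficient
# reproduction.
variable,group,level,count
age,WNH,21-57,3198
age,WNH,58-64,2912
age,WNH,65-72,2949
age,WNH,73-99,2889
age,BNH,21-57,455
age,BNH,58-64,437
age,BNH,65-72,414
age,BNH,73-99,252
grade,WNH,1,5260
grade,WNH,2,3915
grade,WNH,3,2362
grade,WNH,4,411
grade,BNH,1,491
grade,BNH,2,410
grade,BNH,3,556
grade,BNH,4,101
stage,WNH,1,8588
stage,WNH,2,1119
stage,WNH,3,1675
stage,WNH,4,566
stage,BNH,1,968
stage,BNH,2,164
stage,BNH,3,276
stage,BNH,4,150
surgery,WNH,Hysterectomy,11582
surgery,WNH,No hysterectomy,366
surgery,BNH,Hysterectomy,348
surgery,BNH,No hysterectomy,1210
chemo,WNH,Chemo,1744
chemo,WNH,No chemo,10204
chemo,BNH,Chemo,348
chemo,BNH,No chemo,1210
insurance,WNH,"Insured, NOS",561
insurance,WNH,Medicaid,305
insurance,WNH,Medicare,5621
insurance,WNH,Military/VA/Tricare/IHS,229
insurance,WNH,Not insured,436
insurance,WNH,Private,4796
insurance,BNH,"Insured, NOS",48
insurance,BNH,Medicaid,120
insurance,BNH,Medicare,640
insurance,BNH,Military/VA/Tricare/IHS,33
insurance,BNH,Not insured,109
insurance,BNH,Private,608
marital,WNH,Divorced,1307
marital,WNH,Married,6679
marital,WNH,Separated,73
marital,WNH,Single,1907
marital,WNH,Unmarried or Domestic Partner,8
marital,WNH,Widowed,1974
marital,BNH,Divorced,205
marital,BNH,Married,574
marital,BNH,Separated,31
marital,BNH,Single,463
marital,BNH,Unmarried or Domestic Partner,0
marital,BNH,Widowed,285
histology,WNH,Carcinosarcoma,219
histology,WNH,Endometrioid Adenocarcinoma,11103
histology,WNH,Serous,613
histology,WNH,Undifferentiated,13
histology,BNH,Carcinosarcoma,77
histology,BNH,Endometrioid Adenocarcinoma,1280
histology,BNH,Serous,199
histology,BNH,Undifferentiated,2
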