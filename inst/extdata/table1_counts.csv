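subtype,variable,level,n_no_comorbidity,n_comorbidity
DLBCL,sex,male,12904,1748
DLBCL,sex,female,11365,1362
DLBCL,deprivation,least,5348,547
DLBCL,deprivation,q2,5586,652
DLBCL,deprivation,q3,5115,641
DLBCL,deprivation,q4,4665,676
DLBCL,deprivation,most,3555,594
DLBCL,route,elective,15495,1785
DLBCL,route,emergency,7547,1252
DLBCL,route,missing,1227,73
FL,sex,male,5980,532
FL,sex,female,6918,613
FL,deprivation,least,3091,193
FL,deprivation,q2,3025,203
FL,deprivation,q3,2759,254
FL,deprivation,q4,2356,253
FL,deprivation,most,1667,242
FL,route,elective,10332,889
FL,route,emergency,1518,209
FL,route,missing,1058,47
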