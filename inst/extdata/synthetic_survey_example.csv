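"enterprise_id","industry_code","industry_name","chemical_name","cas","oel_twa_ppm","oel_ceiling_ppm","carcinogen_no_oel","exposure_minutes","n_management","engineering_control","ppe"
"E0001","01","Plastic products","methylene chloride",,50,,0,30,4,"EEe","PPEn"
"E0001","01","Plastic products","N,N-dimethylformamide",,10,,0,10,4,"EEe","PPEn"
"E0001","01","Plastic products","toluene",,100,,0,250,4,"EEe","PPEn"
"E0002","01","Plastic products","synthetic ceiling-only agent",,,5,0,30,2,"EEn","PPEe"
"E0002","01","Plastic products","methylene bisphenyl isocyanate",,0.02,,0,10,2,"EEn","PPEe"
"E0002","01","Plastic products","toluene",,100,,0,480,2,"EEn","PPEe"
"E0003","01","Plastic products","acetone",,750,,0,225,3,"EEe","PPEe"
"E0003","01","Plastic products","synthetic ceiling-only agent",,,5,0,30,3,"EEe","PPEe"
"E0004","02","Foods","ethyl acetate",,400,,0,30,2,"EEp","PPEe"
"E0004","02","Foods","ethylene glycol",,50,,0,225,2,"EEp","PPEe"
"E0004","02","Foods","toluene",,100,,0,40,2,"EEp","PPEe"
"E0004","02","Foods","methyl ethyl ketone",,200,,0,10,2,"EEp","PPEe"
"E0005","02","Foods","toluene diisocyanate",,0.005,,0,75,4,"EEp","PPEe"
"E0006","02","Foods","ethylene glycol",,50,,0,225,1,"EEp","PPEe"
"E0006","02","Foods","toluene diisocyanate",,0.005,,0,48,1,"EEp","PPEe"
"E0007","03","Metal products","ethyl acetate",,400,,0,250,4,"EEe","PPEn"
"E0007","03","Metal products","N,N-dimethylformamide",,10,,0,225,4,"EEe","PPEn"
"E0008","03","Metal products","synthetic ceiling-only agent",,,5,0,48,2,"EEn","PPEn"
"E0008","03","Metal products","methylene bisphenyl isocyanate",,0.02,,0,40,2,"EEn","PPEn"
"E0008","03","Metal products","N,N-dimethylformamide",,10,,0,225,2,"EEn","PPEn"
"E0009","03","Metal products","toluene diisocyanate",,0.005,,0,30,3,"EEe","PPEn"
"E0009","03","Metal products","synthetic ceiling-only agent",,,5,0,10,3,"EEe","PPEn"
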