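location,system,is_cs_star,par_intercepted_mj_m2,pct_par_intercepted,et_mm,pct_of_rainfall,n_kg_ha
Bogra,aman rice,FALSE,838,13,560,32,276
Bogra,aman rice - boro rice,FALSE,1938,31,1279,72,748
Bogra,aman rice - rabi maize,FALSE,824,13,558,32,467
Bogra,kharif-II maize - rabi maize - aus rice,TRUE,3844,61,1524,86,769
Dhaka,boro rice,FALSE,1066,17,666,32,452
Dhaka,aman rice - boro rice,FALSE,1838,30,1202,59,677
Dhaka,aman rice - rabi maize,FALSE,792,13,524,26,471
Dhaka,kharif-II maize - rabi maize - aus rice,TRUE,3662,60,1493,73,746
Rajshahi,boro rice,FALSE,1069,17,795,54,286
Rajshahi,aman rice - boro rice,FALSE,1925,30,1372,94,567
Rajshahi,aman rice - boro rice - aus rice,FALSE,2661,41,1854,127,805
Rajshahi,aman rice - rabi maize,FALSE,856,13,577,40,462
Rajshahi,aman rice - rabi maize - kharif-I maize,TRUE,4443,69,1585,109,800
Rangpur,boro rice,FALSE,1169,18,759,33,521
Rangpur,aman rice - boro rice,FALSE,1999,32,1345,58,773
Rangpur,aman rice - rabi maize,FALSE,790,12,482,21,402
Rangpur,kharif-II maize - rabi maize - aus rice,TRUE,4117,65,1583,69,818
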