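location,sequence,csyp_star_t_ha,csyp_star_gj_ha,csyp_star_cv_pct,season,crop,variety,yp_t_ha,yp_gj_ha,start_date,end_date,start_doy,end_doy
Bogra,maize-maize-rice,33.0,486,7.5,kharif-II,maize,late,9.4,139,15-Jun,5-Sep,166,248
Bogra,maize-maize-rice,33.0,486,7.5,rabi,maize,late,16.2,240,1-Oct,6-Feb,274,37
Bogra,maize-maize-rice,33.0,486,7.5,aus,rice,short,7.4,107,3-Mar,25-May,62,145
Dhaka,maize-maize-rice,32.9,483,6.3,kharif-II,maize,late,9.0,133,1-Jun,24-Aug,152,236
Dhaka,maize-maize-rice,32.9,483,6.3,rabi,maize,late,13.9,206,15-Sep,31-Dec,258,365
Dhaka,maize-maize-rice,32.9,483,6.3,aus,rice,intermediate,10.0,144,14-Jan,6-May,14,126
Rajshahi,rice-maize-maize,32.5,480,5.3,aman,rice,short,4.9,71,1-Jul,8-Sep,182,251
Rajshahi,rice-maize-maize,32.5,480,5.3,rabi,maize,late,17.4,258,1-Oct,20-Feb,274,51
Rajshahi,rice-maize-maize,32.5,480,5.3,kharif-I,maize,late,10.2,151,15-Mar,9-Jun,74,160
Rangpur,maize-maize-rice,34.2,504,4.5,kharif-II,maize,late,9.5,141,15-Jun,7-Sep,166,250
Rangpur,maize-maize-rice,34.2,504,4.5,rabi,maize,late,18.0,266,1-Oct,21-Feb,274,52
Rangpur,maize-maize-rice,34.2,504,4.5,aus,rice,extra-short,6.7,97,17-Mar,26-May,76,146
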