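location,system,crop,n_crops,area_pct,ya_t_ha,yp_t_ha,cv_pct
Bogra,aman rice,total,1,25,2.2,9.1,6
Bogra,aman rice - boro rice,total,2,50,6.1,21.5,5
Bogra,aman rice - rabi maize,total,2,25,8.1,20.5,5
Dhaka,boro rice,total,1,40,4.3,12.1,4
Dhaka,aman rice - boro rice,total,2,40,5.8,20.2,4
Dhaka,aman rice - rabi maize,total,2,20,6.4,20.2,4
Rajshahi,boro rice,total,1,25,4.1,9.3,10
Rajshahi,aman rice - boro rice,total,2,25,6.7,18.5,8
Rajshahi,aman rice - boro rice - aus rice,total,3,25,8.9,26.8,7
Rajshahi,aman rice - rabi maize,total,2,25,7.2,21.2,6
Rangpur,boro rice,total,1,30,3.9,13.1,4
Rangpur,aman rice - boro rice,total,2,30,6.3,21.6,4
Rangpur,aman rice - rabi maize,total,2,40,9.3,20.2,5
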