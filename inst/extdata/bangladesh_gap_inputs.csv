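location,basis,csya,csyp,csyp_star
Bogra,t_ha,5.0,18.2,33.0
Dhaka,t_ha,5.0,17.0,32.5
Rajshahi,t_ha,6.0,19.0,32.9
Rangpur,t_ha,6.5,18.5,34.2
Bogra,gj_ha,82,259,486
Dhaka,gj_ha,77,244,483
Rajshahi,gj_ha,97,266,480
Rangpur,gj_ha,99,252,504
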