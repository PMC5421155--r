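location,annual_par_mj_m2,annual_rainfall_mm
Bogra,6252,1767
Dhaka,6145,2050
Rajshahi,6434,1459
Rangpur,6340,2303
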