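name,density,c_long,c_shear,alpha0_db_per_cm,f_ref_hz,alpha_exponent,K,G,E
water,1000,1480,0,0.0022,1e6,2,2.1904e9,0,
glass,2500,5600,3400,0.20,1e6,1,3.986667e10,2.89e10,6.98271e10
polystyrene,1050,2350,1120,0.35,1e6,1,4.042465e9,1.31712e9,3.56427e9
adiprene,880,1650,0,2.0,1e6,1,2.39580e9,0,
polyethylene,950,1950,950,1.1,1e6,1,2.469208e9,8.57375e8,2.30537e9
air,1.204,343,0,1.64,1e6,2,1.41649e5,0,
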