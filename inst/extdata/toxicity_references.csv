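element,rfd_mg_kg_day,slope_factor
As,1.2e-4,150
Cd,1e-5,6.3
Co,5.7e-6,9.8
Cr,2.8e-4,41
Cu,0.004,NA
Hg,8.6e-5,NA
Ni,0.02,NA
Pb,0.0035,0.042
Zn,0.3,1.5
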