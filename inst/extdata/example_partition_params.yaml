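# Example smoking-session partition parameters (assumed, not measured):
# ash_yield         mass fraction of the charge left as ash after burning
# water_volume_l    bowl water volume per session (L)
# tobacco_mass_kg   tobacco charge per session (kg)
ash_yield: 0.25
water_volume_l: 0.8
tobacco_mass_kg: 0.015
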