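# Lumped-parameter left-heart model parameters for the dissected and
# undissected aortic models. Canonical g-mm-s units throughout:
# volumes mm^3, pressures g/(mm s^2), elastances g/(mm^4 s^2),
# resistances g/(mm^4 s), inductances g/mm^4, k_LV s/mm^3.
parameter,dissected,undissected
period,1.3,1.3
end_diastolic_volume,130000,130000
unstressed_volume,0.0,0.0
preload,533.320,533.320
time_to_max_elastance,0.410,0.420
time_to_relaxation,0.205,0.210
max_elastance,0.460,0.400
min_elastance,4.102e-3,4.102e-3
aortic_valve_resistance,1.0e-5,1.0e-5
aortic_valve_inductance,1.0e-5,1.0e-5
ventricular_resistance_k,5.0e-7,5.0e-7
mitral_valve_resistance,3.9453e-7,3.9453e-7
mitral_valve_inductance,1.334e-5,1.334e-5
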