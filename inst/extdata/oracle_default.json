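{"baseline_strain":{"s6":2400,"s7":1750,"s8":1800,"s9":1600,"s10":1650,"s11":1450,"s12":1500},"gamma":{"s6":1.85,"s7":1.75,"s8":1.78,"s9":1.72,"s10":1.74,"s11":1.7,"s12":1.71},"self_coef":{"linear_dp":-0.00961234149403077,"quad_dp":0.000278690063754173,"linear_ap":0,"quad_ap":-0.000166666666666667},"cross_coef":{"linear_dp":-0.00632203223204512,"quad_dp":0.000369762979138053,"linear_ap":0,"quad_ap":-0.000127777777777778},"calcar_gain":3,"collision_inflation":0.15,"noise_cv":0.02,"modulus_scale_exponent":1,"rho_app":{"s6":0.25,"s7":0.25,"s8":0.25,"s9":0.25,"s10":0.25,"s11":0.25,"s12":0.25},"rho_ref":{"s6":0.25,"s7":0.25,"s8":0.25,"s9":0.25,"s10":0.25,"s11":0.25,"s12":0.25},"seed":20260101}
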