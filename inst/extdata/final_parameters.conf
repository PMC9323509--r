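# Calibrated cell-solute model constants, modeling units
# (kg/m3 for solutes, cell/m3 for cells, m2/s, 1/s, kg/cell/s)
D_c_gel = 4.98e-10
D_c_med = 2e-9
M_c = 5.88e-20
c_half = 5.13e-4
D_s_gel = 2.67e-10
D_s_med = 9e-11
M_s = 1.75e-18
s_half = 1.39
A = 4.6
D_v_gel = 4.16e-11
D_v_med = 1.32e-10
K_v = 8.37e-5
alpha = 2.92e-21
beta = 2.86e-22
c_tau = 4.49e-4
n_tau = 2.32e13
delta_0 = 3.18e-6
delta_c = 2.53e-6
delta_s = 5.6e-7
n_max = 6.0e13
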