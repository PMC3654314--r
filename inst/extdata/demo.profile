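# Small synthetic orthorhombic crystal on a reduced detector face:
# a complete simulate -> reduce run takes seconds, which makes this the
# standard end-to-end validation profile.
L = 530
n_x = 320
n_y = 240
c_x = 0.30
c_y = 0.004
x0 = 40
y0 = 120
xy_slope = 0.0041
arm_angle = 40
win_x_min = 10
win_y_min = 12
win_x_max = 310
win_y_max = 228
chi_mode = tan
wavelength = 1.5
phi_start = 0
delta_phi = 1
n_frames = 360
omega_offset = 0
cell_a = 5
cell_b = 7
cell_c = 9
cell_alpha = 90
cell_beta = 90
cell_gamma = 90
threshold = 4
box = 11
xy_tol = 1.5
gap_tol = 0
index_tol = 0.1
intensity = 10000
background = 0
sigma_x = 1.34
sigma_y = 1.13
sigma_phi = 0.6
noise = none
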