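# Curved-PSD instrument profile (HANARO-like machine constants)
# Channel-to-angle conversion factors, origin, channel-axis slope and the
# active window of the 512-channel readout mode; primary wavelength from
# the Ge(311) monochromator at the 39.5 degree take-off.
L = 530
n_x = 512
n_y = 512
c_x = 0.2614
c_y = 0.003917
x0 = 181.50
y0 = 94.135
xy_slope = 0.0041
arm_angle = 40
win_x_min = 60
win_y_min = 9.06
win_x_max = 460
win_y_max = 269.60
chi_mode = tan
wavelength = 1.153
phi_start = 0
delta_phi = 0.2
n_frames = 1800
omega_offset = 0
# NaCl calibration standard
cell_a = 5.6402
cell_b = 5.6402
cell_c = 5.6402
cell_alpha = 90
cell_beta = 90
cell_gamma = 90
threshold = 10
box = 11
xy_tol = 1.5
gap_tol = 0
index_tol = 0.1
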