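# Example run configuration: desk-scale four-condition study settings.
# Any key omitted here falls back to the package default; unknown keys
# are rejected.

[units]
sigma_SI = 1e-9            # 1 nm
tau_SI = 2e-9              # 2 ns
epsilon_SI = 3.890920e-21  # kB * 310 K / 1.1

[forcefield]
wc = 1.7
eps_np = 0.2
eps_receptor = 2.0

[protocol]
dt = 0.005
thermostat_tc = 0.5
barostat_tc = 5.0
temperature = 1.1
box_z = 120
n_steps = 60000
rotation_frequency = 0.0002   # 1/5000 tau^-1
robot_enabled = true
cargo_count = 30
receptor_fraction = 0.1

[robot]
core_radius = 1.5
n_spikes = 12
spike_length_range = [2.2, 3.2]
apex_angle_range = [5, 20]
bead_spacing = 1.0

[builder]
nx = 10
ny = 10
area_per_lipid = 1.2
seed = 301
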