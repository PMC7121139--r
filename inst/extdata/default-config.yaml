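n_total: 4000.0
dt: 1.0
duration: 10000.0
transient: 500.0
vt: -50.0
vr: -60.0
v_floor: -.inf
refractory: 5.0
v_init_low: -60.0
v_init_high: -50.0
tau_m: 20.0
tau_e: 20.0
tau_i: 9.0
seed: 1
method: exact
synapse: delta
populations:
- name: excitatory
  fraction: 0.85
  v0: -49.0
  pc: 0.1
  ws: 2.0
- name: leader
  fraction: 0.05
  v0: -46.0
  pc: 0.1
  ws: 2.0
- name: interneuron
  fraction: 0.1
  v0: -49.0
  pc: 0.2
  ws: -9.0
  tau_m: 9.0
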