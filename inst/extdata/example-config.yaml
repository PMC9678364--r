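# Example simulation configuration (all omitted keys fall back to the
# built-in defaults, i.e. the standard parameter tables).
geometry:
  shape: oblate
  diameter_nm: 4000
  height_nm: 400
  a0_nm: 100
G_uM: 40
formin_uM: 0.1
n_seed: 20
seed_monomers: 30
t_total: 800
dt_chem: 0.01
snapshot_every: 1
seed: 1
chem:
  k_on_BE: 34.8     # fast-treadmilling arm
  k_off_PE: 2.4
  k_destruction: 1.9
schedule:
  - time: 300
    action: add_species
    species: NMII
    conc_uM: 0.06
  - time: 300
    action: add_species
    species: linker
    conc_uM: 4
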