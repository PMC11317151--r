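# Demonstration pipeline configuration (flat key = value).
# All lengths in um, times in s, forces in pN, concentrations in nM.
stages = mt,kymo,binding
seed = 1
mt.n_beads = 5
mt.bridge_formation_prob = 1
mt.mean_lifetime_s = 26.3
mt.loop_min_um = 0.1
mt.loop_max_um = 0.5
mt.max_bridges = 1
kymo.n_kymographs = 10
kymo.diffusion_um2_s = 3.9
binding.kd_nM = 66
binding.n_boot = 200
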