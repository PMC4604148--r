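# Demo experiment: a cohort of simulated cells co-expressing a dissociating
# probe (gfp, enrichment decays 3 -> 1 after the event frame), a persistent
# probe (cfp, flat with a +5% drift) and a constant compartment marker
# (irfp). Run with: run_pipeline(system.file("extdata/demo_config.yaml",
# package = "punctacoloc"), out_dir)
seed: 7
n_cells: 6
n_frames: 12
event_frame: 4
frame_interval: 2      # minutes
nmdp_frame: 1
alpha: 0.05
scene:
  shape: [96, 96]
  n_spots: 25
  overlap_fraction: 0.8
  amplitude: 4000      # photons per spot
  background: 100      # photons per pixel inside the cell
  sigma: 1.5
  min_separation: 5
noise:
  poisson: true
  read_sd: 2
mask:
  k: 3
  min_size: 4
channels:
  - label: gfp
    role: probe
    conserve: true
    kinetics: {type: decay, from: 3, to: 1, tau: 2.5}
  - label: cfp
    role: probe
    conserve: true
    kinetics: {type: drift, value: 3, drift: 0.05}
  - label: irfp
    role: marker
    kinetics: {type: constant, value: 3}
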