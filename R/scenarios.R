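#' Canonical simulated experiments
#'
#' Prebuilt scene configurations for the three experiment archetypes the
#' package analyzes, so that tests, examples and the demo pipeline all run
#' the same study conditions.
#'
#' `scenario_coloc()` is a two-channel single-frame colocalization panel:
#' 40 puncta, a programmable fraction shared between the channels, moderate
#' spot brightness — the setting for nMDP scoring.
#'
#' `scenario_dissociation()` is a time-lapse in which the probe channel's
#' compartment enrichment decays from 3x to 1x after the event frame
#' (exponential, time constant `tau` frames), alongside a kinetically
#' constant compartment marker: a biosensor that loses its binding lipid
#' after drug addition. `scenario_persistence()` is the matched control in
#' which the probe's enrichment stays at 3x with a slight (+5% by the last
#' frame) upward drift: a probe whose localization is independent of the
#' perturbed lipid. Both enable probe-flux conservation, so probe released
#' from compartments reappears as cytosolic background. The probe is
#' strongly punctate (integrated 30000 photons per spot over a 100
#' photon/px cytosol, i.e. peak ~20x background — typical of an
#' overexpressed biosensor against its cytosolic pool) and the marker is
#' kept modest (2500 photons) so masks stay compact.
#'
#' @param seed Integer seed.
#' @param overlap_fraction Fraction of spots shared between the channels.
#' @param n_frames,event_frame Time-lapse length and perturbation frame.
#' @param tau Decay time constant in frames.
#' @param ... Overrides forwarded to [make_scene()].
#' @return A `synthetic_scene`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_coloc <- function(seed, overlap_fraction = 0.8, ...) {
  args <- utils::modifyList(
    list(shape = c(96L, 96L), channels = c("probe", "marker"),
         n_spots = 40L, overlap_fraction = overlap_fraction,
         amplitude = 2000, background = 100, seed = seed),
    list(...))
  do.call(make_scene, args)
}

#' @rdname scenarios
#' @export
scenario_dissociation <- function(seed, n_frames = 16L, event_frame = 5L,
                                  tau = 2.5, ...) {
  kin <- cbind(kinetic_decay(n_frames, event_frame, from = 3, to = 1,
                             tau = tau),
               kinetic_constant(n_frames, 1))
  scenario_timelapse(seed, kin, event_frame, ...)
}

#' @rdname scenarios
#' @export
scenario_persistence <- function(seed, n_frames = 16L, event_frame = 5L,
                                 ...) {
  kin <- cbind(kinetic_drift(n_frames, event_frame, value = 3, drift = 0.05),
               kinetic_constant(n_frames, 1))
  scenario_timelapse(seed, kin, event_frame, ...)
}

scenario_timelapse <- function(seed, kinetics, event_frame, ...) {
  args <- utils::modifyList(
    list(shape = c(128L, 128L), channels = c("probe", "marker"),
         n_spots = 12L, overlap_fraction = 1.0,
         amplitude = c(30000, 2500), background = 100,
         kinetics = kinetics, conserve_probe = c(TRUE, FALSE),
         min_separation = 6, event_frame = event_frame, seed = seed),
    list(...))
  do.call(make_scene, args)
}
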