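# Shared study definitions for the analysis drivers.
# Two synthetic systems over one code path:
#   "reference" — symmetric bundle, three contact channels at mixed rates
#   "perturbed" — same bundle with domain 1 rotated 10 degrees and the
#                 domain-1 channel weakened (lower k_on), mimicking the
#                 loss of a domain-1 anchor
# All seeds are fixed here; every driver regenerates its inputs
# deterministically instead of reading binary intermediates.

library(mgatekit)

STUDY_SEED <- 20260927L %% 100000L  # base seed for the whole study
N_FRAMES <- 3000L

study_channels <- function(system) {
  k_on1 <- if (system == "perturbed") 0.02 else 0.2
  list(channel_spec(3L, 65L, k_on1, 0.1),       # H1:H3 contact
       channel_spec(10L, 72L, 0.05, 0.05),      # H1:H3 contact
       channel_spec(123L, 25L, 0.5, 0.1))       # H5:H1 contact
}

study_spec <- function(system = c("reference", "perturbed")) {
  system <- match.arg(system)
  toy_carrier_spec(
    helix_length = 30L, n_frames = N_FRAMES, noise_sigma = 0.3,
    seed = STUDY_SEED + (system == "perturbed"),
    domain1_rotation = if (system == "perturbed") 10 else 0,
    channels = study_channels(system),
    # slab straddling the monitored H1:H3 charge-site interface
    solvent = solvent_spec(200L, x = c(-2, 9), y = c(0, 11), z = c(0, 9)))
}

study_config <- function() {
  as_mgate_config(list(
    helix_map = list(H1 = c(1, 30), H2 = c(31, 60), H3 = c(61, 90),
                     H4 = c(91, 120), H5 = c(121, 150), H6 = c(151, 180)),
    triplet_offsets = list(odd = c(0, 60, 120)),
    triplets = c(3, 10, 17, 25),
    interactions = list(list(type = "salt_bridge", a = 3, b = 65),
                        list(type = "salt_bridge", a = 10, b = 72),
                        list(type = "salt_bridge", a = 123, b = 25)),
    distance_pairs = list(list(name = "H1_H3_sites",
                               a = "resid 3 and name CS",
                               b = "resid 65 and name CS"))))
}

study_simulation <- function(system) {
  car <- build_toy_carrier(study_spec(system))
  sim <- simulate_trajectory(car)
  list(carrier = car, sim = sim)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
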