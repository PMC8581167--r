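# Shared fixtures: small, fast simulation configurations and a
# nearest-neighbour matcher against ground truth.

small_config <- function(n_colonies = 1, nuclei = 150, noise_sd = 5, ...) {
  sim_config(n_colonies_per_well = n_colonies, nuclei_per_colony = nuclei,
             noise_sd = noise_sd, ...)
}

# Distance from each ground-truth nucleus to its nearest detection (um).
nn_dist_to_truth <- function(detected, truth_nuclei) {
  vapply(seq_len(nrow(truth_nuclei)), function(i) {
    min(sqrt((detected$x_um - truth_nuclei$x_um[i])^2 +
               (detected$y_um - truth_nuclei$y_um[i])^2))
  }, numeric(1))
}

# Majority ground-truth colony for each detected colony's member nuclei.
membership_purity <- function(nuclei, truth_nuclei) {
  matched <- vapply(seq_len(nrow(nuclei)), function(i) {
    j <- which.min((truth_nuclei$x_um - nuclei$x_um[i])^2 +
                     (truth_nuclei$y_um - nuclei$y_um[i])^2)
    truth_nuclei$colony[j]
  }, numeric(1))
  tapply(matched, nuclei$colony, function(v) max(table(v)) / length(v))
}
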