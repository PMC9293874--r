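# Shared fixtures, built once per test session.

test_geom <- function() {
  if (is.null(.fixtures$geom)) .fixtures$geom <- default_geometry(20)
  .fixtures$geom
}

# ground truth with every nuisance and noise source switched off
noise_free_truth <- function(...) {
  ground_truth(drift_coef = rep(0, 5), cardiac_amp = 0, resp_amp = 0,
               motion_coupling = rep(0, 6), noise_sd = 0, subject_sd = 0,
               wm_amp = 0, vent_amp = 0, walk_sd = 0, spike_prob = 0, ...)
}

nf1_schedule <- function() {
  if (is.null(.fixtures$nf1)) .fixtures$nf1 <- build_run_schedule("NF1")
  .fixtures$nf1
}

# one noise-free NF1 subject, cached (several tests reuse it)
noise_free_subject <- function() {
  if (is.null(.fixtures$nf_sub)) {
    .fixtures$nf_sub <- generate_subject(list(NF1 = nf1_schedule()),
                                         test_geom(), noise_free_truth(),
                                         seed = 42)
  }
  .fixtures$nf_sub
}

# one full-noise NF1 subject, cached
noisy_subject <- function() {
  if (is.null(.fixtures$noisy_sub)) {
    .fixtures$noisy_sub <- generate_subject(list(NF1 = nf1_schedule()),
                                            test_geom(), ground_truth(),
                                            seed = 7)
  }
  .fixtures$noisy_sub
}

.fixtures <- new.env(parent = emptyenv())
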