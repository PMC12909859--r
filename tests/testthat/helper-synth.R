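# Shared fixtures, all generated in code.

# Small cohort config: full 5-condition schedule at reduced block length.
tiny_config <- function(n_dyads = 1, block_s = 10, seed = 1, ...) {
  synth_config(n_dyads = n_dyads, schedule = default_schedule(block_s),
               seed = seed, ...)
}

# Single-condition config, handy for connectivity-level checks.
one_block_config <- function(duration = 10, kappa = 0.5, seed = 1, ...) {
  synth_config(
    n_dyads = 1,
    schedule = data.frame(condition = "FP1", duration = duration),
    kappa = matrix(kappa, 1, 2,
                   dimnames = list("FP1", c("theta", "alpha"))),
    seed = seed, ...)
}

# Raw dyad -> screened hyper-epochs with the standard stages.
prep_epochs <- function(rec, ...) {
  rec |> filter_raw() |> select_channels() |> make_hyper_epochs(...) |>
    reject_artifacts()
}

# Bare phase_pair from explicit phase matrices.
make_phase_pair <- function(phi_m, phi_i, band = "theta", condition = "FP1",
                            epoch_index = 1L) {
  structure(list(phi_mother = phi_m, phi_infant = phi_i, band = band,
                 condition = condition, epoch_index = epoch_index),
            class = "phase_pair")
}

# Per-dyad global wPLI through the pipeline for one cohort; bands/epochs
# reduced for desk-scale experiments.
run_synth_cohort <- function(cfg, bands = "theta", n_surrogates = 0) {
  tabs <- lapply(seq_len(cfg$n_dyads), function(i) {
    g <- generate_dyad(cfg, i)
    ep <- prep_epochs(g$recording)
    dyad_synchrony(ep, bands = bands, n_surrogates = n_surrogates,
                   seed = cfg$seed + i)
  })
  as_cohort_table(tabs, bands = bands)
}

# Independent "white-phase" members: the exchangeable null of the
# time-permutation surrogate test (no temporal autocorrelation).
white_phase_pair <- function(nch = 12, n = 1024) {
  make_phase_pair(matrix(runif(nch * n, -pi, pi), nch),
                  matrix(runif(nch * n, -pi, pi), nch))
}
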