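test_that("wPLI analytic limits hold", {
  expect_equal(wpli_pair(rep(pi / 2, 100)), 1)
  expect_equal(wpli_pair(rep(c(pi / 2, -pi / 2), 50)), 0)
  expect_equal(wpli_pair(c(pi / 2, pi / 2, pi / 2, -pi / 2)), 0.5)
  expect_equal(wpli_pair(rep(0, 100)), 0)   # zero-lag convention
  expect_error(wpli_pair(numeric(0)), "empty")
})

test_that("PLV analytic limits hold", {
  expect_equal(plv_pair(rep(1.234, 50)), 1)
  expect_equal(plv_pair(rep(0, 50)), 1)     # PLV sees zero-lag coupling
  expect_equal(plv_pair(rep(c(pi / 2, -pi / 2), 50)), 0)
  set.seed(1)
  expect_lt(plv_pair(runif(1e5, -pi, pi)), 0.02)
})

test_that("vectorized wPLI and PLV match naive loops on random series", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(sample(50:500, 1), -pi, pi)
    expect_equal(wpli_pair(d), wpli_naive(d), tolerance = 1e-12)
    expect_equal(plv_pair(d), plv_naive(d), tolerance = 1e-12)
  }
})

test_that("the C++ pair-matrix kernel agrees with the R scalar path", {
  set.seed(8)
  pm <- matrix(runif(5 * 300, -pi, pi), 5)
  pi_ <- matrix(runif(4 * 300, -pi, pi), 4)
  res <- dyadsync:::.wpli_plv_matrices(pm, pi_)
  for (j in 1:5) for (k in 1:4) {
    d <- pm[j, ] - pi_[k, ]
    expect_equal(res$wpli[j, k], wpli_pair(d), tolerance = 1e-12)
    expect_equal(res$plv[j, k], plv_pair(d), tolerance = 1e-12)
  }
})

test_that("wPLI is bounded, and label-swap symmetric", {
  set.seed(9)
  for (i in 1:50) {
    d <- runif(200, -pi, pi)
    w <- wpli_pair(d)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(wpli_pair(-d), w, tolerance = 1e-12)  # swap members
  }
  # equality with 1 iff all sin(dphi) share one sign
  expect_equal(wpli_pair(runif(100, 0.1, pi - 0.1)), 1)
})

test_that("band-passed phases advance at the oscillation frequency", {
  srate <- 512
  t <- seq(0, 6, length.out = 6 * srate)
  x <- matrix(rep(sin(2 * pi * 4 * t), 12), 12, byrow = TRUE)
  ann <- data.frame(onset = 0, duration = 6, condition = "FP1")
  rec <- dyad_recording(x, x, srate, analysis_channels(), ann)
  ep <- make_hyper_epochs(rec)
  pps <- bandpass_and_phase(ep, "theta")
  phi <- pps[[2]]$phi_mother[1, ]
  slope <- mean(diff(unwrap_phase(phi))) * srate / (2 * pi)
  expect_lt(abs(slope - 4) / 4, 0.01)
  # identical members: zero phase difference everywhere
  expect_equal(max(abs(pps[[2]]$phi_mother - pps[[2]]$phi_infant)), 0)
})

test_that("a quarter-cycle shift appears as a pi/2 phase difference", {
  srate <- 512
  t <- seq(0, 6, length.out = 6 * srate)
  x <- matrix(rep(sin(2 * pi * 4 * t), 12), 12, byrow = TRUE)
  y <- matrix(rep(sin(2 * pi * 4 * t - pi / 2), 12), 12, byrow = TRUE)
  ann <- data.frame(onset = 0, duration = 6, condition = "FP1")
  rec <- dyad_recording(x, y, srate, analysis_channels(), ann)
  pps <- bandpass_and_phase(make_hyper_epochs(rec), "theta")
  d <- delta_phi(pps[[2]], 1, 1)
  mid <- 200:800
  expect_lt(max(abs(d[mid] - pi / 2)), 0.05)
})

test_that("surrogate retention sits at the nominal level on white phases", {
  set.seed(501)
  ret <- replicate(15, mean(surrogate_validate(white_phase_pair(), 200, 0.05)))
  # strict-exceedance rule: theoretical retention 11/201 = 5.47%
  expect_gt(mean(ret), 0.035)
  expect_lt(mean(ret), 0.065)
})

test_that("surrogate masks are deterministic under a seed and retain locks", {
  cfg <- one_block_config(duration = 4, kappa = 1, seed = 5, noise_sd = 0,
                          lag_phase = pi / 2, artifact_rate = 0)
  g <- generate_dyad(cfg, 1)
  ep <- g$recording |> select_channels() |> make_hyper_epochs()
  pp <- bandpass_and_phase(ep, "theta")[[2]]
  set.seed(77); m1 <- surrogate_validate(pp, 200)
  set.seed(77); m2 <- surrogate_validate(pp, 200)
  expect_identical(m1, m2)
  expect_true(all(m1))   # wPLI = 1 beats every surrogate
})

test_that("band-limited independent members over-retain under permutation", {
  # Narrow-band phases are autocorrelated; a time permutation destroys that
  # autocorrelation, so the surrogate null is too easy to beat and retention
  # far exceeds the nominal level.  This mirrors the very high epoch
  # inclusion rates seen on real infant-mother EEG.
  cfg <- one_block_config(duration = 6, kappa = 0, seed = 19,
                          artifact_rate = 0)
  g <- generate_dyad(cfg, 1)
  ep <- g$recording |> filter_raw() |> select_channels() |> make_hyper_epochs()
  pps <- bandpass_and_phase(ep, "theta")
  set.seed(404)
  ret <- mean(sapply(pps[1:3], function(p) mean(surrogate_validate(p, 100))))
  expect_gt(ret, 0.5)
})

test_that("PLV over-retains relative to wPLI under zero-lag common input", {
  cfg <- one_block_config(duration = 8, kappa = 0, seed = 20,
                          artifact_rate = 0)
  rec <- generate_dyad(cfg, 1)$recording
  set.seed(21)
  common <- dyadsync:::narrowband_noise(ncol(rec$mother), c(3, 5), rec$srate)
  rec$mother <- rec$mother + rep(2, 12) %o% common
  rec$infant <- rec$infant + rep(2, 12) %o% common   # zero lag
  ep <- rec |> filter_raw() |> select_channels() |> make_hyper_epochs()
  pps <- bandpass_and_phase(ep, "theta")
  set.seed(22)
  rates <- sapply(pps[1:4], function(pp) {
    res <- dyadsync:::.surrogate_counts(pp$phi_mother, pp$phi_infant,
                                        100L, TRUE)
    c(w = mean(res$wpli_below >= 95), p = mean(res$plv_below >= 95))
  })
  expect_gt(mean(rates["p", ]), mean(rates["w", ]))
})

test_that("aggregation averages retained pair-epoch values only", {
  mk_ec <- function(w, valid, cond = "FP1") {
    structure(list(wpli = w, plv = w, valid = valid, condition = cond,
                   band = "theta", epoch_index = 1L),
              class = "epoch_connectivity")
  }
  m1 <- matrix(0.2, 2, 2); m2 <- matrix(0.4, 2, 2)
  all_ok <- matrix(TRUE, 2, 2)
  # identical epochs: idempotent mean
  agg <- aggregate_connectivity(list(mk_ec(m1, all_ok), mk_ec(m1, all_ok)))
  expect_equal(agg$pair_matrix[[1]], m1)
  expect_equal(agg$global_wpli, 0.2)
  # two epochs 0.2 / 0.4 both retained -> 0.3
  agg2 <- aggregate_connectivity(list(mk_ec(m1, all_ok), mk_ec(m2, all_ok)))
  expect_equal(agg2$global_wpli, 0.3)
  # one flagged invalid -> average equals the retained one
  mask <- all_ok; mask[1, 1] <- FALSE
  agg3 <- aggregate_connectivity(list(mk_ec(m1, mask), mk_ec(m2, all_ok)))
  expect_equal(agg3$pair_matrix[[1]][1, 1], 0.4)
  expect_equal(agg3$pair_matrix[[1]][2, 2], 0.3)
  expect_equal(agg3$retention_fraction, mean(c(mask, all_ok)))
  # epoch granularity: an epoch with under half its pairs valid is dropped
  bad <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  agg4 <- aggregate_connectivity(list(mk_ec(m1, bad), mk_ec(m2, all_ok)),
                                 granularity = "epoch")
  expect_equal(agg4$global_wpli, 0.4)
  # global equals the mean of the pair matrix
  expect_equal(agg2$global_wpli, mean(agg2$pair_matrix[[1]]))
})

test_that("still-face coupling drop is recovered in condition means", {
  cfg <- tiny_config(n_dyads = 3, block_s = 10, seed = 611)
  st <- do.call(rbind, lapply(1:3, function(i) {
    g <- generate_dyad(cfg, i)
    dyad_synchrony(prep_epochs(g$recording), bands = "theta",
                   n_surrogates = 0)
  }))
  mu <- tapply(st$global_wpli, st$condition, mean)
  expect_gt(mean(mu[c("FP1", "FP2", "RU")]), mean(mu[c("SF1", "SF2")]))
})
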