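test_that("star-to-path interpolation hits both endpoints exactly", {
  star <- make_interpolated_tree(5, 0)
  expect_setequal(edge_key(star), edge_key(cbind(1, 2:5)))
  path <- make_interpolated_tree(5, 1)
  expect_setequal(edge_key(path), edge_key(cbind(1:4, 2:5)))
  expect_error(make_interpolated_tree(2, 0.5), "at least 3")
})

test_that("intermediate shifts give trees strictly between path and star", {
  tr <- spanning_tree(make_interpolated_tree(58, 0.5), 58)
  lf <- leaf_fraction(tr)
  expect_gt(lf, 2 / 58)
  expect_lt(lf, 57 / 58)
  # deterministic construction
  expect_identical(make_interpolated_tree(58, 0.5), make_interpolated_tree(58, 0.5))
})

test_that("leaf fraction and diameter fall monotonically along the interpolation", {
  shifts <- seq(0, 1, by = 0.1)
  lf <- vapply(shifts, function(s)
    leaf_fraction(spanning_tree(make_interpolated_tree(20, s), 20)), numeric(1))
  di <- vapply(shifts, function(s)
    tree_diameter(spanning_tree(make_interpolated_tree(20, s), 20)), numeric(1))
  expect_true(all(diff(lf) <= 0))
  expect_true(all(diff(di) >= 0))   # diameter grows star -> path
})

test_that("coupling_spec validates its invariants", {
  edges <- make_interpolated_tree(5, 0)
  expect_error(coupling_spec(5, edges, phase_lag = 0), "0 or pi")
  expect_error(coupling_spec(5, edges, phase_lag = pi), "0 or pi")
  expect_error(coupling_spec(5, edges, coupling_strength = 1.2), "\\[0, 1\\]")
  expect_error(coupling_spec(5, edges[1:3, ]), "must have 4 edges")
  bad <- rbind(c(1, 2), c(1, 2), c(3, 4), c(4, 5))
  expect_error(coupling_spec(5, bad))
})

test_that("generated recordings are reproducible and respect Nyquist", {
  cs <- coupling_spec(4, make_interpolated_tree(4, 0), carrier_band = c(9, 11))
  expect_error(generate_recording(cs, 256, fs = 20, seed = 1), "Nyquist")
  r1 <- generate_recording(cs, 512, fs = 128, seed = 9)
  r2 <- generate_recording(cs, 512, fs = 128, seed = 9)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(cs, 512, fs = 128, seed = 10)
  expect_false(identical(r1$data, r3$data))
  expect_true(all(is.finite(r1$data)))
})

test_that("a noiseless coupled pair locks at the imposed lag with PLI 1", {
  cs <- coupling_spec(2, rbind(c(1, 2)), coupling_strength = 1,
                      phase_lag = pi / 2, carrier_band = c(9.5, 10.5),
                      noise_sd = 0, phase_noise_sd = 0)
  rec <- generate_recording(cs, 2048, 256, seed = 3)
  ph <- instantaneous_phase(one_epoch(rec$data, fs = 256))[[1]]
  expect_equal(pli_pair(ph[1, ], ph[2, ]), 1)
  # sign convention of coupling_spec: channel 1 (the root) leads channel 2
  dphi <- Arg(exp(1i * (ph[1, ] - ph[2, ])))
  expect_gt(median(dphi), 0)
})

test_that("uncoupled noisy channels stay at the PLI null level", {
  cs <- coupling_spec(2, rbind(c(1, 2)), coupling_strength = 0,
                      carrier_band = c(9, 11), noise_sd = 1)
  plis <- vapply(1:20, function(s) {
    rec <- generate_recording(cs, 2048, 256, seed = 100 + s)
    ep <- bandpass_filter(extract_epochs(rec, 1, 2048),
                          band_definition("alpha", 8, 13))
    pli_matrix(ep)[[1]][1, 2]
  }, numeric(1))
  # null expectation ~ sqrt(2/(pi*2048)) ~ 0.018 for 2048 iid signs; the
  # narrowband autocorrelation inflates this, but values must stay small
  expect_lt(mean(plis), 0.15)
})

test_that("volume conduction is instantaneous and dimension-checked", {
  rec <- sine_recording(c(10, 12, 14), fs = 128, n = 256)
  expect_identical(apply_volume_conduction(rec, diag(3))$data, rec$data)
  expect_error(apply_volume_conduction(rec, diag(4)), "3 x 3")
  expect_error(apply_volume_conduction(rec, -diag(3)), "nonnegative")
  # an all-zero mixing row silences that channel (pure linearity)
  m <- diag(3); m[2, ] <- 0
  mixed <- apply_volume_conduction(rec, m)
  expect_true(all(mixed$data[2, ] == 0))
  expect_identical(mixed$data[1, ], rec$data[1, ])
})

test_that("cohorts are deterministic functions of their specification", {
  sp <- cohort_spec(n_patients = 2, n_controls = 2, n_channels = 6, fs = 128,
                    n_epochs = 1, epoch_length = 256, seed = 77)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(lapply(c1$subjects, function(s) s$recording$data),
                   lapply(c2$subjects, function(s) s$recording$data))
  expect_identical(vapply(c1$subjects, `[[`, 0, "disability"),
                   vapply(c2$subjects, `[[`, 0, "disability"))
})

test_that("cohort groups, disability ranges and topology shifts follow the cohort_spec", {
  sp <- cohort_spec(n_patients = 8, n_controls = 5, n_channels = 6, fs = 128,
                    n_epochs = 1, epoch_length = 256, seed = 5,
                    disability_range = c(4L, 40L))
  co <- generate_cohort(sp)
  grp <- vapply(co$subjects, `[[`, "", "group")
  dis <- vapply(co$subjects, `[[`, 0, "disability")
  shf <- vapply(co$subjects, `[[`, 0, "shift")
  expect_equal(sum(grp == "patient"), 8)
  expect_equal(sum(grp == "control"), 5)
  expect_true(all(dis[grp == "control"] == 0))
  expect_true(all(dis[grp == "patient"] >= 4 & dis[grp == "patient"] <= 40))
  expect_equal(shf[grp == "patient"],
               pmin(1, sp$patient_shift + sp$disability_slope * dis[grp == "patient"] / 48))
  expect_true(all(shf[grp == "control"] == sp$control_shift))
})

test_that("star and path cohorts separate cleanly in recovered leaf fraction", {
  beta <- band_definition("beta", 13, 30)
  recover_leaf <- function(shift, seed) {
    edges <- make_interpolated_tree(10, shift)
    cs <- coupling_spec(10, edges, coupling_strength = 0.9, noise_sd = 0.1)
    rec <- generate_recording(cs, 1024, 128, seed = seed)
    rec <- apply_volume_conduction(rec, exponential_mixing(10, 0.5))
    mats <- pli_matrix(bandpass_filter(extract_epochs(rec, 2, 512), beta))
    mean(vapply(mats, function(m) leaf_fraction(build_mst(m)), numeric(1)))
  }
  star_lf <- vapply(1:10, function(s) recover_leaf(0, 400 + s), numeric(1))
  path_lf <- vapply(1:10, function(s) recover_leaf(1, 500 + s), numeric(1))
  expect_gt(min(star_lf), max(path_lf))
})
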