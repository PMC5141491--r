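test_that("analytic phase tracks the phase of pure oscillations", {
  fs <- 256; n <- 2048
  t <- (0:(n - 1)) / fs
  ep <- one_epoch(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs = fs)
  ph <- instantaneous_phase(ep)[[1]]
  dphi <- Arg(exp(1i * (ph[1, ] - ph[2, ])))
  core <- 100:(n - 100)                 # away from Hilbert edge effects
  expect_equal(dphi[core], rep(pi / 2, length(core)), tolerance = 1e-3)
  # a signal against itself has identically zero phase difference
  ep2 <- one_epoch(rbind(cos(2 * pi * 7 * t), cos(2 * pi * 7 * t)), fs = fs)
  ph2 <- instantaneous_phase(ep2)[[1]]
  expect_equal(ph2[1, ], ph2[2, ])
  # unwrapped phase of a tone advances by 2*pi*f/fs per sample
  slope <- diff(Arg(exp(1i * ph[1, core])))
  slope <- slope[abs(slope) < pi]       # drop wrap points
  expect_equal(median(slope), 2 * pi * 10 / fs, tolerance = 1e-3)
})

test_that("a drifting-frequency tone yields a monotone phase whose slope tracks frequency", {
  fs <- 256; n <- 2048
  t <- (0:(n - 1)) / fs
  f_inst <- 8 + 4 * t / max(t)               # 8 -> 12 Hz linear chirp
  phase_true <- 2 * pi * cumsum(f_inst) / fs
  ep <- one_epoch(matrix(cos(phase_true), 1), fs = fs)
  ph <- instantaneous_phase(ep)[[1]][1, ]
  core <- 200:(n - 200)
  d <- diff(ph[core]); d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_true(all(d > 0))                    # monotone advance
  est_f <- d * fs / (2 * pi)
  expect_equal(stats::cor(est_f, f_inst[core][-1]), 1, tolerance = 0.02)
})

test_that("flat channels are flagged and contribute zero PLI", {
  mat <- rbind(sin(2 * pi * 10 * (0:511) / 256), 0)
  expect_warning(ph <- instantaneous_phase(one_epoch(mat)), "flat")
  expect_true(all(ph[[1]][2, ] == 0))
  expect_warning(m <- pli_matrix(one_epoch(rbind(mat[2, ], mat[2, ]))), "flat")
  expect_equal(m[[1]][1, 2], 0)
})

test_that("pli_pair matches its closed-form unit cases", {
  n <- 2048
  expect_equal(pli_pair(rep(pi / 2, n), rep(0, n)), 1)
  alt <- rep(c(pi / 4, -pi / 4), n / 2)
  expect_equal(pli_pair(alt, rep(0, n)), 0)
  expect_error(pli_pair(1:5 / 10, 1:4 / 10), "equal length")
  # symmetry and common-offset invariance
  set.seed(31)
  x <- runif(500, -pi, pi); y <- runif(500, -pi, pi)
  expect_equal(pli_pair(x, y), pli_pair(y, x))
  expect_equal(pli_pair(x + 1.3, y + 1.3), pli_pair(x, y), tolerance = 1e-12)
})

test_that("uniform random phase differences keep PLI near the sqrt(2/(pi n)) null", {
  set.seed(32)
  n <- 2048
  draws <- vapply(1:300, function(i)
    pli_pair(runif(n, -pi, pi), rep(0, n)), numeric(1))
  expect_equal(mean(draws), sqrt(2 / (pi * n)), tolerance = 0.1)
  expect_gte(mean(draws < 0.06), 0.99)
})

test_that("PLI is a phase-only statistic, invariant to amplitude rescaling", {
  set.seed(33)
  fs <- 256
  x <- matrix(rnorm(2 * 1024), 2)
  b <- eeg_bands()$alpha
  f1 <- bandpass_filter(one_epoch(x, fs = fs), b)
  f2 <- bandpass_filter(one_epoch(x * c(5, 0.01), fs = fs), b)
  expect_equal(pli_matrix(f1)[[1]], pli_matrix(f2)[[1]], tolerance = 1e-9)
})

test_that("pli_matrix equals per-pair scalar recomputation and is a valid PLI matrix", {
  set.seed(34)
  ph <- matrix(runif(5 * 400, -pi, pi), 5, 400)
  ep <- one_epoch(cos(ph))    # irrelevant payload; inject phases directly below
  phases <- structure(list(ph), labels = ep$labels, band = NULL, fs = ep$fs)
  m <- pli_matrix(phases)[[1]]
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j], pli_pair(ph[i, ], ph[j, ]))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  # a duplicated channel gives PLI exactly 0 (all phase differences are 0)
  phd <- structure(list(ph[c(1, 1, 2), ]), labels = c("a", "b", "c"),
                   band = NULL, fs = 256)
  expect_equal(pli_matrix(phd)[[1]]["a", "b"], 0)
})

test_that("the long edge table carries every pair of every epoch exactly once", {
  set.seed(36)
  mats <- replicate(2, random_pli_matrix(4, labels = letters[1:4]), simplify = FALSE)
  tbl <- pli_edge_table(mats, subject_id = "S1", band = "beta")
  expect_equal(nrow(tbl), 2 * 6)
  expect_setequal(paste(tbl$ch_i, tbl$ch_j)[tbl$epoch == 1],
                  c("a b", "a c", "b c", "a d", "b d", "c d"))
  expect_equal(tbl$pli[tbl$epoch == 2 & tbl$ch_i == "a" & tbl$ch_j == "c"],
               mats[[2]]["a", "c"])
  expect_error(pli_edge_table(list()), "at least one")
})

test_that("global mean PLI averages upper triangles, then epochs", {
  cmat <- function(c, n = 4) { m <- matrix(c, n, n); diag(m) <- 0; m }
  expect_equal(global_mean_pli(list(cmat(0.3))), 0.3)
  expect_equal(global_mean_pli(list(cmat(0.2), cmat(0.6))), 0.4)
  set.seed(35)
  mats <- replicate(4, random_pli_matrix(6), simplify = FALSE)
  flat <- mean(unlist(lapply(mats, function(m) m[upper.tri(m)])))
  expect_equal(global_mean_pli(mats), flat)
  expect_error(global_mean_pli(list()), "at least one")
})
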