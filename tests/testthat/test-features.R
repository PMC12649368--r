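test_that("mechanical work integrates power with sign and mass normalization", {
  fs <- 400
  n <- 2 * fs + 1
  w <- mechanical_work(rep(10, n), rep(0.1, n), fs, c(1, n), mass = 1)
  expect_equal(w, 2, tolerance = 1e-9)
  # odd in velocity
  expect_equal(mechanical_work(rep(10, n), rep(-0.1, n), fs, c(1, n), 1), -2,
               tolerance = 1e-9)
  # analytic integral of sin(pi t) over [0, 1]
  t <- seq(0, 1, by = 1 / fs)
  w2 <- mechanical_work(sin(pi * t), rep(1, length(t)), fs,
                        c(1, length(t)), 1)
  expect_equal(w2, 2 / pi, tolerance = 1e-4)
  expect_error(mechanical_work(1:10, 1:10, fs, c(5, 20), 1), "window")
})

test_that("work is additive over contiguous windows", {
  set.seed(2)
  fs <- 400
  x <- cumsum(rnorm(1200)); v <- rnorm(1200)
  total <- mechanical_work(x, v, fs, c(1, 1200), 70)
  parts <- mechanical_work(x, v, fs, c(1, 400), 70) +
    mechanical_work(x, v, fs, c(400, 800), 70) +
    mechanical_work(x, v, fs, c(800, 1200), 70)
  expect_equal(total, parts, tolerance = 1e-9)
})

test_that("SPARC is scale-invariant and penalizes in-band ripple", {
  fs <- 400
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- 2 + sin(pi * t / 2)
  s0 <- sparc(x, fs)
  for (c in c(0.01, 7, 1e3)) expect_equal(sparc(c * x, fs), s0)
  # 5% ripple at 6 Hz makes the profile strictly less smooth
  expect_lt(sparc(x + 0.05 * max(x) * sin(2 * pi * 6 * t), fs), s0)
  expect_error(sparc(rep(0, 800), fs), "all-zero")
  expect_error(sparc(x[1:50], fs), "0.25")
})

test_that("SPARC matches a dense-grid evaluation of the spectral arc length", {
  fs <- 400
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- ifelse(abs(t - 1) <= 0.5, 0.5 * (1 + cos(2 * pi * (t - 1))), 0)
  # independent oracle: direct DTFT on a fine grid + trapezoid arc length
  oracle <- function(x, fs, thr = 0.05, fmax = 10, df = 5e-4) {
    f <- seq(0, fmax, by = df)
    k <- seq_along(x) - 1
    V <- vapply(f, function(fi) Mod(sum(x * exp(-2i * pi * fi * k / fs))), 1)
    Vh <- V / V[1]
    i_c <- max(which(Vh >= thr))
    fc <- if (i_c < length(f)) {
      f[i_c] + df * (Vh[i_c] - thr) / (Vh[i_c] - Vh[i_c + 1])
    } else fmax
    keep <- f < fc
    fg <- c(f[keep], fc)
    Vg <- c(Vh[keep], stats::approx(f, Vh, xout = fc)$y)
    -sum(sqrt((diff(fg) / fc)^2 + diff(Vg)^2))
  }
  expect_equal(sparc(x, fs), oracle(x, fs), tolerance = 1e-3)
})

test_that("TCCI hits its closed-form anchors and stays in [0, 1]", {
  fs <- 400
  n <- fs + 1
  # identical maximal normalized torques -> 1
  expect_equal(tcci(rep(2, n), rep(2, n), fs, c(1, n)), 1, tolerance = 1e-9)
  # disjoint supports -> 0
  a <- c(rep(1, 200), rep(0, 201)); b <- c(rep(0, 200), rep(1, 201))
  expect_equal(tcci(a, b, fs, c(1, n)), 0, tolerance = 1e-9)
  # t vs 1 - t on a unit window: integral of min is 1/4
  t <- seq(0, 1, length.out = n)
  expect_equal(tcci(t, 1 - t, fs, c(1, n), max_ag = 1, max_ant = 1), 0.25,
               tolerance = 1e-3)
  expect_error(tcci(rep(0, n), t, fs, c(1, n)), "zero task-maximum")

  set.seed(4)
  for (i in 1:20) {
    x <- abs(rnorm(n)); y <- abs(rnorm(n))
    v <- tcci(x, y, fs, c(1, n))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lte(v, min(mean(x / max(x)), mean(y / max(y))) + 0.05)
  }
})

test_that("the metric catalogue and feature table have the documented shape", {
  nm <- htm_metric_names()
  expect_length(nm, 26)
  expect_equal(sum(grepl("^Work_", nm)), 11)
  expect_equal(sum(grepl("^Sparc_", nm)), 11)
  expect_equal(sum(grepl("^TCCI_", nm)), 4)

  run <- default_run()
  ft <- run$feature_table
  expect_equal(nrow(ft), 40)
  expect_equal(ncol(ft) - 3, 130)  # subject, group, severity + metrics
  expect_true(all(paste0(rep(nm, each = 5), "__",
                         c("PhaseI", "PhaseII", "PhaseIII", "PhaseIV",
                           "Whole")) %in% names(ft)))
  # whole-task work equals the sum of the four phase works
  for (m in c("Work_ElFE", "Work_BB", "Work_PM")) {
    parts <- rowSums(sapply(c("PhaseI", "PhaseII", "PhaseIII", "PhaseIV"),
                            function(w) ft[[paste0(m, "__", w)]]))
    expect_equal(ft[[paste0(m, "__Whole")]], parts, tolerance = 1e-9)
  }
  expect_true(all(ft[grepl("^TCCI", names(ft))] >= 0 &
                    ft[grepl("^TCCI", names(ft))] <= 1))
  expect_true(all(ft[grepl("^Sparc", names(ft))] < 0))
})
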