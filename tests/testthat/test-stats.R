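test_that("BH adjustment reproduces hand computations", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), policy = "global"),
               rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 6), policy = "global"), rep(0.2, 6))
  expect_equal(fdr_adjust(0.37, policy = "global"), 0.37)
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH matches a brute-force step-up oracle on random inputs", {
  bh_brute <- function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) {
      # adjusted p_i = min over j with p_j >= p_i of m * p_j / rank(p_j)
      r <- rank(p, ties.method = "max")
      min(1, min((m * p / r)[p >= p[i]]))
    }, 1)
  }
  set.seed(11)
  for (rep in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdr_adjust(p, policy = "global"), bh_brute(p),
                 tolerance = 1e-12)
  }
})

test_that("per-window FDR families are adjusted independently", {
  p <- c(0.01, 0.02, 0.01, 0.02)
  w <- c("A", "A", "B", "B")
  per <- fdr_adjust(p, policy = "per-window", windows = w)
  expect_equal(per, c(0.02, 0.02, 0.02, 0.02))
  glob <- fdr_adjust(p, policy = "global")
  expect_equal(glob, rep(0.02, 4))
  expect_error(fdr_adjust(p, policy = "per-window", windows = w[1:2]),
               "length")
})

test_that("group comparison routes tests by normality and detects shifts", {
  set.seed(21)
  mk_ft <- function(healthy, stroke) {
    ft <- data.frame(subject = sprintf("P%02d", 1:40),
                     group = rep(c("healthy", "stroke"), each = 20),
                     severity = c(rep(66, 20), sample(21:55, 20, TRUE)))
    ft[["M_normal__Whole"]] <- c(healthy, stroke)
    ft[["M_skewed__Whole"]] <- exp(c(healthy, stroke))
    ft[["M_const__Whole"]] <- 1
    ft
  }
  ft <- mk_ft(rnorm(20), rnorm(20, mean = 2))  # 2-SD location shift
  cmp <- compare_groups(ft)
  rn <- cmp[cmp$metric == "M_normal", ]
  expect_equal(rn$test, "t")
  expect_true(rn$significant)
  expect_gt(rn$direction, 0)
  expect_equal(cmp[cmp$metric == "M_skewed", "test"], "mann-whitney")
  rc <- cmp[cmp$metric == "M_const", ]
  expect_equal(rc$test, "skipped")
  expect_equal(rc$reason, "zero variance")

  ft0 <- mk_ft(rnorm(20), rnorm(20))  # identical distributions
  cmp0 <- compare_groups(ft0)
  expect_lte(sum(cmp0$significant, na.rm = TRUE), 1)
})

test_that("percent reduction is relative magnitude loss", {
  expect_equal(percent_reduction(1, 0.5), 50)
  expect_equal(percent_reduction(-2, -1), 50)
  expect_equal(percent_reduction(0.08, 0.02), 75)
})

test_that("severity correlations agree with a rank-based oracle", {
  ft <- data.frame(subject = sprintf("P%02d", 1:12),
                   group = rep(c("healthy", "stroke"), each = 6),
                   severity = c(rep(66, 6), c(25, 30, 35, 40, 45, 50)))
  sev <- ft$severity[7:12]
  ft[["Work_ElFE__PhaseII"]] <- c(rnorm(6), sev * 0.01)        # rho = 1
  ft[["TCCI_AD_PD__PhaseII"]] <- c(rnorm(6), rev(sev) * 0.01)  # rho = -1
  tied <- c(1, 1, 2, 3, 3, 4)
  ft[["Work_BB__PhaseII"]] <- c(rnorm(6), tied)
  res <- severity_correlation(ft, metrics = c("Work_ElFE", "TCCI_AD_PD",
                                              "Work_BB"))
  get <- function(m) res$rho[res$metric == m & res$window == "PhaseII"]
  expect_equal(get("Work_ElFE"), 1)
  expect_equal(get("TCCI_AD_PD"), -1)
  # brute-force Spearman with midranks
  expect_equal(get("Work_BB"), cor(rank(tied), rank(sev)), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p))
})
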