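test_that("saturation time is measured by interpolated threshold crossings", {
  # synthetic trapezoid: rise over [0,1], hold 1.0 over [1,5], fall over [5,6]
  tt <- seq(0, 10, 1e-3)
  dj <- approx(c(0, 1, 5, 6, 10), c(0, 1, 1, 0, 0), xout = tt)$y
  tr <- tibble::tibble(time = tt, deltaJ = dj)
  ts <- compute_tsat(tr, threshold = 0.9)
  # crossings at t = 0.9 (rising) and t = 5.1 (falling)
  expect_equal(as.numeric(ts), 4.2, tolerance = 1e-3)
  expect_true(attr(ts, "saturating"))

  # dense-scan oracle: count samples at/above threshold on a 0.1 ms grid
  t2 <- seq(0, 10, 1e-4)
  d2 <- approx(c(0, 1, 5, 6, 10), c(0, 1, 1, 0, 0), xout = t2)$y
  oracle <- sum(d2 >= 0.9) * 1e-4
  expect_equal(as.numeric(ts), oracle, tolerance = 1e-3)

  # sub-saturating trace: explicitly "not saturating", never 0
  low <- tibble::tibble(time = tt, deltaJ = 0.5 * dj)
  ts2 <- compute_tsat(low)
  expect_true(is.na(ts2))
  expect_false(attr(ts2, "saturating"))
})

test_that("recovery time constant recovers a known exponential", {
  tt <- seq(0, 30, 1e-3)
  dj <- 0.6 * pmin(tt / 0.5, 1) * exp(-pmax(tt - 0.5, 0) / 2)
  tr <- tibble::tibble(time = tt, deltaJ = dj)
  expect_equal(fit_tau_rec(tr), 2, tolerance = 1e-3)
  # window-start invariance for a pure exponential
  a <- fit_tau_rec(tr, window = c(0.4, 0.99))
  b <- fit_tau_rec(tr, window = c(0.6, 0.99))
  expect_lt(abs(a - b) / a, 0.01)
  # saturating responses are rejected
  sat <- tibble::tibble(time = tt, deltaJ = pmin(2 * dj + 0.5, 1))
  expect_error(fit_tau_rec(sat), "saturating")
})

test_that("Pepperberg slope equals the generating constant and an OLS oracle", {
  S <- 10^seq(2.5, 4.5, 0.5)
  tsat <- 2 * log(S / 100)
  fit <- pepperberg_fit(S, tsat)
  expect_equal(fit$tau_D, 2, tolerance = 1e-10)
  # closed-form normal-equations oracle on the first four points
  x <- log(S[1:4]); y <- tsat[1:4] + c(0.1, -0.05, 0.02, 0)
  slope_oracle <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  fit2 <- pepperberg_fit(S, tsat + c(0.1, -0.05, 0.02, 0, 0))
  expect_equal(fit2$tau_D, slope_oracle, tolerance = 1e-10)

  expect_error(pepperberg_fit(S, c(NA, NA, 1, 2, 3)), "at least 4")
  expect_error(pepperberg_fit(rev(S), tsat), "increasing")

  td <- tidy(fit)
  expect_equal(unname(td$estimate[td$term == "log_strength"]), 2,
               tolerance = 1e-10)
  expect_equal(glance(fit)$n_points, 4)
})

test_that("molecular-class sums respect rhodopsin bookkeeping", {
  tr <- sat_trace()
  cls <- class_abundances(tr)
  net <- wt_model()
  # all R* classes + capped + dark + opsin = rhodopsin total, at all times
  total <- cls$Rst_0_3P + cls$Rst_4_6P + cls$ArrB_1_3P + cls$ArrB_4_6P +
    tr$R + tr$R_Gt + tr$Ops
  expect_lt(max(abs(total - net$params$R_total)) / net$params$R_total, 1e-6)
  # dark start: no activated rhodopsin in either class
  expect_equal(cls$Rst_0_3P[1], 0)
  expect_equal(cls$Rst_4_6P[1], 0)
  # sparsely phosphorylated complexes finish binding before the heavily
  # phosphorylated class does
  plateau_t <- function(x) cls$time[which(x >= 0.99 * max(x))[1]]
  expect_lt(plateau_t(cls$ArrB_1_3P), plateau_t(cls$ArrB_4_6P))
})

test_that("tsat_ladder tabulates peaks and stops after enough saturating points", {
  lad <- genotype_ladder("WT", mutant_spec())
  expect_true(all(diff(lad$strength) > 0))
  expect_equal(sum(lad$saturating), 4)
  expect_true(all(lad$peak >= 0 & lad$peak <= 1 + 1e-9))
  # saturation is monotone in flash strength at fixed genotype
  expect_true(all(diff(lad$tsat[lad$saturating]) > 0))
})
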