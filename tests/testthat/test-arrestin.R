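test_that("oligomer reactions share constants and close properly", {
  rxns <- oligomer_reactions()
  ks <- vapply(rxns, function(r) r$k, numeric(1))
  names(ks) <- vapply(rxns, function(r) r$name, character(1))
  expect_equal(unname(ks["Arr_dimerize"]), 1.787e-8)
  expect_equal(unname(ks["Arr_tetramerize"]), 1.787e-8)
  expect_equal(unname(ks["Arr_didissoc"]), 0.646)
  expect_equal(unname(ks["Arr_tetradissoc"]), 0.646)
  # kA4 = 0 closes the monomer pool: only dissociation remains
  f <- build_derivatives(rod_network(
    species = tibble::tibble(name = c("Arr", "Arr_di", "Arr_tetra"),
                             initial = c(0, 1e6, 1e6), unit = "count"),
    reactions = oligomer_reactions(kA4 = 0, kA5 = 0.646)))
  d <- f(0, c(Arr = 5, Arr_di = 1e6, Arr_tetra = 1e6))
  expect_gt(d[["Arr"]], 0)
  expect_equal(d[["Arr"]], 2 * 0.646 * 1e6)
  # forward flux vanishes at zero monomers
  d0 <- f(0, c(Arr = 0, Arr_di = 0, Arr_tetra = 0))
  expect_equal(unname(d0), c(0, 0, 0))
})

test_that("analytic equilibrium solver matches a bisection oracle", {
  p <- default_params()
  # brute-force bisection on the monotone closure function
  oracle <- function(total, q) {
    lo <- 0; hi <- total
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mid + 2 * q * mid^2 + 4 * q^3 * mid^4 > total) hi <- mid else lo <- mid
    }
    a <- (lo + hi) / 2
    c(a, q * a^2, q^3 * a^4)
  }
  for (total in c(1e6, 3e8, 42)) {
    got <- arr_equilibrium_pools(total, p$kA4, p$kA5)
    ref <- oracle(total, p$kA4 / p$kA5)
    expect_equal(unname(got), ref, tolerance = 1e-10)
    expect_equal(got[["Arr"]] + 2 * got[["Arr_di"]] + 4 * got[["Arr_tetra"]],
                 total, tolerance = 1e-10)
  }
  expect_equal(unname(arr_equilibrium_pools(1e8, kA4 = 0, kA5 = 0.646)),
               c(1e8, 0, 0))
  expect_equal(unname(arr_equilibrium_pools(0, p$kA4, p$kA5)), c(0, 0, 0))
})

test_that("Ca2+-dependent forward-rate variant is off by default and monotone", {
  expect_identical(ca_dependent_forward_rate(1.787e-8, 0, 0.1, 0.6), 1.787e-8)
  # dark state factor is exactly 1
  expect_equal(ca_dependent_forward_rate(2, 1.5, 0.6, 0.6), 2)
  # factor decreases as Ca2+ falls below dark
  f_low <- ca_dependent_forward_rate(1, 2, 0.1, 0.6)
  f_dark <- ca_dependent_forward_rate(1, 2, 0.6, 0.6)
  expect_lt(f_low, f_dark)
  expect_error(ca_dependent_forward_rate(1, 1, 0.1, 0), "positive")
  # disabled variant leaves the assembled network identical to the base model
  expect_identical(rodcascade:::pack_network(build_rod_model(omega_Arr = 0)),
                   rodcascade:::pack_network(build_rod_model()))
})

test_that("storage oligomers feed the monomer pool during a saturating flash", {
  cls <- class_abundances(sat_trace())
  i4 <- cls$time <= 4
  dark <- cls$Arr_monomer[1]
  # monomer pool dips then recovers toward its dark value
  tmin <- which.min(cls$Arr_monomer[i4])
  expect_lt(cls$Arr_monomer[tmin], dark)
  expect_gt(tmin, 1)
  late <- cls$Arr_monomer[max(which(i4))]
  expect_gt(late, cls$Arr_monomer[tmin])
  # oligomer-held arrestin declines monotonically over the first 4 s
  expect_true(all(diff(cls$Arr_oligomer[i4]) <= 1e-6 * dark))
})
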