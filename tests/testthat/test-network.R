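test_that("mass-action derivatives match hand-written forms", {
  f <- build_derivatives(toy_decay(k = 1))
  expect_equal(f(0, c(A = 2, B = 0)), c(A = -2, B = 2))

  # dimerization stoichiometry: dA/dt = -2 k A^2, dA2/dt = +k A^2
  f2 <- build_derivatives(toy_dimer(kf = 3, kr = 0))
  expect_equal(f2(0, c(A = 5, A2 = 0)), c(A = -2 * 3 * 25, A2 = 3 * 25))

  # three-reaction toy vs an independently hand-coded derivative
  net <- rod_network(
    species = tibble::tibble(name = c("X", "Y", "Z"),
                             initial = c(4, 1, 0.5), unit = "count"),
    reactions = list(
      mass_action("r1", 0.7, c(X = 1, Y = 1), c(Z = 1)),
      mass_action("r2", 1.3, c(Z = 1), c(X = 1, Y = 1)),
      mass_action("r3", 0.2, c(X = 1), c(Y = 1))))
  oracle <- function(x, y, z) {
    v1 <- 0.7 * x * y; v2 <- 1.3 * z; v3 <- 0.2 * x
    c(X = -v1 + v2 - v3, Y = -v1 + v2 + v3, Z = v1 - v2)
  }
  f3 <- build_derivatives(net)
  for (s in list(c(4, 1, 0.5), c(0, 2, 3), c(1e3, 1e-3, 7))) {
    expect_lt(max(abs(f3(0, stats::setNames(s, c("X", "Y", "Z"))) -
                      oracle(s[1], s[2], s[3]))), 1e-12)
  }
  expect_error(
    rod_network(tibble::tibble(name = "A", initial = 1, unit = "count"),
                list(mass_action("bad", 1, c(A = 1), c(Q = 1)))),
    "unknown species")
})

test_that("integration reproduces closed-form decay and detailed balance", {
  traj <- integrate_network(toy_decay(k = 1), t_grid = c(0, 0.5, 1))
  expect_equal(traj$A[3], exp(-1), tolerance = 1e-7)
  expect_equal(traj$A + traj$B, rep(1, 3), tolerance = 1e-9)

  # reversible dimerization relaxes to the algebraic equilibrium kf A^2 = kr A2
  net <- toy_dimer(kf = 2, kr = 0.5, A0 = 10)
  eq <- integrate_network(net, t_grid = c(0, 50, 100))
  A <- eq$A[3]; A2 <- eq$A2[3]
  expect_equal(2 * A^2, 0.5 * A2, tolerance = 1e-6)
  expect_equal(A + 2 * A2, 10, tolerance = 1e-9)
})

test_that("compiled and R derivative paths agree along a trajectory", {
  net <- wt_model()
  y0 <- initial_state(net)
  set.seed(42)
  y <- y0 * runif(length(y0), 0.9, 1.1) + 1
  tg <- c(0, 1e-4, 2e-4)
  a <- integrate_network(net, y, t_grid = tg, compiled = TRUE)
  b <- integrate_network(net, y, t_grid = tg, compiled = FALSE)
  rel <- abs(unlist(a[3, -1]) - unlist(b[3, -1])) / pmax(abs(unlist(b[3, -1])), 1)
  expect_lt(max(rel), 1e-10)
})

test_that("adaptive integration matches a fixed-step RK4 reference", {
  net <- toy_dimer(kf = 0.3, kr = 0.2, A0 = 4)
  f <- build_derivatives(net)
  rk4 <- function(y, t_end, h) {
    t <- 0
    while (t < t_end - h / 2) {
      k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    y
  }
  ref <- rk4(c(A = 4, A2 = 0), 2, 1e-4)
  got <- unlist(integrate_network(net, t_grid = c(0, 1, 2))[3, -1])
  expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-12)), 1e-4)
})

test_that("volume doubling with fixed concentrations preserves them", {
  # mixed-unit toy: a counted species binding a micromolar ligand
  mk <- function(vol, n0) {
    conv <- 1 / (MOLEC_PER_UM * vol)
    rod_network(
      species = tibble::tibble(name = c("P", "PL", "L"),
                               initial = c(n0, 0, 2), unit = c("count", "count", "uM")),
      reactions = list(
        reaction("bind", 0.05, c("P", "L"), c(P = -1, PL = 1, L = -conv)),
        reaction("unbind", 0.2, "PL", c(P = 1, PL = -1, L = conv))),
      volume_pl = vol)
  }
  t1 <- integrate_network(mk(1, 1e5), t_grid = seq(0, 5, 0.5))
  t2 <- integrate_network(mk(2, 2e5), t_grid = seq(0, 5, 0.5))
  expect_equal(t2$L, t1$L, tolerance = 1e-6)        # concentrations identical
  expect_equal(t2$P, 2 * t1$P, tolerance = 1e-6)    # counts scale with volume
})

test_that("steady-state solver respects conserved totals and trivial cases", {
  # all rates zero: the guess is already a fixed point
  net0 <- rod_network(tibble::tibble(name = c("A", "B"), initial = c(3, 4),
                                     unit = "count"),
                      list(mass_action("off", 0, c(A = 1), c(B = 1))))
  expect_equal(find_steady_state(net0), c(A = 3, B = 4))

  # pure oligomerization subsystem converges to the analytic equilibrium
  p <- default_params()
  arr <- rod_network(
    species = tibble::tibble(name = c("Arr", "Arr_di", "Arr_tetra"),
                             initial = c(3e8, 0, 0), unit = "count"),
    reactions = oligomer_reactions(p$kA4, p$kA5),
    conservation = list(arr = c(Arr = 1, Arr_di = 2, Arr_tetra = 4)))
  ss <- find_steady_state(arr, tol = 1e-9)
  ref <- arr_equilibrium_pools(3e8, p$kA4, p$kA5)
  expect_equal(unname(ss), unname(ref), tolerance = 1e-6)

  # Rec conformational subsystem at clamped Ca: RecT/RecR ratio from rates
  rec <- rod_network(
    species = tibble::tibble(name = c("RecT", "RecR"), initial = c(1e7, 1e6),
                             unit = "count"),
    reactions = list(
      mass_action("relax", p$kRec1 * 0.6, c(RecT = 1), c(RecR = 1)),
      mass_action("tense", p$kRec2, c(RecR = 1), c(RecT = 1))))
  ss2 <- find_steady_state(rec, tol = 1e-10)
  expect_equal(ss2[["RecT"]] / ss2[["RecR"]], p$kRec2 / (p$kRec1 * 0.6),
               tolerance = 1e-6)
})

test_that("trajectories conserve pools and stay non-negative", {
  net <- wt_model()
  tr <- sat_trace()
  resid <- conservation_residuals(net, tr[, net$species$name])
  expect_lt(max(resid), 1e-6)
  expect_gt(min(as.matrix(tr[, net$species$name])), -1e-9)
})
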