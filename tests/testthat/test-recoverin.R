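test_that("recoverin reactions carry measured constants with unit conversion", {
  p <- default_params()
  rxns <- rec_reactions(p)
  names(rxns) <- vapply(rxns, function(r) r$name, character(1))
  expect_equal(rxns[["Rec_relax"]]$k, 0.011)
  expect_equal(rxns[["Rec_tense"]]$k, 0.05)
  # kRec3 converted from 9.69 uM^-1 s^-1 to per-molecule units at 1 pL
  expect_equal(rxns[["RecRK_bind"]]$k, 9.69 / 6.02214e5, tolerance = 1e-6)
  expect_equal(rxns[["RecRK_unbind"]]$k, 0.61)
  # reaction 1 consumes free Ca2+ explicitly, one ion per recoverin
  expect_equal(unname(rxns[["Rec_relax"]]$changes["Ca"]), -1 / 6.02214e5)
  # zero Ca2+ shuts the forward flux
  f <- build_derivatives(rod_network(
    species = tibble::tibble(name = c("RecT", "RecR_Ca", "Ca"),
                             initial = c(1e6, 0, 0),
                             unit = c("count", "count", "uM")),
    reactions = rxns[c("Rec_relax", "Rec_tense")]))
  expect_equal(unname(f(0, c(RecT = 1e6, RecR_Ca = 0, Ca = 0))),
               c(0, 0, 0))
})

test_that("dark calcium implied by the conformational equilibrium is ~0.6 uM", {
  # printed dark pools: RecT = 1.41e7, RecR_Ca = 1.87e6
  expect_equal(implied_dark_calcium(1.41e7, 1.87e6), 0.603, tolerance = 1e-3)
  expect_equal(implied_dark_calcium(1e6, 0), 0)
  expect_equal(implied_dark_calcium(2 * 1.41e7, 2 * 1.87e6),
               implied_dark_calcium(1.41e7, 1.87e6))
  expect_error(implied_dark_calcium(0, 1e6), "positive")
})

test_that("buffer capacity is reduced by the recoverin concentration", {
  expect_equal(adjust_buffer_capacity(100, 0), 100)
  expect_equal(adjust_buffer_capacity(100, 33.1), 66.9)
  expect_error(adjust_buffer_capacity(30, 33.1), "non-positive")
})

test_that("the assembled dark state reproduces the recoverin pool structure", {
  net <- wt_model()
  y0 <- initial_state(net)
  # RecT ~ 23.4 uM within 10%
  expect_equal(molecules_to_umolar(y0[["RecT"]]), 23.4, tolerance = 0.1)
  # pool ordering: RecT > RecRK > RecR_Ca
  expect_gt(y0[["RecT"]], y0[["RecRK"]])
  expect_gt(y0[["RecRK"]], y0[["RecR_Ca"]])
  # dark free Ca sits at the configured 0.6 uM and stays there
  expect_equal(y0[["Ca"]], 0.6)
  tr <- integrate_network(net, t_grid = c(0, 30, 60))
  expect_equal(tr$Ca[3], 0.6, tolerance = 0.02)
})

test_that("falling calcium releases kinase from the recoverin complex", {
  net <- wt_model()
  tr <- run_protocol(net, stimulus_protocol("step", 450, step_duration = 30),
                     horizon = 40, dt = 5e-3, auto_extend = FALSE)
  during <- tr$time > 1.5 & tr$time < 30
  expect_lt(min(tr$Ca_uM[during]), 0.3)          # light lowers Ca2+
  rk0 <- tr$RK[1]
  expect_gt(max(tr$RK[during]), 2 * rk0)         # free kinase rises
  # monotone release while Ca2+ is falling steeply
  i <- which(tr$time > 2 & tr$time < 10)
  expect_true(all(diff(tr$RK[i]) > -1e-6 * max(tr$RK)))
})
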