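test_that("photon flux converts through collecting area and species factor", {
  expect_equal(photons_to_isomerizations(10), 4)
  expect_equal(photons_to_isomerizations(10, species_factor = 2), 8)
  expect_equal(photons_to_isomerizations(0), 0)
})

test_that("mutant specs validate names and scaling semantics", {
  expect_error(mutant_spec(RKX = 2), "unknown protein")
  expect_error(mutant_spec(RK = -1), ">= 0")

  net <- wt_model()
  # identity spec: dark state and packed network bit-identical
  id <- apply_mutant(net, mutant_spec())
  expect_identical(initial_state(id), initial_state(net))
  expect_identical(rodcascade:::pack_network(id), rodcascade:::pack_network(net))

  # scaling a total then re-equilibrating conserves the scaled total exactly
  half <- apply_mutant(net, mutant_spec(Arr = 0.5, RGS = 2))
  y <- initial_state(half)
  arr_tot <- y[["Arr"]] + 2 * y[["Arr_di"]] + 4 * y[["Arr_tetra"]]
  expect_equal(arr_tot, 0.5 * net$params$Arr_total, tolerance = 1e-9)
  expect_equal(y[["RGS"]], 2 * net$params$RGS_total)

  # recoverin knockout leaves the kinase fully free at dark
  rec0 <- apply_mutant(net, mutant_spec(Rec = 0))
  y0 <- initial_state(rec0)
  expect_equal(unname(y0[c("RecT", "RecR_Ca", "RecRK")]), c(0, 0, 0))
  expect_equal(y0[["RK"]], net$params$RK_total)

  # oligomerization switch: kA4 = 0 and an all-monomer dark pool
  off <- apply_mutant(net, mutant_spec(oligomerization_off = TRUE))
  expect_equal(off$params$kA4, 0)
  yoff <- initial_state(off)
  expect_equal(yoff[["Arr"]], net$params$Arr_total)
  expect_equal(yoff[["Arr_di"]] + yoff[["Arr_tetra"]], 0)
})

test_that("protocols produce traces with the expected structure", {
  net <- wt_model()
  flat <- run_protocol(net, stimulus_protocol("flash", 0), horizon = 2,
                       dt = 1e-2, keep_species = FALSE, auto_extend = FALSE)
  expect_lt(max(abs(flat$deltaJ)), 1e-6)

  expect_error(run_protocol(net, stimulus_protocol("flash", 10), horizon = 0.5),
               "horizon")

  # flash family: monotonically increasing peak amplitudes
  fam <- c(4.8, 19.2, 76.8, 307.2, 1228.8, 4915.2)
  peaks <- vapply(fam, function(s) {
    max(run_protocol(net, stimulus_protocol("flash", s), horizon = 12,
                     dt = 5e-3, keep_species = FALSE,
                     auto_extend = FALSE)$deltaJ)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # a sub-saturating flash returns to within 1% of baseline
  tr <- run_protocol(net, stimulus_protocol("flash", 4.8), horizon = 30,
                     dt = 5e-3, keep_species = FALSE, auto_extend = FALSE)
  expect_lt(tail(tr$deltaJ, 1), 0.01)
})

test_that("an adapting background desensitizes without breaking recovery", {
  net <- wt_model()
  dark <- run_protocol(net, stimulus_protocol("flash", 1000, onset = 30),
                       horizon = 60, dt = 5e-3, keep_species = FALSE,
                       auto_extend = FALSE)
  lit <- run_protocol(net, stimulus_protocol("background_flash", 1000,
                                             background = 48, onset = 30),
                      horizon = 60, dt = 5e-3, keep_species = FALSE,
                      auto_extend = FALSE)
  base_lit <- lit$deltaJ[max(which(lit$time < 30))]
  # the background suppresses a substantial, sub-saturating fraction of the
  # circulating current
  expect_gt(base_lit, 0.3)
  expect_lt(base_lit, 0.9)
  # reduced incremental sensitivity: the same flash adds less suppression on
  # the adapting background than from darkness
  inc_dark <- max(dark$deltaJ) - 0
  inc_lit <- max(lit$deltaJ) - base_lit
  expect_lt(inc_lit, inc_dark)
  # the adapted response relaxes back to its pre-flash plateau
  expect_equal(tail(lit$deltaJ, 1), base_lit, tolerance = 0.05)
})

test_that("extra RK on an RGS-underexpressing background leaves tau_D alone", {
  s <- genotype_ladder("0.2x RGS UX", mutant_spec(RGS = 0.2))
  d <- genotype_ladder("3x RK/0.2x RGS", mutant_spec(RK = 3, RGS = 0.2))
  tau_s <- pepperberg_fit(s$strength, s$tsat)$tau_D
  tau_d <- pepperberg_fit(d$strength, d$tsat)$tau_D
  expect_lt(abs(tau_d / tau_s - 1), 0.10)
})

test_that("the recipe catalog covers the simulated experiments", {
  cat <- recipe_catalog()
  expect_true(all(c("flash_family", "rec_ko_family", "rgs_ux_rk_ox_double",
                    "class_tracking_sat", "table1_sweep") %in% names(cat)))
  wt5 <- vapply(cat$wt_rec_family$protocols, function(p) p$strength, numeric(1))
  expect_equal(wt5[1:3], c(9.44, 16.48, 34.24))
  wt6 <- vapply(cat$wt_rk_family$protocols, function(p) p$strength, numeric(1))
  expect_equal(wt6, c(3.2, 13.6, 34.4, 127.2, 362.4, 896))
  expect_equal(vapply(cat$rec_ox_4x$protocols, function(p) p$strength, numeric(1)),
               c(3, 6, 15, 29, 70, 157, 317, 570))
  expect_length(cat$table1_sweep$genotypes, 13)
  expect_equal(cat$class_tracking_sat$protocols[[1]]$strength, 118000)
  expect_equal(cat$rgs_ux_rk_ox_double$mutant$factors[["RGS"]], 0.2)
})
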