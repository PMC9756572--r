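test_that("matrix exponential agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  set.seed(4)
  for (n in c(3L, 12L, 27L)) {
    A <- matrix(rnorm(n * n), n)
    A <- A - diag(rowSums(abs(A))) # push the spectrum leftwards
    E1 <- dermvbe:::expm_dense(A * 0.4)
    E2 <- as.matrix(Matrix::expm(Matrix::Matrix(A * 0.4)))
    expect_equal(E1, E2, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("spectral segment propagation matches stepwise exponentials", {
  set.seed(5)
  n <- 10L
  A <- matrix(abs(rnorm(n * n)), n) * 0.5
  diag(A) <- 0
  A <- A - diag(colSums(A)) # Metzler, zero column sums
  x0 <- abs(rnorm(n))
  dts <- c(0.3, 1.1, 2.7)
  st <- dermvbe:::segment_propagate(A, x0, dts)
  x <- x0
  prev <- 0
  for (i in seq_along(dts)) {
    x <- drop(dermvbe:::expm_dense(A * (dts[i] - prev)) %*% x)
    expect_equal(st[i, ], x, tolerance = 1e-8, ignore_attr = TRUE)
    prev <- dts[i]
  }
  # mass conserved by the propagator
  expect_equal(rowSums(st), rep(sum(x0), length(dts)), tolerance = 1e-10)
})

test_that("build_skin lays out the compartment stack", {
  cmp <- fix_compound()
  f <- fix_spray()
  sys10 <- build_skin(cmp, f, skin_physiology(n_sc_layers = 10),
    dose_api = 0.01, dose_volume = 5e-3, area = 0.5, mode = "ivpt")
  expect_equal(sum(grepl("^sc_", sys10$names)), 10L)
  expect_equal(sys10$names[1L], "vehicle")
  expect_equal(utils::tail(sys10$names, 1L), "receptor")
  sysv <- build_skin(cmp, f, skin_physiology(),
    dose_api = 0.01, dose_volume = 5e-3, area = 0.5, mode = "in_vivo")
  expect_true(all(c("central", "peripheral", "eliminated", "removed")
    %in% sysv$names))
  expect_error(
    build_skin(cmp, f, skin_physiology(), 0.01, 5e-3, 0.5, mode = "franz"),
    "arg"
  )
})

test_that("steady-state flux matches the analytic series-membrane value", {
  cmp <- fix_compound()
  f <- fix_binary(viscosity = 1e-9) # negligible vehicle-side resistance
  for (N in c(1L, 2L, 5L)) {
    p <- skin_physiology(n_sc_layers = N, P_cell = 0)
    J_sim <- simulated_series_flux(cmp, f, p, area = 1, donor_conc = 1)
    J_an <- analytic_series_flux(cmp, f, p, area = 1, donor_conc = 1)
    expect_equal(J_sim, J_an, tolerance = 0.01)
  }
})

test_that("doubling every layer permeability doubles the SC-limited flux", {
  cmp <- fix_compound()
  f <- fix_binary(viscosity = 1e-9)
  # make the SC the only appreciable resistance
  p1 <- skin_physiology(P_cell = 0, D_ve = 1, D_dermis = 1, K_ve_water = 5)
  p2 <- p1
  p2$D_sclip <- 2 * p1$D_sclip
  J1 <- simulated_series_flux(cmp, f, p1, area = 1, donor_conc = 1)
  J2 <- simulated_series_flux(cmp, f, p2, area = 1, donor_conc = 1)
  expect_equal(J2 / J1, 2, tolerance = 0.02)
})

test_that("rhs closes the mass balance and respects equilibrium", {
  cmp <- fix_compound()
  f <- fix_binary()
  p <- skin_physiology(baseline_dermis_blood_flow = 0) # no uptake sink
  sys <- build_skin(cmp, f, p, dose_api = 0.01, dose_volume = 5e-3,
    area = 0.5, mode = "in_vivo")
  nsk <- sys$n_skin
  # partition equilibrium: amounts proportional to V * K in the skin stack
  x <- setNames(numeric(length(sys$names)), sys$names)
  x[seq_len(nsk)] <- sys$V_skin * sys$K_skin * 0.37
  d <- skin_rhs(x, sys)
  expect_lt(max(abs(d)), 1e-12)
  # zero state -> zero derivatives; total derivative always sums to zero
  expect_equal(unname(skin_rhs(x * 0, sys)), numeric(length(x)))
  x2 <- x
  x2[2L] <- x2[2L] * 3
  expect_lt(abs(sum(skin_rhs(x2, sys))), 1e-15)
  # empty vehicle cannot feed sc_1
  x3 <- x * 0
  x3["sc_1"] <- 0.01
  d3 <- skin_rhs(x3, sys, vehicle_volume = 0)
  expect_equal(unname(d3["vehicle"]), 0)
  expect_error(skin_rhs(c(x3[-1L], NaN), sys), "non-finite|length")
})

test_that("simulation handles degenerate doses and partitions", {
  cmp <- fix_compound()
  f <- fix_spray()
  p <- skin_physiology()
  sys0 <- build_skin(cmp, f, p, dose_api = 0, dose_volume = 0, area = 0.5,
    mode = "ivpt")
  res0 <- simulate_system(sys0, t_end = 10)
  expect_equal(max(abs(res0$amounts)), 0)

  pK0 <- skin_physiology(K_sclip_vehicle = 0)
  sysK <- build_skin(cmp, f, pK0, dose_api = 0.01, dose_volume = 5e-3,
    area = 0.5, mode = "ivpt")
  resK <- simulate_system(sysK, t_end = 24)
  expect_equal(resK$amounts[, "vehicle"],
    rep(0.01, nrow(resK$amounts)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(resK$amounts[, "receptor"]), 0)
})

test_that("receptor uptake is monotone and conservative across sweeps", {
  cmp <- fix_compound()
  f <- fix_spray()
  p <- skin_physiology()

  visc <- vapply(c(1, 100, 1e4, 1e5, 5e5), function(v) {
    receptor24(cmp, fix_spray(viscosity = v), p)
  }, 0)
  expect_true(all(diff(visc) <= 1e-9))

  sol <- vapply(c(0.1, 0.25, 0.4, 0.7, 1), function(s) {
    mod <- modify_formulation(f, p, "solubility", s)
    receptor24(cmp, mod$formulation, mod$physiology)
  }, 0)
  expect_true(all(diff(sol) <= 1e-9))

  ks <- vapply(c(0.5, 1, 2, 4, 8), function(k) {
    pk <- p
    pk$K_sclip_vehicle <- k
    receptor24(cmp, f, pk)
  }, 0)
  expect_true(all(diff(ks) >= -1e-9))

  # halving the SC stack strictly increases flux
  expect_gt(
    receptor24(cmp, f, skin_physiology(n_sc_layers = 10)),
    receptor24(cmp, f, p)
  )

  # mass balance and receptor monotonicity for the base case
  r <- run_ivpt(cmp, f, p)
  expect_lt(r$trace$mass_balance_error, 1e-6)
  expect_true(all(diff(r$trace$amounts[, "receptor"]) >= -1e-12))
  # total absorbed approaches the dissolved dose with a sink boundary
  sys <- build_skin(cmp, f, p, dose_api = 0.01, dose_volume = 5e-3,
    area = 0.5, mode = "ivpt")
  late <- simulate_system(sys, t_end = 5000, t_eval = c(0, 5000))
  expect_equal(unname(late$amounts[2L, "receptor"]), 0.01,
    tolerance = 0.01)
})

test_that("partition coefficient scales inversely with vehicle solubility", {
  expect_equal(partition_from_solubility(0.55, 2, 0.55), 2)
  expect_equal(partition_from_solubility(1.1, 2, 0.55), 1)
  s <- c(0.1, 0.2, 0.5, 1)
  expect_true(all(diff(partition_from_solubility(s, 2, 0.55)) < 0))
  expect_error(partition_from_solubility(-1, 2, 0.55), "positive")
})
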