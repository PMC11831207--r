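test_that("the wild-type population is an exact fixed point", {
  s <- make_strategy("pdne1")
  for (Rm in c(2, 6, 20)) {
    lc <- life_cycle(Rm)
    counts <- equilibrium_state(s, lc)
    for (i in 1:5) counts <- step_population(counts, s, lc)
    counts <- counts[counts > 0]
    expect_equal(sort(names(counts)), c("W/W|F", "W/W|M"))
    expect_equal(unname(counts[order(names(counts))]), c(1, 1),
                 tolerance = 1e-12)
  }
  expect_error(life_cycle(1), "Rm")
  expect_error(life_cycle(0.5), "Rm")
})

test_that("a culled population recovers monotonically to equilibrium", {
  s <- make_strategy("pdne1")
  lc <- life_cycle(6)
  init <- c("W/W|F" = 0.5, "W/W|M" = 1)   # half the females removed
  sim <- simulate_release(s, lc, release_schedule(0), horizon = 12,
                          init = init)
  f <- sim$series$females_rel
  expect_true(all(diff(f) > 0))
  expect_equal(f[13], 1, tolerance = 1e-6)
})

test_that("sterile-male releases at parity halve the juvenile cohort", {
  sit <- make_strategy("sit")
  lc <- life_cycle(6)
  eng <- drivebalance:::compile_engine(sit)
  counts <- drivebalance:::counts_to_vec(equilibrium_state(sit, lc), eng)
  rel <- counts * 0
  rel[sit$release_genotype] <- 1        # rho = 1: half of all matings
  st <- drivebalance:::engine_step(counts, eng, lc, rel)
  expect_equal(st$J, lc$Rm, tolerance = 1e-12)   # J0/2 = Rm
  expect_equal(st$load, 0.5, tolerance = 1e-12)
})

test_that("zero-release schedules leave the population flat", {
  sim <- simulate_release(make_strategy("sit"), life_cycle(6),
                          release_schedule(0), horizon = 10)
  expect_equal(sim$series$females_rel, rep(1, 11), tolerance = 1e-12)
  expect_equal(sim$series$males_rel, rep(1, 11), tolerance = 1e-12)
  # horizon 0: only the initial record
  sim0 <- simulate_release(make_strategy("sit"), life_cycle(6),
                           release_schedule(0.5), horizon = 0)
  expect_equal(nrow(sim0$series), 1L)
})

test_that("a single large release settles at the load-determined equilibrium", {
  s <- make_strategy("pdne1")
  Rm <- 6
  sim <- simulate_release(s, life_cycle(Rm),
                          release_schedule(1, cadence = "single"),
                          horizon = 80)
  p <- sim$allele_freq[, "pdne.G"]
  # the construct frequency is constant after the release: neutrality
  expect_equal(diff(range(p[-1])), 0, tolerance = 1e-10)
  # female count settles at (Rm(1-L) - 1)/(Rm - 1), with the load taken at
  # the hatchling census frequency q = p/(1-p)
  q <- p[81] / (1 - p[81])
  L <- reproductive_load(q)
  expect_equal(sim$series$females_rel[81], (Rm * (1 - L) - 1) / (Rm - 1),
               tolerance = 1e-8)
})

test_that("simulator frequencies match the analytic recursion", {
  # density dependence is uniform across genotypes, so allele-frequency
  # dynamics must be identical to the single-sex analytic model
  q0 <- 0.15
  gt <- c("W/W", "G/W", "G/G")
  hw <- c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2)

  # embryonic costs: adult census coincides with the hatchling census
  st <- make_strategy("pdne1", u = 0.7, s_edit = 0.8, h_edit = 0.6,
                      s_construct = 0.9, h_construct = 0.05,
                      timing = "early")
  init <- stats::setNames(c(hw, hw), c(paste0(gt, "|F"), paste0(gt, "|M")))
  sim <- simulate_release(st, life_cycle(6), release_schedule(0),
                          horizon = 15, init = init)
  qa <- analytic_recursion(q0, st$params, 15, census = "adult")
  expect_equal(sim$allele_freq[, "pdne.G"], qa, tolerance = 1e-10,
               ignore_attr = TRUE)

  # post-density-dependence costs, adults initialized at the analytic
  # model's post-selection state
  stL <- make_strategy("pdne1", u = 0.7, s_edit = 0.8, h_edit = 0.6,
                       s_construct = 0.9, h_construct = 0.05,
                       timing = "late")
  late <- vapply(paste0(gt, "|F"), function(k)
    viability(k, stL$arch, stL$params)$late_survival, numeric(1))
  hwL <- hw * late
  initL <- stats::setNames(c(hwL, hwL), c(paste0(gt, "|F"), paste0(gt, "|M")))
  simL <- simulate_release(stL, life_cycle(6), release_schedule(0),
                           horizon = 15, init = initL)
  qaL <- analytic_recursion(q0, stL$params, 15, census = "adult")
  expect_equal(simL$allele_freq[, "pdne.G"], qaL, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("time series serialize with stable columns and methods work", {
  sim <- simulate_release(make_strategy("pdne1"), life_cycle(6),
                          release_schedule(0.1), horizon = 5)
  df <- as.data.frame(sim)
  expect_equal(names(df)[1:3], c("generation", "females_rel", "males_rel"))
  expect_true("pdne.G" %in% names(df))
  expect_equal(names(df)[ncol(df)], "load")
  expect_output(print(sim), "gd_sim")
  expect_output(print(summary(sim)), "first passage")
  expect_silent(grDevices::pdf(NULL))
  expect_invisible(plot(sim))
  expect_invisible(plot(sim, what = "freq"))
  grDevices::dev.off()
})
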