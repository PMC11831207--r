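test_that("bisection brackets the minimal release rate", {
  st <- make_strategy("pdne1")
  lc <- life_cycle(6)
  r <- min_release_rate(st, lc, target = 0.8, horizon = 15, tol = 1e-4)
  expect_true(r$attainable)
  # rho* achieves the goal; rho* - 2*tol does not
  ok <- simulate_release(st, lc, release_schedule(r$rho_star), 15)
  expect_lte(min(ok$series$females_rel[-1]), 0.2 + 1e-9)
  just_below <- simulate_release(st, lc,
                                 release_schedule(r$rho_star - 2 * r$tol), 15)
  expect_gt(min(just_below$series$females_rel[-1]), 0.2)
  expect_equal(r$achieved_generation,
               which(ok$series$females_rel[-1] <= 0.2 + 1e-12)[1])
})

test_that("suppression is monotone in the release rate", {
  lc <- life_cycle(6)
  for (nm in c("pdne1", "sit", "fsridl")) {
    st <- make_strategy(nm)
    sup <- vapply(c(0.02, 0.1, 0.3, 1, 3), function(rho)
      suppression_achieved(simulate_release(st, lc, release_schedule(rho),
                                            horizon = 15)), numeric(1))
    expect_true(all(diff(sup) > -1e-12), label = paste(nm, "monotone"))
  }
})

test_that("degenerate searches behave sensibly", {
  st <- make_strategy("pdne1")
  lc <- life_cycle(6)
  # a vanishing target needs a vanishing release
  r0 <- min_release_rate(st, lc, target = 0.01, horizon = 10, tol = 1e-5)
  expect_lt(r0$rho_star, 0.01)
  # unattainable targets are flagged, not raised
  ru <- min_release_rate(make_strategy("sit"), life_cycle(20),
                         target = 0.95, horizon = 36, rho_max = 0.5)
  expect_false(ru$attainable)
  expect_true(is.na(ru$rho_star))
  expect_error(min_release_rate(st, lc, target = 0), "target")
})

test_that("fold efficiency is a guarded ratio", {
  lc <- life_cycle(6)
  a <- min_release_rate(make_strategy("sit"), lc, 0.8, 15)
  b <- min_release_rate(make_strategy("pdne1"), lc, 0.8, 15)
  expect_equal(fold_efficiency(a, a), 1)
  expect_gt(fold_efficiency(a, b), 1)
  b2 <- min_release_rate(make_strategy("pdne1"), lc, 0.8, 20)
  expect_error(fold_efficiency(a, b2), "horizon")
  ru <- min_release_rate(make_strategy("sit"), lc, 0.8, 15, rho_max = 0.1)
  expect_false(ru$attainable)
  expect_error(fold_efficiency(ru, b), "unattainable")
})

test_that("parameter sweeps respond in the documented direction", {
  st <- make_strategy("pdne1")
  lc <- life_cycle(6)
  # degenerate grid reproduces the baseline
  base <- parameter_sweep(st, "u", 1, lc, target = 0.8, horizon = 15)
  ref <- min_release_rate(st, lc, 0.8, 15)
  expect_equal(base$rho_star, ref$rho_star, tolerance = 1e-9)
  # heterozygous construct costs increase selection, hence release rates
  sw <- parameter_sweep(st, "h_construct", c(0, 0.05, 0.1), lc,
                        target = 0.8, horizon = 15)
  expect_true(all(diff(sw$rho_star) > 0))
  expect_error(parameter_sweep(st, "not_a_param", 1, lc), "not a genetic")
})

test_that("linkage correlation matches its closed form and boundary rules", {
  expect_equal(linkage_correlation(c(0.3, 0.3, 0.3)), 1)
  expect_equal(linkage_correlation(c(0.09, 0.3, 0.3)), 0)
  p <- c(0.2, 0.5, 0.3)
  expect_equal(linkage_correlation(p),
               (p[1] - p[2] * p[3]) /
                 sqrt(p[2] * (1 - p[2]) * p[3] * (1 - p[3])))
  expect_error(linkage_correlation(c(0, 0, 0.3)), "absent or fixed")
  expect_error(linkage_correlation(c(0.3, 1, 0.3)), "absent or fixed")
})

test_that("linked cleave-and-rescue boosting decays by recombination", {
  st <- make_strategy("pdne1", booster = "cnr")   # r = 0.05, coupled release
  sim <- simulate_release(st, life_cycle(6),
                          release_schedule(1, cadence = "single"),
                          horizon = 30)
  co <- linkage_correlation(sim)
  expect_true(is.na(co[1]))          # booster absent before the release
  expect_gt(co[2], 0.9)              # near-complete coupling on release
  expect_true(all(diff(co[-1]) < 0)) # recombination erodes the correlation
  # the booster itself declines once uncoupled
  b <- sim$allele_freq[, "cnr_booster.B_cnr"]
  expect_lt(b[31], b[2])
})

test_that("homing boosters are transient: boost the construct, then vanish", {
  st <- make_strategy("pdne1", sex_limited_edit = "female_only",
                      booster = "homing")
  sim <- simulate_release(st, life_cycle(6),
                          release_schedule(1, cadence = "single"),
                          horizon = 60)
  b <- sim$allele_freq[, "homing_booster.H_homing"]
  g <- sim$allele_freq[, "pdne.G"]
  expect_true(all(diff(b[-1]) < 1e-12))     # monotone loss after release
  expect_lt(b[61], 0.25 * b[2])
  expect_gt(g[61], g[2])                    # the construct was boosted
  # ... and plateaus once the booster is effectively gone
  expect_lt(abs(g[61] - g[51]), 1e-3)
})
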