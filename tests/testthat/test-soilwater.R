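test_that("initial moisture interpolates between LL15 and DUL", {
  s <- toy_soil(ll15 = 0.10, dul = 0.30)
  expect_equal(initialize_moisture(s, 0)$sw, 0.10)
  expect_equal(initialize_moisture(s, 1)$sw, 0.30)
  expect_equal(initialize_moisture(s, 0.6)$sw, 0.22)
  expect_error(initialize_moisture(s, 1.2), "\\[0, 1\\]")
})

test_that("rain partition conserves water and respects the threshold", {
  s <- make_soil("loam", 100)
  expect_equal(partition_rain(s, 0), list(runoff = 0, infiltration = 0))
  p5 <- partition_rain(s, 5)
  expect_equal(p5$runoff, 0)
  expect_equal(p5$infiltration, 5)
  p40 <- partition_rain(s, 40)
  expect_equal(p40$runoff + p40$infiltration, 40)
  ro <- vapply(seq(0, 80, 5), function(r) partition_rain(s, r)$runoff,
               numeric(1))
  expect_true(all(diff(ro) >= 0))
})

test_that("the drainage cascade moves above-DUL water down and conserves", {
  s <- make_soil("loam", 90) # three layers
  s$sw <- s$dul
  out <- drain_cascade(s)
  expect_equal(out$soil$sw, s$sw) # fixed point at DUL
  expect_equal(out$drainage, 0)

  s2 <- toy_soil(nlay = 2)
  s2$sw <- c(s2$sat[1], s2$dul[2])
  out2 <- drain_cascade(s2) # coefficient 0.5 from make_soil defaults
  moved <- 0.5 * (s2$sat[1] - s2$dul[1]) * s2$thickness_mm[1]
  expect_equal((s2$sat[1] - out2$soil$sw[1]) * s2$thickness_mm[1], moved)
  expect_equal((out2$soil$sw[2] - s2$dul[2]) * s2$thickness_mm[2],
               0.5 * moved, tolerance = 1e-9) # half drains on through layer 2

  before <- sum(s2$sw * s2$thickness_mm) + 30
  out3 <- drain_cascade(s2, infiltration = 30)
  after <- sum(out3$soil$sw * out3$soil$thickness_mm) + out3$drainage
  expect_equal(before, after, tolerance = 1e-9)
})

test_that("soil evaporation is canopy-shaded, bounded and two-stage", {
  s <- initialize_moisture(make_soil("loam", 100), 1)
  bare <- soil_evaporation(s, radn = 20, lai = 0)$evaporation
  shaded <- soil_evaporation(s, radn = 20, lai = 6)$evaporation
  expect_lt(shaded, 0.1 * bare)
  # at the air-dry limit nothing evaporates
  dry <- s
  dry$sw[1] <- 0.5 * dry$ll15[1]
  expect_equal(soil_evaporation(dry, 25, 0)$evaporation, 0)
  # cumulative drawdown never exceeds available water and slows in stage II
  e <- numeric(30)
  for (i in 1:30) {
    st <- soil_evaporation(s, 25, 0)
    e[i] <- st$evaporation
    s <- st$soil
  }
  expect_true(all(s$sw >= 0.5 * s$ll15 - 1e-12))
  expect_lt(mean(e[15:30]), mean(e[1:3]))
})

test_that("potential supply follows the kl convention with pro-rata roots", {
  s <- toy_soil(ll15 = 0.10, dul = 0.30, kl = 0.07, thickness = 300)
  s$sw <- 0.20 # sw - ll15 = 0.10
  expect_equal(potential_supply(s, 300), 0.07 * 0.10 * 300) # 2.1 mm
  expect_equal(potential_supply(s, 150), 0.5 * 2.1)
  s$sw <- s$ll15
  expect_equal(potential_supply(s, 300), 0)
})

test_that("potential supply is monotone in moisture and rooting depth", {
  s <- initialize_moisture(make_soil("silty clay loam", 150), 0.5)
  sup <- vapply(seq(0, 1500, 100), function(rd) potential_supply(s, rd),
                numeric(1))
  expect_true(all(diff(sup) >= 0))
  sup2 <- vapply(seq(0, 1, 0.1), function(f) {
    potential_supply(initialize_moisture(s, f), 1500)
  }, numeric(1))
  expect_true(all(diff(sup2) >= 0))
})

test_that("transpiration extraction is proportional, bounded and guarded", {
  s <- toy_soil(nlay = 2)
  s$sw <- 0.20
  out <- extract_transpiration(s, 1, 600)
  expect_equal((0.20 - out$sw[1]) * 300, 0.5, tolerance = 1e-9)
  expect_equal(out$sw[1], out$sw[2]) # symmetric layers share equally
  expect_identical(extract_transpiration(s, 0, 600)$sw, s$sw)
  expect_true(all(extract_transpiration(
    s, potential_supply(s, 600), 600)$sw >= s$ll15 - 1e-9))
  expect_error(extract_transpiration(s, 99, 600), "exceeds supply")
})

test_that("season-long water balance closes below 1e-6 mm", {
  for (a in c("WW", "ED")) {
    w <- generate_season(archetype(a), 1, seed = 31)
    s <- run_season(w, make_soil("loam", 200), cultivar("short"),
                    management())
    expect_lt(water_balance_closure(s$ledger), 1e-6)
  }
})
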