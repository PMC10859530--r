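test_that("phenology targets are fixed when the photoperiod slope is zero", {
  cv <- cultivar("short")
  expect_identical(advance_phenology(500, cv, daylength = 11),
                   advance_phenology(500, cv, daylength = 15))
  cv2 <- cultivar("short", photoperiod_slope = 10)
  p_short_day <- advance_phenology(440, cv2, daylength = 11)$phase
  p_long_day <- advance_phenology(440, cv2, daylength = 15)$phase
  expect_gte(p_short_day, p_long_day) # long days delay floral initiation
})

test_that("maturity groups order flowering by leaf number", {
  tt_fl <- vapply(c("short", "medium", "full"), function(m) {
    phase_targets(cultivar(m))[["flowering"]]
  }, numeric(1))
  expect_true(all(diff(tt_fl) > 0))
  expect_identical(cultivar("short")$leaf_no, 15L)
  expect_identical(cultivar("full")$leaf_no, 19L)
})

test_that("anthesis date equals summed targets over daily thermal time", {
  # targets summing to 700 deg-days to flowering, constant 14 deg-days/day
  cv <- cultivar("short", tt_sow_germ = 50, tt_germ_emerg = 50,
                 tt_emerg_endjuv = 200, tt_endjuv_to_init = 100,
                 tt_init_flag = 200, tt_flag_flower = 100)
  w <- flat_weather(420, tmax = 30, tmin = 20, radn = 18, rain = 6)
  s <- run_season(w, make_soil("clay", 200), cv,
                  management("05-01", initial_fasw = 1))
  expect_equal(s$anthesis_doy - s$sowing_doy + 1, 50) # 700 / 14
})

test_that("leaf area follows the TPLA logistic and scales with density", {
  cv <- cultivar("short")
  mid <- leaf_area(cv$tpla_inflection, cv, density = 10)
  expect_equal(mid, cv$tpla_max * 1.3 / 2 * 10, tolerance = 1e-12)
  expect_equal(leaf_area(400, cv, 20), 2 * leaf_area(400, cv, 10))
  expect_gt(leaf_area(2000, cultivar("full"), 10),
            leaf_area(2000, cultivar("short"), 10))
  # senescence: linear decline to zero at maturity
  expect_lt(leaf_area(900, cv, 10, tt_since_flowering = 500,
                      lai_at_flowering = 4), 4)
  expect_equal(leaf_area(900, cv, 10,
                         tt_since_flowering = cv$tt_flower_sgf +
                           cv$tt_sgf_egf + cv$tt_egf_mat,
                         lai_at_flowering = 4), 0)
})

test_that("grain set follows the growth-rate / dm_per_seed relation", {
  expect_equal(grain_number(2.5, 1, 0.00099), 2525.2525, tolerance = 1e-4)
  expect_equal(grain_number(0, 20), 0)
  expect_equal(reported_yield(5.0), 5.714286, tolerance = 1e-6)
})

test_that("the hourly transpiration of an LT cultivar never exceeds its cap", {
  w <- generate_season(archetype("ED"), 3, seed = 41)
  for (cap in c(0.4, 0.9)) {
    s <- run_season(w, make_soil("loam", 200), cultivar("medium", cap),
                    management())
    expect_lte(max(s$hourly_transp), cap)
  }
})

test_that("LT and non-LT runs are identical when demand never hits the cap", {
  # a cool, humid season keeps hourly demand small
  a <- archetype("WW")
  a$diurnal_range <- 5
  a$tmean_annual <- 10
  w <- generate_season(a, 1, seed = 17)
  soil <- make_soil("clay", 200)
  s_non <- run_season(w, soil, cultivar("short", Inf), management())
  s_lt <- run_season(w, soil, cultivar("short", 0.9), management())
  expect_lt(max(s_non$hourly_transp), 0.9) # premise: cap never reached
  expect_identical(s_non$daily, s_lt$daily)
  expect_identical(s_non$yield, s_lt$yield)
})

test_that("the LT trait saves water by flowering on paired inputs", {
  soil <- make_soil("loam", 200)
  for (i in 1:5) {
    w <- generate_season(archetype("MD"), i, seed = 23)
    s_non <- run_season(w, soil, cultivar("medium", Inf), management())
    s_lt <- run_season(w, soil, cultivar("medium", 0.9), management())
    expect_lte(s_lt$transp_at_flowering, s_non$transp_at_flowering + 1e-9)
    expect_gte(s_lt$pasw_at_flowering, s_non$pasw_at_flowering - 1e-9)
  }
})

test_that("a rainless season at 20% initial moisture fails", {
  a <- archetype("ED")
  a$p01[] <- 0
  a$p11[] <- 0
  w <- generate_season(a, 1, seed = 2)
  s <- run_season(w, make_soil("sandy loam", 150), cultivar("short"),
                  management(initial_fasw = 0.2))
  expect_true(s$failed)
  expect_true(is.na(s$yield))
  expect_error(grain_yield(s), "grain")
})

test_that("season outputs respect basic physical bounds", {
  w <- generate_season(archetype("LD"), 6, seed = 77)
  s <- run_season(w, make_soil("loam", 200), cultivar("full"), management())
  d <- s$daily
  expect_true(all(d$waterSD >= 0 & d$waterSD <= 1))
  expect_true(all(d$lai >= 0))
  expect_true(all(d$biomass >= 0))
  expect_true(all(diff(d$cum_tt) >= 0))
  expect_equal(rowSums(s$hourly_transp), d$transpiration, tolerance = 1e-9)
  expect_equal(s$yield, s$dry_yield / 0.875)
  # transpiration cannot exceed initial store plus infiltration
  infil <- sum(s$ledger$rain - s$ledger$runoff)
  expect_lte(s$total_transpiration,
             pawc(make_soil("loam", 200)) + infil)
  expect_error(run_season(w[1:200, ], make_soil("loam", 200),
                          cultivar("short"), management()), "365")
})
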