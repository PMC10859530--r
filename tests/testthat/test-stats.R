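test_that("the mixed model recovers a known trait effect", {
  d <- simulate_gxe_table(n_loc = 4, n_year = 6, trait_eff = c(nonLT = 0,
                                                               LT = 0.3),
                          seed = 10)
  f <- fit_mixed(preset_spec("eq1"), d, method = "REML")
  expect_true(f$converged)
  est <- lme4::fixef(f$fit)[["traitnonLT"]]
  se <- summary(f$fit)$coefficients["traitnonLT", "Std. Error"]
  expect_lt(abs(-est - 0.3), 2 * se) # nonLT vs LT contrast
  # row order cannot matter
  f2 <- fit_mixed(preset_spec("eq1"), d[sample(nrow(d)), ], method = "REML")
  expect_equal(lme4::fixef(f$fit), lme4::fixef(f2$fit), tolerance = 1e-6)
})

test_that("zero between-year variation collapses the year variance", {
  d <- simulate_gxe_table(3, 5, sd_year = 0, sd_res = 0.05, seed = 4)
  f <- fit_mixed(preset_spec("eq4"), d, method = "REML")
  vc <- as.data.frame(lme4::VarCorr(f$fit))
  vy <- vc$vcov[vc$grp == "year:location"]
  expect_lt(vy, 0.01)
})

test_that("backward AIC selection respects marginality and reduces AIC", {
  spurious <- logical(0)
  for (sd in c(13, 14, 15)) {
    d <- simulate_gxe_table(4, 6,
                            maturity_eff = c(short = 0, medium = 0,
                                             full = 0),
                            planting_eff = c("05-01" = 0, "05-15" = 0,
                                             "06-01" = 0),
                            trait_eff = c(nonLT = 0, LT = 0.5),
                            trait_env = rbind(nonLT = c(WW = 0, LD = 0,
                                                        MD = 0, ED = 0),
                                              LT = c(WW = -0.3, LD = 0,
                                                     MD = 0.3, ED = 0.5)),
                            seed = sd)
    full <- fit_mixed(preset_spec("full"), d, method = "ML")
    st <- stepwise_backward_aic(preset_spec("full"), d)
    expect_lte(st$final_AIC, full$AIC)
    # the generating trait and environment structure is always kept
    expect_true(all(c("trait", "env_w") %in% st$spec$fixed))
    # marginality: every interaction's factors appear as retained terms
    for (tm in grep(":", st$spec$fixed, value = TRUE)) {
      for (fac in strsplit(tm, ":")[[1]]) {
        expect_true(fac %in% st$spec$fixed)
      }
    }
    spurious <- c(spurious, "maturity:planting" %in% st$spec$fixed)
  }
  # interactions absent from the generating model are usually eliminated
  # (AIC keeps a noise term now and then; that is its known liberality)
  expect_lte(sum(spurious), 1)
})

test_that("a strong cell-specific effect keeps high-order structure", {
  d <- simulate_gxe_table(4, 8, sd_res = 0.2, seed = 21)
  idx <- d$trait == "LT" & d$maturity == "full" & d$env_w == "ED" &
    d$planting == "06-01"
  d$yield[idx] <- d$yield[idx] + 3
  st <- stepwise_backward_aic(preset_spec("full"), d)
  expect_true(any(vapply(st$spec$fixed, function(t) {
    length(strsplit(t, ":")[[1]]) == 4
  }, logical(1))))
})

test_that("the likelihood ratio matches brute force and handles identity", {
  d <- simulate_gxe_table(3, 5, seed = 6)
  red <- fit_mixed(preset_spec("eq4"), d, method = "ML")
  full <- fit_mixed(preset_spec("full"), d, method = "ML")
  lr <- likelihood_ratio(red, full)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$statistic, max(0, 2 * (full$logLik - red$logLik)),
               tolerance = 1e-10)
  expect_equal(lr$df, attr(stats::logLik(full$fit), "df") -
                 attr(stats::logLik(red$fit), "df"))
  same <- likelihood_ratio(red, red)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio(full, red), "not nested")
})

test_that("Tukey comparisons are gated on F and letter groups separate", {
  d <- simulate_gxe_table(4, 6, env_eff = c(WW = 0, LD = 0, MD = 0, ED = 0),
                          sd_res = 0.4, seed = 8)
  f0 <- fit_mixed(preset_spec("eq1"), d, method = "REML")
  t0 <- tukey_hsd(f0, "env_w")
  if (!t0$performed) {
    expect_gte(t0$f_p, 0.05)
  } else {
    # equal generating means: no pair should separate strongly
    expect_gt(min(t0$pairs$p.value), 0.001)
  }
  d2 <- simulate_gxe_table(4, 6, env_eff = c(WW = 4, LD = 0, MD = 0, ED = 0),
                           sd_res = 0.4, seed = 8)
  f2 <- fit_mixed(preset_spec("eq1"), d2, method = "REML")
  t2 <- tukey_hsd(f2, "env_w")
  expect_true(t2$performed)
  expect_equal(nrow(t2$pairs), choose(4, 2))
  ww_letter <- t2$letters$letter[t2$letters$level == "WW"]
  others <- t2$letters$letter[t2$letters$level != "WW"]
  expect_false(ww_letter %in% others)
})

test_that("rmse matches hand values and a brute-force loop", {
  expect_equal(rmse(52, 53), 1)
  expect_equal(rmse(c(3, 4), c(3, 4)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(2)
  o <- rnorm(50); s <- rnorm(50)
  acc <- 0
  for (i in seq_along(o)) acc <- acc + (o[i] - s[i])^2
  expect_equal(rmse(o, s), sqrt(acc / 50), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal-length")
})

test_that("report writes present sections, flags absent ones, repeats bytes", {
  dir <- withr::local_tempdir()
  tabs <- list(relative_change = data.frame(archetype = c("WW", "ED"),
                                            mean_rel = c(0.1, 0.9),
                                            sd_rel = c(0.05, 0.3),
                                            n = c(5, 5)))
  report(tabs, file.path(dir, "r1"))
  report(tabs, file.path(dir, "r2"))
  s1 <- readLines(file.path(dir, "r1", "summary.txt"))
  expect_identical(s1, readLines(file.path(dir, "r2", "summary.txt")))
  expect_true(any(grepl("\\[runs\\] absent", s1)))
  expect_true(file.exists(file.path(dir, "r1", "relative_change.csv")))
})
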