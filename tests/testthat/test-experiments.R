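make_small_design <- function(n_years = 5, seed = 42) {
  sites <- generate_gradient_sites(5)
  factorial_design(sites[3, ], n_years = n_years,
                   maturities = c("short", "medium", "full"),
                   plantings = c("05-01", "05-15", "06-01"),
                   seed = seed)
}

test_that("the factorial enumerates every cell and pairs traits exactly", {
  des <- make_small_design()
  tab <- run_factorial(des)
  expect_equal(nrow(tab), 2 * 3 * 3 * 1 * 5) # 90 records
  key <- c("site", "year", "maturity", "planting")
  lt <- tab[tab$trait == "LT", ]
  nl <- tab[tab$trait == "nonLT", ]
  m <- merge(nl, lt, by = key, suffixes = c(".n", ".l"))
  expect_equal(nrow(m), 45)
  expect_identical(m$sowing_doy.n, m$sowing_doy.l)
  expect_identical(m$season_rain.n, m$season_rain.l)
  expect_identical(m$archetype.n, m$archetype.l)
  # end-to-end determinism under the master seed
  tab2 <- run_factorial(make_small_design())
  expect_identical(tab, tab2)
  tab3 <- run_factorial(make_small_design(seed = 43))
  expect_false(identical(tab$yield, tab3$yield))
})

test_that("relative change is a pair-first percentage with exclusions", {
  tab <- data.frame(
    site = 1, year = rep(1:3, each = 2),
    archetype = rep(c("MD", "MD", "WW"), each = 2),
    trait = rep(c("nonLT", "LT"), 3),
    maturity = "short", planting = "05-01",
    yield = c(4.0, 4.32, 5.0, 5.6, 0, 2),
    failed = FALSE
  )
  rc <- relative_change(tab, by = "archetype")
  md <- rc[rc$archetype == "MD", ]
  expect_equal(md$mean_rel, mean(c(8, 12)))  # (+8, +12) -> +10
  expect_equal(md$n, 2)
  expect_equal(attr(rc, "excluded"), 1)      # zero-yield baseline dropped
  same <- tab
  same$yield <- rep(c(3, 3), 3)
  expect_equal(relative_change(same, by = NULL)$mean_rel, 0)
})

test_that("moisture sensitivity spans the levels with drought-side spread", {
  site <- generate_gradient_sites(5)[4, ]
  out <- sensitivity_initial_moisture(site, levels = c(0.2, 0.6, 0.9),
                                      n_years = 8, seed = 3)
  expect_equal(out$level, c(0.2, 0.6, 0.9))
  expect_true(all(out$n > 0))
  expect_true(all(is.finite(out$mean_rel)))
  expect_gte(out$mean_rel[1], 0) # LT never hurts on the drought-prone site
})

test_that("cap sensitivity returns per-archetype rows over the cap grid", {
  site <- generate_gradient_sites(5)[5, ]
  out <- sensitivity_lt_threshold(site, caps = c(0.2, 0.8), n_years = 8,
                                  seed = 3)
  expect_setequal(unique(out$cap), c(0.2, 0.8))
  for (a in intersect(unique(out$archetype), c("MD", "ED"))) {
    lo <- out[out$cap == 0.2 & out$archetype == a, ]
    hi <- out[out$cap == 0.8 & out$archetype == a, ]
    if (nrow(lo) && nrow(hi)) {
      expect_gte(lo$mean_rel, hi$mean_rel)
      expect_gte(lo$sd_rel, hi$sd_rel)
    }
  }
})

test_that("best combination maximises mean yield with deterministic ties", {
  tab <- expand.grid(site = 1, year = 1:2, trait = "nonLT",
                     maturity = c("short", "full"),
                     planting = c("05-01", "06-01"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$failed <- FALSE
  tab$yield <- 4
  tab$yield[tab$maturity == "full" & tab$planting == "05-01"] <- 5
  bc <- best_combination(tab)
  expect_identical(bc$maturity, "full")
  expect_identical(bc$planting, "05-01")
  ties <- tab
  ties$yield <- 4 # all equal: earlier planting, shorter maturity win
  bt <- best_combination(ties)
  expect_identical(bt$maturity, "short")
  expect_identical(bt$planting, "05-01")
  allfail <- tab
  allfail$failed <- TRUE
  expect_true(best_combination(allfail)$all_failed)
})

test_that("terminal-drought sites avoid the full-season maturity", {
  # a low-rainfall site whose droughts strike at or after flowering
  # (late / mid-season types); early droughts that break with midsummer
  # rains can instead reward later maturities, so they are excluded here
  site <- generate_gradient_sites(5)[5, ]
  site$w_WW <- 0; site$w_LD <- 0.4; site$w_MD <- 0.6; site$w_ED <- 0
  des <- factorial_design(site, n_years = 8,
                          traits = c(nonLT = Inf),
                          maturities = c("short", "medium", "full"),
                          plantings = "05-01", seed = 11)
  bc <- best_combination(run_factorial(des))
  expect_true(bc$maturity %in% c("short", "medium"))
})

test_that("envirotype_runs joins cluster labels back onto the table", {
  sites <- generate_gradient_sites(5)
  des <- factorial_design(sites[4, ], n_years = 12,
                          maturities = "medium", plantings = "05-15",
                          seed = 9)
  tab <- run_factorial(des, keep_trajectories = TRUE)
  out <- envirotype_runs(tab, k_range = 2:3, seed = 1)
  expect_true("env_w" %in% names(out))
  expect_equal(nrow(out), nrow(tab))
  # both trait rows of a season share the non-LT run's label
  key <- paste(out$site, out$year)
  for (k in unique(key)) {
    expect_length(unique(out$env_w[key == k]), 1)
  }
  expect_error(envirotype_runs(run_factorial(des)), "keep_trajectories")
})
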