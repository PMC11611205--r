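test_that("percent change follows the disparity sign convention", {
  # worked example from the published top-producer table
  expect_equal(percent_change(0.932, 0.742), 20.3863, tolerance = 1e-4)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.5, 0.6), -20)
  expect_true(is.na(percent_change(0, 0.5)))
  # antisymmetry: equal gains and losses relative to the same fmi_p
  d <- 0.07
  expect_equal(percent_change(0.7, 0.7 - d), -percent_change(0.7, 0.7 + d))
})

test_that("published worked-example pairs reproduce reported disparities", {
  ref <- worked_example_fmi()
  expect_equal(nrow(ref), 25)
  pc <- percent_change(ref$fmi_p, ref$mean_fmi_c)
  expect_equal(pc[ref$country == "United States of America"], 20.36,
               tolerance = 0.005) # 0.1 percentage point
  expect_equal(pc[ref$country == "Iceland"], 7.33, tolerance = 0.014)
  expect_equal(pc[ref$country == "Norway"], 6.89, tolerance = 0.015)
})

test_that("an identity relationship regresses to the identity line", {
  agg <- tibble::tibble(
    country_id = sprintf("C%d", 1:10), derivation = "proportional",
    fmi_p = seq(0.1, 0.9, length.out = 10),
    fmi_c = seq(0.1, 0.9, length.out = 10)
  )
  fit <- fit_fmi_relationship(agg)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_fmi_relationship(agg[1:2, ]),
               class = "seatrace_validation_error")
})

test_that("a constant import mix recovers the fixed blending share as slope", {
  sw <- star_world(hub_fmi = 0.5)
  out <- run_derivations(sw$balance, sw$trade, sw$fmi,
                         derivations = "guillen")
  fit <- fit_fmi_relationship(out$aggregates)
  expect_equal(fit$slope, 0.74, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.26 * 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("regression matches an independent normal-equations fit", {
  w <- generate_world(world_config(
    n_countries = 15, n_groups = 3, n_hubs = 2, seed = 1
  ))
  inputs <- prepare_world_inputs(w)
  out <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
  fit <- fit_fmi_relationship(out$aggregates)
  for (d in fit$derivation) {
    sub <- out$aggregates[out$aggregates$derivation == d, ]
    ne <- normal_equation_fit(sub$fmi_p, sub$fmi_c)
    expect_equal(fit$slope[fit$derivation == d], unname(ne["slope"]),
                 tolerance = 1e-9, info = d)
    expect_equal(fit$intercept[fit$derivation == d], unname(ne["intercept"]),
                 tolerance = 1e-9, info = d)
  }
})

test_that("trader rankings follow pooled volumes with lexicographic ties", {
  mk <- function(rep, par, dir, w) {
    tibble::tibble(
      reporter_id = rep, partner_id = par, direction = dir,
      product_code = "S01A", product_desc = "fish", year = 2015L,
      product_weight_t = w, is_food = TRUE, farmed_flag = "unknown",
      live_weight_t = w, product_group = "Pelagic Fish"
    )
  }
  trade <- dplyr::bind_rows(
    mk("A", "D", "export", 5), mk("B", "D", "export", 3),
    mk("C", "D", "export", 2), mk("D", "A", "import", 10)
  )
  rk <- rank_traders(trade)
  expect_equal(rk$share_of_global_exports[match(c("A", "B", "C"),
                                                rk$country_id)],
               c(0.5, 0.3, 0.2))
  expect_equal(rk$country_id[rk$export_rank == 1], "A")
  expect_equal(rk$country_id[rk$import_rank == 1], "D")
  expect_equal(rk$share_of_global_imports[rk$country_id == "D"], 1)
  # ties broken lexicographically
  tied <- dplyr::bind_rows(mk("B", "D", "export", 5), mk("A", "D", "export", 5))
  rk2 <- rank_traders(tied)
  expect_equal(rk2$country_id[rk2$export_rank == 1], "A")
})

test_that("rankings on a generated world match a groupby-sum oracle", {
  w <- generate_world(world_config(
    n_countries = 10, n_groups = 3, n_hubs = 2, seed = 8
  ))
  inputs <- prepare_world_inputs(w)
  rk <- rank_traders(inputs$trade)
  exp_rows <- inputs$trade[inputs$trade$direction == "export" &
                             inputs$trade$live_weight_t > 0, ]
  want <- c(tapply(exp_rows$live_weight_t, exp_rows$reporter_id, sum))
  got <- setNames(rk$exports_t, rk$country_id)[names(want)]
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_equal(
    rk$n_export_partners[match(names(want), rk$country_id)],
    as.numeric(tapply(exp_rows$partner_id, exp_rows$reporter_id,
                      function(x) length(unique(x))))
  )
})

test_that("partner breakdowns report shares, FMI and coverage", {
  w <- generate_world(world_config(
    n_countries = 10, n_groups = 3, n_hubs = 2, seed = 8
  ))
  inputs <- prepare_world_inputs(w)
  rk <- rank_traders(inputs$trade)
  top <- rk$country_id[rk$import_rank == 1]
  bd <- partner_breakdown(inputs$trade, top, "import", inputs$fmi, top_k = 3)
  expect_lte(nrow(bd), 3)
  expect_true(all(diff(bd$volume_t) <= 0))
  expect_lte(attr(bd, "coverage"), 1 + 1e-12)
  expect_true(all(!is.na(bd$partner_fmi_p)))
  full <- partner_breakdown(inputs$trade, top, "import", top_k = Inf)
  expect_equal(attr(full, "coverage"), 1, tolerance = 1e-12)
})

test_that("full runs are reproducible and mode-aware", {
  w <- generate_world(world_config(
    n_countries = 10, n_groups = 3, n_hubs = 2,
    aquaculture_fraction = 0.5, seed = 12
  ))
  inputs <- list(
    balance = w$balance, trade = w$trade, harmonization = w$harmonization,
    fmi = w$fmi, covariates = w$covariates, conversion = w$conversion,
    group_mapping = w$group_mapping
  )
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_full_analysis(inputs, out1)
  r2 <- run_full_analysis(inputs, out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_equal(r1$manifest$config_hash, r2$manifest$config_hash)

  # unknown derivation is a configuration error
  expect_error(run_full_analysis(inputs, out1, derivations = "mrio"),
               class = "seatrace_config_error")

  # mode row counts differ by exactly the countries whose trade vanished
  filt <- filter_trade(w$trade, w$harmonization)
  core_reps <- unique(filt$records$reporter_id)
  kept <- exclude_aquaculture(
    classify_group(assign_conversion(filt$records, w$conversion),
                   w$group_mapping),
    aquaculture_rules()
  )$records
  excl_reps <- unique(kept$reporter_id)
  lost <- setdiff(intersect(core_reps, unique(w$balance$country_id)),
                  excl_reps)
  expect_equal(r1$core$n_countries - r1$no_aquaculture$n_countries,
               length(lost))
})
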