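test_that("consumption follows the balance identity with a zero floor", {
  bal <- tibble::tibble(
    country_id = "A", product_group = "Pelagic Fish", year = 2015L,
    production_t = c(50, 0, 5), imports_t = c(10, 0, 1),
    exports_t = c(20, 0, 10), food_supply_t = 0
  )
  expect_warning(out <- compute_consumption(bal),
                 class = "seatrace_floor_warning")
  expect_equal(out$consumption_t, c(40, 0, 0))
  expect_equal(out$consumption_t, pmax(0, with(bal, production_t +
                                                 imports_t - exports_t)))
})

test_that("global FMI is the production-share-weighted mean", {
  bal <- tibble::tibble(
    country_id = c("A", "B"), product_group = "Pelagic Fish", year = 2015L,
    production_t = c(100, 100), imports_t = 0, exports_t = 0,
    food_supply_t = 100
  )
  fmi <- tibble::tibble(country_id = c("A", "B"), fmi = c(0.4, 0.8))
  expect_equal(compute_global_fmi(bal, fmi)$fmi_glbl, 0.6)
  solo <- bal[1, ]
  expect_equal(compute_global_fmi(solo, fmi)$fmi_glbl, 0.4)
  expect_error(compute_global_fmi(bal, fmi[1, ]),
               class = "seatrace_validation_error")
})

test_that("import FMI expands the partner sum as in the hand example", {
  shares <- tibble::tibble(
    reporter_id = "R", product_group = "Pelagic Fish",
    partner_id = c("J1", "J2"), share = c(0.6, 0.4)
  )
  comps <- tibble::tibble(
    partner_id = c("J1", "J2"), product_group = "Pelagic Fish",
    p_pe = c(0.5, 0.5), p_ie = c(0.5, 0.5)
  )
  fmi <- tibble::tibble(country_id = c("J1", "J2"), fmi = c(0.8, 0.2))
  glbl <- tibble::tibble(product_group = "Pelagic Fish", fmi_glbl = 0.5)
  out <- compute_fmi_imports(shares, comps, fmi, glbl)
  expect_equal(out$fmi_i, 0.6 * (0.5 * 0.8 + 0.5 * 0.5) +
                 0.4 * (0.5 * 0.2 + 0.5 * 0.5))

  # single partner, pure own production: collapses to the partner's FMI
  one <- compute_fmi_imports(
    shares[1, ] |> dplyr::mutate(share = 1),
    comps |> dplyr::mutate(p_pe = c(1, 1), p_ie = 0), fmi, glbl
  )
  expect_equal(one$fmi_i, 0.8)
  # full re-export regularization: collapses to the global FMI
  re <- compute_fmi_imports(
    shares[1, ] |> dplyr::mutate(share = 1),
    comps |> dplyr::mutate(p_pe = 0, p_ie = 1), fmi, glbl
  )
  expect_equal(re$fmi_i, 0.5)
  # a partner with positive share but no usable composition is an error
  expect_error(
    compute_fmi_imports(shares, comps |> dplyr::mutate(p_pe = NA_real_),
                        fmi, glbl),
    class = "seatrace_validation_error"
  )
})

test_that("consumption FMI blends production and import scores", {
  bal <- tibble::tibble(
    country_id = c("A", "B"), product_group = "Pelagic Fish", year = 2015L,
    production_t = c(50, 100), imports_t = c(10, 0), exports_t = 0,
    food_supply_t = c(60, 100)
  )
  fmi <- tibble::tibble(country_id = c("A", "B"), fmi = c(0.9, 0.7))
  fmi_i <- tibble::tibble(reporter_id = "A", product_group = "Pelagic Fish",
                          fmi_i = 0.5)
  # proportional: a 50:10 split gives ppc = 5/6
  prop <- compute_fmi_consumption(bal, fmi, fmi_i, "proportional")
  a <- prop[prop$country_id == "A", ]
  expect_equal(a$ppc_used, 5 / 6)
  expect_equal(a$fmi_c, 5 / 6 * 0.9 + 1 / 6 * 0.5)
  # autarky: no imports means fmi_c equals fmi_p under every derivation
  for (d in c("proportional", "gephart", "guillen")) {
    b <- compute_fmi_consumption(bal, fmi, fmi_i, d)
    expect_equal(b$fmi_c[b$country_id == "B"], 0.7, info = d)
  }
  # fixed-share derivation: 0.74 x 0.9 + 0.26 x 0.5
  gu <- compute_fmi_consumption(bal, fmi, fmi_i, "guillen")
  expect_equal(gu$fmi_c[gu$country_id == "A"], 0.74 * 0.9 + 0.26 * 0.5)
  expect_equal(gu$ppc_used[gu$country_id == "A"], 0.74)
  # zero-import override is logged
  expect_true(gu$ppc_overridden[gu$country_id == "B"])
  # P + I = 0 cells are omitted
  bal0 <- dplyr::add_row(
    bal, country_id = "Z", product_group = "Pelagic Fish", year = 2015L,
    production_t = 0, imports_t = 0, exports_t = 0, food_supply_t = 0
  )
  fmi0 <- dplyr::add_row(fmi, country_id = "Z", fmi = 0.5)
  out0 <- compute_fmi_consumption(bal0, fmi0, fmi_i, "proportional")
  expect_false("Z" %in% out0$country_id)
})

test_that("aggregation weights by consumption share", {
  res <- tibble::tibble(
    country_id = "A",
    product_group = c("Pelagic Fish", "Demersal Fish"),
    derivation = "proportional",
    ppc_used = 1, ppc_overridden = FALSE, fmi_p = 0.5,
    fmi_i = NA_real_, fmi_c = c(0.6, 0.8), consumption_t = c(100, 100)
  )
  agg <- aggregate_fmi_c(res)
  expect_equal(agg$fmi_c, 0.7)
  # single group: aggregate equals that group
  agg1 <- aggregate_fmi_c(res[1, ])
  expect_equal(agg1$fmi_c, 0.6)
})

test_that("run_derivations averages the three derivations per country", {
  sw <- star_world()
  out <- run_derivations(sw$balance, sw$trade, sw$fmi)
  three <- out$aggregates |>
    dplyr::filter(country_id == "X01") |>
    dplyr::arrange(derivation)
  s <- out$summary[out$summary$country_id == "X01", ]
  expect_equal(s$mean_fmi_c, mean(three$fmi_c))
  expect_equal(s$min_fmi_c, min(three$fmi_c))
  expect_equal(s$max_fmi_c, max(three$fmi_c))
  expect_error(run_derivations(sw$balance, sw$trade, sw$fmi,
                               derivations = "mrio"),
               class = "seatrace_config_error")
})

test_that("a closed no-trade world returns FMI_P under every derivation", {
  w <- generate_world(world_config(
    n_countries = 4, n_groups = 2, trade_density = 0, n_hubs = 0,
    reexport_fraction = 0, missing_fmi_fraction = 0,
    nonfood_fraction = 0, seed = 9
  ))
  inputs <- prepare_world_inputs(w)
  out <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
  cmp <- dplyr::left_join(out$aggregates, inputs$fmi, by = "country_id")
  expect_equal(cmp$fmi_c, cmp$fmi)
  expect_true(all(out$results$ppc_used == 1))
})

test_that("pipeline matches the brute-force expansion on small worlds", {
  for (s in 1:10) {
    w <- generate_world(small_world(seed = s))
    expect_lt(oracle_max_diff(w), 1e-12)
  }
})

test_that("every weight vector is a proper convex combination", {
  for (s in 1:3) {
    w <- generate_world(world_config(
      n_countries = 10, n_groups = 3, n_hubs = 2, seed = s
    ))
    inputs <- prepare_world_inputs(w)
    out <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
    shares <- out$weights$import_shares |>
      dplyr::group_by(reporter_id, product_group) |>
      dplyr::summarise(s = sum(share), .groups = "drop")
    expect_true(all(abs(shares$s - 1) < 1e-9))
    comp <- out$weights$composition |> dplyr::filter(!is.na(p_pe))
    expect_true(all(abs(comp$p_pe + comp$p_ie - 1) < 1e-9))
    expect_true(all(comp$p_pe >= 0 & comp$p_pe <= 1))
    gw <- out$weights$global_weights |>
      dplyr::group_by(product_group) |>
      dplyr::summarise(s = sum(p_pglbl), .groups = "drop")
    expect_true(all(abs(gw$s - 1) < 1e-9))
    expect_true(all(out$results$ppc_used >= 0 & out$results$ppc_used <= 1))
    # convexity: every score stays inside the FMI range it blends
    expect_true(all(out$results$fmi_c >= 0 & out$results$fmi_c <= 1))
    rng <- range(inputs$fmi$fmi)
    expect_true(all(out$aggregates$fmi_c >= rng[1] &
                      out$aggregates$fmi_c <= rng[2]))
    expect_true(all(out$global_fmi$fmi_glbl >= rng[1] &
                      out$global_fmi$fmi_glbl <= rng[2]))
  }
})

test_that("raising a partner's FMI weakly raises downstream scores", {
  w <- generate_world(world_config(
    n_countries = 10, n_groups = 2, n_hubs = 2, missing_fmi_fraction = 0,
    seed = 11
  ))
  inputs <- prepare_world_inputs(w)
  base <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
  target <- inputs$fmi$country_id[which.min(inputs$fmi$fmi)]
  bumped_fmi <- inputs$fmi |>
    dplyr::mutate(fmi = ifelse(country_id == target,
                               pmin(1, fmi + 0.1), fmi))
  bumped <- run_derivations(inputs$balance, inputs$trade, bumped_fmi)
  cmp <- dplyr::inner_join(
    base$aggregates, bumped$aggregates,
    by = c("country_id", "derivation"), suffix = c("_0", "_1")
  )
  expect_true(all(cmp$fmi_c_1 >= cmp$fmi_c_0 - 1e-12))
})
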