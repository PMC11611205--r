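make_training <- function(n = 40, noise_sd = 0, seed = 1,
                          spi_coef = 0.004,
                          offsets = c(Africa = 0.1, Asia = 0.2,
                                      Europe = 0.35)) {
  set.seed(seed)
  ids <- sprintf("K%02d", seq_len(n))
  spi <- runif(n, 30, 95)
  region <- sample(names(offsets), n, replace = TRUE)
  fmi <- spi_coef * spi + unname(offsets[region]) + rnorm(n, 0, noise_sd)
  list(
    known = tibble::tibble(country_id = ids, fmi = fmi),
    covariates = tibble::tibble(country_id = ids, spi = spi,
                                geo_region = region),
    spi_coef = spi_coef, offsets = offsets
  )
}

test_that("a noiseless linear truth is recovered exactly", {
  tr <- make_training(n = 30, noise_sd = 0)
  m <- fit_gapfill_model(tr$known, tr$covariates)
  expect_equal(unname(m$coefficients["spi"]), tr$spi_coef, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # treatment coding: intercept is the baseline region's offset
  expect_equal(unname(m$coefficients["(Intercept)"]),
               unname(tr$offsets[sort(names(tr$offsets))[1]]),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected as rank deficient", {
  known <- tibble::tibble(country_id = c("A", "B"), fmi = c(0.4, 0.5))
  cov_const <- tibble::tibble(country_id = c("A", "B"), spi = 50,
                              geo_region = "Asia")
  expect_error(fit_gapfill_model(known, cov_const),
               class = "seatrace_validation_error")
})

test_that("the generating SPI coefficient is recovered within 3 SE", {
  tr <- make_training(n = 40, noise_sd = 0.05, seed = 7)
  m <- fit_gapfill_model(tr$known, tr$covariates)
  se <- summary(m$fit)$coefficients["spi", "Std. Error"]
  expect_lt(abs(m$coefficients[["spi"]] - tr$spi_coef), 3 * se)
})

test_that("gapfill predictions match a hand-computed model matrix product", {
  tr <- make_training(n = 25, noise_sd = 0.03, seed = 2)
  m <- fit_gapfill_model(tr$known, tr$covariates)
  missing <- tibble::tibble(
    country_id = c("M1", "M2", "M3"),
    spi = c(40, 60, 80),
    geo_region = c("Africa", "Asia", "Europe")
  )
  out <- gapfill(m, missing)
  co <- m$coefficients
  regions <- sort(names(tr$offsets))
  hand <- vapply(seq_len(3), function(i) {
    x <- co[["(Intercept)"]] + co[["spi"]] * missing$spi[i]
    rg <- missing$geo_region[i]
    term <- paste0("geo_region", rg)
    if (term %in% names(co)) x <- x + co[[term]]
    x
  }, numeric(1))
  expect_equal(out$fmi, pmin(1, pmax(0, hand)), tolerance = 1e-12)
  expect_true(all(out$provenance == "gapfilled"))
})

test_that("out-of-range predictions are clamped and flagged", {
  known <- tibble::tibble(country_id = sprintf("K%d", 1:6),
                          fmi = c(0.2, 0.4, 0.6, 0.8, 0.9, 1.0))
  covs <- tibble::tibble(country_id = sprintf("K%d", 1:6),
                         spi = c(20, 40, 60, 80, 90, 100),
                         geo_region = "Asia")
  m <- fit_gapfill_model(known, covs)
  out <- gapfill(m, tibble::tibble(country_id = "HOT", spi = 200,
                                   geo_region = "Asia"))
  expect_equal(out$fmi, 1)
  expect_true(out$clamped)
})

test_that("gapfill refuses silent imputation", {
  tr <- make_training(n = 20)
  m <- fit_gapfill_model(tr$known, tr$covariates)
  expect_error(
    gapfill(m, tibble::tibble(country_id = "X", spi = NA_real_,
                              geo_region = "Asia")),
    class = "seatrace_validation_error"
  )
  expect_error(
    gapfill(m, tibble::tibble(country_id = "X", spi = 50,
                              geo_region = "Oceania")),
    "Oceania", class = "seatrace_validation_error"
  )
})

test_that("group FMI is the unweighted member mean", {
  harm <- dplyr::bind_rows(
    identity_harmonization(c("A", "B", "C")),
    tibble::tibble(raw_name = c("EU", "SOLO"), canonical_id = c("EU", "SOLO"),
                   kind = "group", members = c("A;B", "C"))
  )
  est <- tibble::tibble(country_id = c("A", "B", "C"), fmi = c(0.4, 0.8, 0.37))
  expect_equal(group_fmi(harm, "EU", est)$fmi, 0.6)
  expect_equal(group_fmi(harm, "SOLO", est)$fmi, 0.37)
  # brute-force mean over a 5-member group
  harm5 <- dplyr::bind_rows(
    identity_harmonization(sprintf("M%d", 1:5)),
    tibble::tibble(raw_name = "G5", canonical_id = "G5", kind = "group",
                   members = paste(sprintf("M%d", 1:5), collapse = ";"))
  )
  est5 <- tibble::tibble(country_id = sprintf("M%d", 1:5),
                         fmi = c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(group_fmi(harm5, "G5", est5)$fmi, sum(est5$fmi) / 5)
  expect_error(group_fmi(harm5, "G5", est5[-3, ]),
               class = "seatrace_validation_error")
})

test_that("assembled FMI tables are total, unique and within bounds", {
  w <- generate_world(world_config(
    n_countries = 12, n_groups = 2, n_hubs = 2,
    missing_fmi_fraction = 0.4, seed = 3
  ))
  ids <- c(unique(w$balance$country_id), "GRP1")
  est <- assemble_fmi(w$fmi, w$covariates, w$harmonization,
                      required_ids = ids)
  expect_setequal(est$country_id, ids)
  expect_false(any(duplicated(est$country_id)))
  expect_true(all(est$fmi >= 0 & est$fmi <= 1))
  expect_setequal(
    unique(est$provenance),
    intersect(c("surveyed", "modeled", "gapfilled", "group_mean"),
              est$provenance)
  )
  # provenance partition: released countries keep their provenance
  released <- est[est$country_id %in% w$fmi$country_id, ]
  expect_true(all(released$provenance %in% c("surveyed", "modeled")))
  filled <- est[!est$country_id %in% c(w$fmi$country_id, "GRP1"), ]
  expect_true(all(filled$provenance == "gapfilled"))
  expect_equal(est$provenance[est$country_id == "GRP1"], "group_mean")
  # deterministic: no randomness anywhere in the fill
  expect_identical(
    est, assemble_fmi(w$fmi, w$covariates, w$harmonization, required_ids = ids)
  )
})
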