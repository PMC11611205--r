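# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from disk except files the tests write themselves.

groups8 <- seatrace::isscaap_groups()

# Minimal valid balance table: one country-group-year per row.
tiny_balance <- function() {
  tibble::tibble(
    country_id = c("A", "A", "B"),
    product_group = c("Pelagic Fish", "Demersal Fish", "Pelagic Fish"),
    year = 2015L,
    production_t = c(50, 20, 100),
    imports_t = c(10, 0, 5),
    exports_t = c(20, 5, 30),
    food_supply_t = c(40, 15, 75)
  )
}

tiny_trade <- function() {
  tibble::tibble(
    reporter_id = c("A", "B"),
    partner_id = c("B", "A"),
    direction = c("import", "export"),
    product_code = "S01A",
    product_desc = "pelagic fish, whole, fresh or chilled",
    year = 2015L,
    product_weight_t = c(10, 10),
    is_food = TRUE,
    farmed_flag = "unknown"
  )
}

identity_harmonization <- function(ids) {
  tibble::tibble(
    raw_name = ids, canonical_id = ids, kind = "country", members = ""
  )
}

# A hub-and-spoke world in which every importer buys only from one pure
# producer, so FMI_I is the same constant for all importers: the setting
# in which the fixed-share derivations have a closed-form regression.
star_world <- function(n_importers = 20, hub_fmi = 0.5) {
  ids <- sprintf("X%02d", seq_len(n_importers))
  g <- "Pelagic Fish"
  balance <- tibble::tibble(
    country_id = c("HUB", ids),
    product_group = g,
    year = 2015L,
    production_t = c(1e6, seq(1e3, 5e4, length.out = n_importers)),
    imports_t = c(0, rep(1e4, n_importers)),
    exports_t = c(n_importers * 1e4, rep(0, n_importers)),
    food_supply_t = 0
  )
  balance$food_supply_t <- with(balance, production_t + imports_t - exports_t)
  trade <- tibble::tibble(
    reporter_id = ids,
    partner_id = "HUB",
    direction = "import",
    product_code = "S01A",
    product_desc = "pelagic fish, whole, fresh or chilled",
    year = 2015L,
    product_weight_t = 1e4,
    is_food = TRUE,
    farmed_flag = "unknown",
    live_weight_t = 1e4,
    product_group = g
  )
  fmi <- tibble::tibble(
    country_id = c("HUB", ids),
    fmi = c(hub_fmi, seq(0.1, 0.95, length.out = n_importers))
  )
  list(balance = balance, trade = trade, fmi = fmi)
}

# Small-world configuration used by the propagation/oracle suites.
small_world <- function(seed, n_countries = 6, n_groups = 3, ...) {
  seatrace::world_config(
    n_countries = n_countries, n_groups = n_groups, n_hubs = 1,
    years = 2012:2014, trade_density = 0.5,
    missing_fmi_fraction = 0, aquaculture_fraction = 0,
    nonfood_fraction = 0, seed = seed, ...
  )
}
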