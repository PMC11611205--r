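#' Configuration for a synthetic seafood trade world
#'
#' Bundles every parameter of the synthetic-world generator into a validated
#' list. The generated world is a closed economy: every tonne consumed
#' anywhere was produced somewhere, so mass-balance invariants are exact and
#' a complete provenance ledger of consumption origins can be kept.
#'
#' Countries play one of three roles. *Exporters* produce seafood and sell a
#' fraction of their production abroad but do not import. *Importers*
#' produce for themselves and buy from exporters and hubs but do not export.
#' *Processing hubs* import from exporters and re-export a fixed fraction of
#' their inflow under their own flag — the trade records attribute those
#' tonnes to the hub, while the ledger keeps the true origins. This
#' two-tier chain (producer, then at most one hub, then consumer) is the
#' simplest structure that reproduces the provenance ambiguity created by
#' real-world seafood processing.
#'
#' @param n_countries Number of countries (at least 2).
#' @param n_groups Number of ISSCAAP product groups to simulate (1--8),
#'   taken in order from [isscaap_groups()].
#' @param years Integer vector of calendar years to simulate.
#' @param trade_density Probability that an eligible (seller, buyer) pair
#'   trades within a product group and year.
#' @param reexport_fraction Fraction of each hub's inflow that is processed
#'   and re-exported under the hub's own flag, in \[0, 1\].
#' @param n_hubs Number of processing-hub countries. Must be positive when
#'   `reexport_fraction > 0`.
#' @param export_frac_range Range (length 2) from which each exporter's
#'   exported fraction of production is drawn uniformly, per group and year.
#' @param production_meanlog,production_sdlog Log-normal parameters of the
#'   per country x group x year production draw (tonnes live weight). The
#'   defaults give a heavy-tailed volume distribution with a median around
#'   20 thousand tonnes.
#' @param spi_range Range of the uniform Social Progress Index draw
#'   (0--100 scale).
#' @param spi_coef Coefficient linking SPI to FMI in the generating rule.
#' @param region_offsets Named numeric vector of additive region effects on
#'   FMI; names define the region label set.
#' @param fmi_noise_sd Standard deviation of the Gaussian noise added to
#'   the generating FMI rule.
#' @param missing_fmi_fraction Fraction of countries whose FMI is withheld
#'   from the released table (to be gap-filled); covariates remain complete.
#' @param disagreement_meanlog,disagreement_sdlog Log-normal parameters of
#'   the per-country multiplicative factor by which the trade-record source
#'   inflates quantities relative to the balance-sheet source. Only the
#'   trade table is scaled, so relative partner shares are unaffected.
#' @param aquaculture_fraction Probability that a trade flow is labelled as
#'   a farmed product in its description.
#' @param nonfood_fraction Number of extra non-food trade records (e.g.
#'   ornamental fish), as a fraction of the number of food flows. Non-food
#'   records take no part in the mass balance.
#' @param include_group_alias If `TRUE` and the world has at least four
#'   countries, the harmonization table carries one aggregate reporter
#'   alias (`"GRP1"`) whose members are the first three countries.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#'
#' @return A list of class `seatrace_config`.
#' @export
#' @examples
#' cfg <- world_config(n_countries = 6, n_groups = 2, seed = 1)
world_config <- function(n_countries = 30,
                         n_groups = 8,
                         years = 2012:2017,
                         trade_density = 0.3,
                         reexport_fraction = 0.75,
                         n_hubs = 3,
                         export_frac_range = c(0.2, 0.6),
                         production_meanlog = log(2e4),
                         production_sdlog = 1.3,
                         spi_range = c(30, 95),
                         spi_coef = 0.004,
                         region_offsets = c(
                           Africa = 0.05, Americas = 0.25, Asia = 0.15,
                           Europe = 0.35, Oceania = 0.30
                         ),
                         fmi_noise_sd = 0.05,
                         missing_fmi_fraction = 0.25,
                         disagreement_meanlog = log(1.6),
                         disagreement_sdlog = 0.25,
                         aquaculture_fraction = 0.10,
                         nonfood_fraction = 0.05,
                         include_group_alias = TRUE,
                         seed) {
  if (missing(seed) || is.null(seed)) {
    stop_config("world_config(): `seed` is mandatory")
  }
  if (n_countries < 2) stop_config("world_config(): need at least 2 countries")
  if (n_groups < 1 || n_groups > 8) {
    stop_config("world_config(): `n_groups` must be between 1 and 8")
  }
  fracs <- c(
    trade_density = trade_density, reexport_fraction = reexport_fraction,
    missing_fmi_fraction = missing_fmi_fraction,
    aquaculture_fraction = aquaculture_fraction
  )
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad) > 0) {
    stop_config(sprintf(
      "world_config(): %s must lie in [0, 1]", paste(bad, collapse = ", ")
    ))
  }
  if (reexport_fraction > 0 && n_hubs == 0) {
    stop_config(
      "world_config(): `reexport_fraction` > 0 requires at least one hub"
    )
  }
  if (n_countries - n_hubs < 2) {
    stop_config("world_config(): need at least 2 non-hub countries")
  }
  cfg <- list(
    n_countries = as.integer(n_countries), n_groups = as.integer(n_groups),
    years = as.integer(years), trade_density = trade_density,
    reexport_fraction = reexport_fraction, n_hubs = as.integer(n_hubs),
    export_frac_range = export_frac_range,
    production_meanlog = production_meanlog,
    production_sdlog = production_sdlog,
    spi_range = spi_range, spi_coef = spi_coef,
    region_offsets = region_offsets, fmi_noise_sd = fmi_noise_sd,
    missing_fmi_fraction = missing_fmi_fraction,
    disagreement_meanlog = disagreement_meanlog,
    disagreement_sdlog = disagreement_sdlog,
    aquaculture_fraction = aquaculture_fraction,
    nonfood_fraction = nonfood_fraction,
    include_group_alias = isTRUE(include_group_alias),
    seed = as.integer(seed)
  )
  structure(cfg, class = "seatrace_config")
}

#' Synthetic conversion-factor table for generated product codes
#'
#' Each simulated product group carries two product codes: an `A` form
#' (whole, fresh; conversion factor 1) and a `B` form (fillets, frozen;
#' conversion factor 2, i.e. one tonne of product came from two tonnes live
#' weight), plus the mandatory default entry with factor 1.
#'
#' @param n_groups Number of product groups (1--8).
#' @return A tibble with columns `match_key`, `cf`, `source`, `note`.
#' @export
synthetic_conversion_table <- function(n_groups = 8) {
  gi <- seq_len(n_groups)
  tibble::tibble(
    match_key = c(sprintf("S%02dA", gi), sprintf("S%02dB", gi), ""),
    cf = c(rep(1, n_groups), rep(2, n_groups), 1),
    source = c(rep("fao", 2 * n_groups), "default"),
    note = c(
      rep("whole, fresh or chilled", n_groups),
      rep("fillets, frozen", n_groups),
      "default for unmatched products"
    )
  )
}

#' Synthetic product-code to ISSCAAP-group mapping
#'
#' @param n_groups Number of product groups (1--8).
#' @return A tibble with columns `product_code`, `product_group`; the
#'   non-food code `NF01` maps to `"Aquatic Animals NEI"`.
#' @export
synthetic_group_mapping <- function(n_groups = 8) {
  groups <- isscaap_groups()[seq_len(n_groups)]
  gi <- seq_len(n_groups)
  tibble::tibble(
    product_code = c(sprintf("S%02dA", gi), sprintf("S%02dB", gi), "NF01"),
    product_group = c(groups, groups, "Aquatic Animals NEI")
  )
}

#' Generate a provenance-tracked synthetic seafood trade world
#'
#' Draws country attributes (SPI, region, FMI), role assignments
#' (exporter / importer / processing hub), heavy-tailed production volumes
#' and bilateral trade flows under the configuration in `config`, and
#' returns every table the analysis pipeline ingests together with a
#' provenance ledger recording the true origin of every consumed tonne.
#'
#' The world is closed: for every country, product group and year,
#' `consumption + exports = production + imports` holds exactly, and the
#' ledger's origin tonnes marginalize back to the balance table's
#' consumption column. The trade table reports product weights (live
#' weight divided by the product's conversion factor) inflated by a
#' per-importer disagreement factor, mimicking the systematic magnitude
#' disagreement between trade-record and balance-sheet sources; because
#' the factor is constant within an importer, relative partner shares are
#' preserved.
#'
#' @param config A [world_config()] object.
#' @return A list of class `seatrace_world` with elements `config`,
#'   `balance`, `trade`, `fmi`, `covariates`, `harmonization`,
#'   `conversion`, `group_mapping`, `ledger` and `truth` (a list holding
#'   the complete FMI table, role assignments, disagreement factors and
#'   raw flow-level records with true live weights).
#' @export
#' @examples
#' w <- generate_world(world_config(n_countries = 6, n_groups = 2, seed = 1))
#' head(w$balance)
generate_world <- function(config) {
  if (!inherits(config, "seatrace_config")) {
    stop_config("generate_world() expects a `world_config()` object")
  }
  set.seed(config$seed)
  n <- config$n_countries
  id_fmt <- if (n > 99) "C%03d" else "C%02d"
  countries <- sprintf(id_fmt, seq_len(n))
  groups <- isscaap_groups()[seq_len(config$n_groups)]
  years <- config$years

  # --- country attributes -------------------------------------------------
  spi <- runif(n, config$spi_range[1], config$spi_range[2])
  region <- sample(names(config$region_offsets), n, replace = TRUE)
  fmi_true <- clamp01(
    config$spi_coef * spi + unname(config$region_offsets[region]) +
      rnorm(n, 0, config$fmi_noise_sd)
  )
  disagreement <- rlnorm(n, config$disagreement_meanlog,
                         config$disagreement_sdlog)

  # --- roles --------------------------------------------------------------
  hubs <- if (config$n_hubs > 0) sample(countries, config$n_hubs) else character()
  others <- setdiff(countries, hubs)
  is_exporter <- runif(length(others)) < 0.5
  if (!any(is_exporter)) is_exporter[1] <- TRUE
  if (all(is_exporter)) is_exporter[length(is_exporter)] <- FALSE
  exporters <- others[is_exporter]
  importers <- others[!is_exporter]
  role <- setNames(rep("importer", n), countries)
  role[exporters] <- "exporter"
  role[hubs] <- "hub"

  # --- per group x year production and flows ------------------------------
  codes_a <- setNames(sprintf("S%02dA", seq_along(groups)), groups)
  codes_b <- setNames(sprintf("S%02dB", seq_along(groups)), groups)
  balance_rows <- vector("list", length(groups) * length(years))
  flow_rows <- list()
  ledger_rows <- list()
  cell <- 0L
  for (g in groups) {
    for (y in years) {
      cell <- cell + 1L
      P <- setNames(
        rlnorm(n, config$production_meanlog, config$production_sdlog),
        countries
      )
      # stage 1: exporters sell own production to hubs and importers
      flows <- list() # each: from, to, tonnes (live weight)
      for (i in exporters) {
        targets <- c(hubs, importers)
        sel <- targets[runif(length(targets)) < config$trade_density]
        if (length(sel) == 0) next
        ef <- runif(1, config$export_frac_range[1], config$export_frac_range[2])
        w <- runif(length(sel))
        flows[[length(flows) + 1L]] <- data.frame(
          from = i, to = sel, tonnes = ef * P[i] * w / sum(w),
          stringsAsFactors = FALSE
        )
      }
      stage1 <- if (length(flows)) do.call(rbind, flows) else
        data.frame(from = character(), to = character(), tonnes = numeric())
      # stage 2: hubs re-export a fraction of inflow, origins preserved in
      # the ledger but the flow is flagged from the hub
      stage2 <- list()
      hub_mix <- list() # origin composition of each hub's inflow
      for (h in hubs) {
        inflow <- stage1[stage1$to == h, , drop = FALSE]
        tot_in <- sum(inflow$tonnes)
        mix <- if (tot_in > 0) {
          tapply(inflow$tonnes, inflow$from, sum) / tot_in
        } else {
          numeric()
        }
        hub_mix[[h]] <- mix
        re <- config$reexport_fraction * tot_in
        if (re <= 0 || length(importers) == 0) next
        sel <- importers[runif(length(importers)) < config$trade_density]
        if (length(sel) == 0) sel <- sample(importers, 1)
        w <- runif(length(sel))
        stage2[[length(stage2) + 1L]] <- data.frame(
          from = h, to = sel, tonnes = re * w / sum(w),
          stringsAsFactors = FALSE
        )
      }
      stage2 <- if (length(stage2)) do.call(rbind, stage2) else
        data.frame(from = character(), to = character(), tonnes = numeric())
      all_flows <- rbind(stage1, stage2)

      # balance quantities
      I <- setNames(rep(0, n), countries)
      E <- setNames(rep(0, n), countries)
      if (nrow(all_flows) > 0) {
        ti <- tapply(all_flows$tonnes, all_flows$to, sum)
        I[names(ti)] <- ti
        te <- tapply(all_flows$tonnes, all_flows$from, sum)
        E[names(te)] <- te
      }
      C <- P + I - E
      balance_rows[[cell]] <- data.frame(
        country_id = countries, product_group = g, year = y,
        production_t = unname(P), imports_t = unname(I),
        exports_t = unname(E), food_supply_t = unname(C),
        stringsAsFactors = FALSE
      )

      # provenance ledger: true origins of every consumed tonne
      led <- list()
      for (cc in countries) {
        dom <- P[[cc]] - if (role[[cc]] == "exporter") E[[cc]] else 0
        org <- setNames(dom, cc)
        inflow <- all_flows[all_flows$to == cc, , drop = FALSE]
        keep <- if (role[[cc]] == "hub") 1 - config$reexport_fraction else 1
        if (nrow(inflow) > 0 && keep > 0) {
          for (k in seq_len(nrow(inflow))) {
            src <- inflow$from[k]
            t_in <- inflow$tonnes[k] * keep
            if (role[[src]] == "hub") {
              mix <- hub_mix[[src]]
              add <- t_in * mix
            } else {
              add <- setNames(t_in, src)
            }
            for (o in names(add)) {
              cur <- if (o %in% names(org)) org[[o]] else 0
              org[o] <- cur + add[[o]]
            }
          }
        }
        org <- org[!is.na(org) & org > 0]
        if (length(org) > 0) {
          led[[length(led) + 1L]] <- data.frame(
            consumer_id = cc, product_group = g, year = y,
            origin_id = names(org), tonnes = unname(org),
            stringsAsFactors = FALSE
          )
        }
      }
      ledger_rows[[cell]] <- do.call(rbind, led)
      if (nrow(all_flows) > 0) {
        all_flows$product_group <- g
        all_flows$year <- y
        flow_rows[[cell]] <- all_flows
      }
    }
  }
  balance <- tibble::as_tibble(do.call(rbind, balance_rows))
  ledger <- tibble::as_tibble(do.call(rbind, ledger_rows))
  flows <- if (length(flow_rows)) {
    tibble::as_tibble(do.call(rbind, flow_rows))
  } else {
    tibble::tibble(
      from = character(), to = character(), tonnes = numeric(),
      product_group = character(), year = integer()
    )
  }

  # --- trade records (product weight, both directions) --------------------
  group_names_lc <- tolower(groups)
  names(group_names_lc) <- groups
  if (nrow(flows) > 0) {
    use_b <- runif(nrow(flows)) < 0.5
    code <- ifelse(use_b, codes_b[flows$product_group],
                   codes_a[flows$product_group])
    cf <- ifelse(use_b, 2, 1)
    form <- ifelse(use_b, "fillets, frozen", "whole, fresh or chilled")
    farmed <- runif(nrow(flows)) < config$aquaculture_fraction
    desc <- paste0(
      ifelse(farmed, "farmed ", ""),
      group_names_lc[flows$product_group], ", ", form
    )
    factor_to <- disagreement[match(flows$to, countries)]
    pw <- flows$tonnes * factor_to / cf
    food <- tibble::tibble(
      reporter_id = c(flows$from, flows$to),
      partner_id = c(flows$to, flows$from),
      direction = rep(c("export", "import"), each = nrow(flows)),
      product_code = rep(code, 2),
      product_desc = rep(desc, 2),
      year = rep(flows$year, 2),
      product_weight_t = rep(pw, 2),
      is_food = TRUE,
      farmed_flag = rep(ifelse(farmed, "farmed", "unknown"), 2)
    )
    flows$product_code <- code
    flows$farmed <- farmed
  } else {
    food <- tibble::tibble(
      reporter_id = character(), partner_id = character(),
      direction = character(), product_code = character(),
      product_desc = character(), year = integer(),
      product_weight_t = numeric(), is_food = logical(),
      farmed_flag = character()
    )
  }
  n_nonfood <- round(config$nonfood_fraction * nrow(flows))
  if (n_nonfood > 0) {
    nf_from <- sample(countries, n_nonfood, replace = TRUE)
    nf_to <- vapply(nf_from, function(f) sample(setdiff(countries, f), 1), "")
    nf_w <- rlnorm(n_nonfood, config$production_meanlog - 3,
                   config$production_sdlog)
    nonfood <- tibble::tibble(
      reporter_id = c(nf_from, nf_to),
      partner_id = c(nf_to, nf_from),
      direction = rep(c("export", "import"), each = n_nonfood),
      product_code = "NF01",
      product_desc = "ornamental aquarium fish, live",
      year = rep(sample(years, n_nonfood, replace = TRUE), 2),
      product_weight_t = rep(nf_w, 2),
      is_food = FALSE,
      farmed_flag = "unknown"
    )
    trade <- dplyr::bind_rows(food, nonfood)
  } else {
    trade <- food
  }

  # --- FMI release (masked) and covariates --------------------------------
  n_missing <- round(config$missing_fmi_fraction * n)
  masked <- if (n_missing > 0) sample(countries, n_missing) else character()
  # keep at least one surveyed observation per region so the gap-fill
  # model stays full rank
  for (rg in unique(region)) {
    members <- countries[region == rg]
    if (all(members %in% masked)) masked <- setdiff(masked, members[1])
  }
  known <- setdiff(countries, masked)
  prov <- ifelse(runif(length(known)) < 0.6, "surveyed", "modeled")
  fmi <- tibble::tibble(
    country_id = known,
    fmi = fmi_true[match(known, countries)],
    provenance = prov,
    se = NA_real_
  )
  covariates <- tibble::tibble(
    country_id = countries, spi = spi, geo_region = region
  )

  # --- harmonization ------------------------------------------------------
  harmonization <- tibble::tibble(
    raw_name = countries, canonical_id = countries,
    kind = "country", members = ""
  )
  if (config$include_group_alias && n >= 4) {
    harmonization <- dplyr::bind_rows(
      harmonization,
      tibble::tibble(
        raw_name = "GRP1", canonical_id = "GRP1", kind = "group",
        members = paste(countries[1:3], collapse = ";")
      )
    )
  }

  structure(
    list(
      config = config,
      balance = balance,
      trade = trade,
      fmi = fmi,
      covariates = covariates,
      harmonization = harmonization,
      conversion = synthetic_conversion_table(config$n_groups),
      group_mapping = synthetic_group_mapping(config$n_groups),
      ledger = ledger,
      truth = list(
        fmi = tibble::tibble(country_id = countries, fmi = fmi_true),
        roles = tibble::tibble(country_id = countries, role = unname(role)),
        disagreement = tibble::tibble(
          country_id = countries, factor = disagreement
        ),
        flows = flows
      )
    ),
    class = "seatrace_world"
  )
}

#' @export
print.seatrace_world <- function(x, ...) {
  cat(sprintf(
    "<seatrace_world> %d countries x %d groups x %d years (seed %d)\n",
    x$config$n_countries, x$config$n_groups, length(x$config$years),
    x$config$seed
  ))
  cat(sprintf(
    "  %d trade records, %d ledger entries, %d/%d countries with released FMI\n",
    nrow(x$trade), nrow(x$ledger), nrow(x$fmi), x$config$n_countries
  ))
  invisible(x)
}

#' Ground-truth consumption-weighted FMI from a provenance ledger
#'
#' Computes, for every consumer, the exact consumption-weighted mean of the
#' production FMI of the true origin countries of its consumption — the
#' quantity the trade-propagation estimator approximates. Returned per
#' product group and aggregated over groups.
#'
#' @param ledger Ledger tibble with columns `consumer_id`, `product_group`,
#'   `year`, `origin_id`, `tonnes` (as in a `seatrace_world`).
#' @param fmi Tibble with columns `country_id`, `fmi` covering every origin.
#' @return Tibble with columns `country_id`, `product_group` (the groups
#'   plus `"AGGREGATE"`), `consumption_t` and `fmi_true_c`.
#' @export
true_consumption_fmi <- function(ledger, fmi) {
  miss <- setdiff(unique(ledger$origin_id), fmi$country_id)
  if (length(miss) > 0) {
    stop_validation(sprintf(
      "true_consumption_fmi(): origins without FMI: %s",
      paste(miss, collapse = ", ")
    ))
  }
  scored <- ledger |>
    dplyr::left_join(fmi, by = c(origin_id = "country_id"))
  per_group <- scored |>
    dplyr::group_by(country_id = .data$consumer_id, .data$product_group) |>
    dplyr::summarise(
      consumption_t = sum(.data$tonnes),
      fmi_true_c = sum(.data$tonnes * .data$fmi) / sum(.data$tonnes),
      .groups = "drop"
    )
  aggregate <- scored |>
    dplyr::group_by(country_id = .data$consumer_id) |>
    dplyr::summarise(
      product_group = AGGREGATE_GROUP,
      consumption_t = sum(.data$tonnes),
      fmi_true_c = sum(.data$tonnes * .data$fmi) / sum(.data$tonnes),
      .groups = "drop"
    )
  dplyr::bind_rows(per_group, aggregate) |>
    dplyr::arrange(.data$country_id, .data$product_group)
}

#' Estimator bias as a function of re-export intensity
#'
#' Runs the full propagation pipeline on synthetic worlds generated over a
#' grid of re-export fractions and seeds, and measures the mean absolute
#' error of the aggregate consumption FMI against the provenance-ledger
#' ground truth, per derivation. Worlds are generated with complete FMI
#' tables and no aquaculture or non-food records so that the measured error
#' isolates the re-export approximation.
#'
#' @param config A [world_config()] used as the template (its
#'   `reexport_fraction` and `seed` are overridden cell by cell).
#' @param reexport_fractions Numeric vector of re-export fractions to test.
#' @param seeds Integer vector of world seeds averaged over per cell.
#' @param derivations Character vector of derivation names.
#' @return Tibble with columns `reexport_fraction`, `derivation`,
#'   `mean_abs_error`.
#' @export
estimator_bias_study <- function(config,
                                 reexport_fractions = c(0, 0.3, 0.6),
                                 seeds = 1:5,
                                 derivations = c("proportional", "gephart",
                                                 "guillen")) {
  cells <- tidyr::expand_grid(
    reexport_fraction = reexport_fractions, seed = seeds
  )
  res <- purrr::pmap(cells, function(reexport_fraction, seed) {
    cfg <- config
    cfg$reexport_fraction <- reexport_fraction
    cfg$seed <- as.integer(seed)
    cfg$missing_fmi_fraction <- 0
    cfg$aquaculture_fraction <- 0
    cfg$nonfood_fraction <- 0
    world <- generate_world(cfg)
    inputs <- prepare_world_inputs(world)
    out <- run_derivations(inputs$balance, inputs$trade, inputs$fmi,
                           derivations = derivations)
    truth <- true_consumption_fmi(world$ledger, world$truth$fmi) |>
      dplyr::filter(.data$product_group == AGGREGATE_GROUP)
    out$aggregates |>
      dplyr::inner_join(
        dplyr::select(truth, "country_id", "fmi_true_c"),
        by = "country_id"
      ) |>
      dplyr::group_by(.data$derivation) |>
      dplyr::summarise(
        err = mean(abs(.data$fmi_c - .data$fmi_true_c)), .groups = "drop"
      ) |>
      dplyr::mutate(reexport_fraction = reexport_fraction, seed = seed)
  })
  dplyr::bind_rows(res) |>
    dplyr::group_by(.data$reexport_fraction, .data$derivation) |>
    dplyr::summarise(mean_abs_error = mean(.data$err), .groups = "drop")
}

#' Prepare pipeline inputs from a synthetic world
#'
#' Convenience wrapper running the ingestion and product-processing stages
#' on a generated world: trade filtering and canonicalization, live-weight
#' conversion, group classification, optional aquaculture exclusion, and
#' FMI assembly (gap-filling withheld countries from covariates).
#'
#' @param world A `seatrace_world`.
#' @param mode `"core"` keeps every food record; `"no_aquaculture"`
#'   additionally removes records matched by [aquaculture_rules()].
#' @param rules Rule set for the exclusion mode.
#' @return List with `balance`, `trade` (processed import/export records)
#'   and `fmi` (complete estimates table).
#' @export
prepare_world_inputs <- function(world, mode = c("core", "no_aquaculture"),
                                 rules = aquaculture_rules()) {
  mode <- match.arg(mode)
  filt <- filter_trade(world$trade, world$harmonization)
  trade <- assign_conversion(filt$records, world$conversion)
  trade <- classify_group(trade, world$group_mapping)
  if (mode == "no_aquaculture") {
    trade <- exclude_aquaculture(trade, rules)$records
  }
  fmi <- assemble_fmi(
    world$fmi, world$covariates, world$harmonization,
    required_ids = unique(c(world$balance$country_id, trade$reporter_id,
                            trade$partner_id))
  )
  list(balance = world$balance, trade = trade, fmi = fmi)
}
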