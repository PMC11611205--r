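#' Percent change from production to consumption sustainability
#'
#' `(fmi_p - mean_fmi_c) / fmi_p * 100`: positive values mean a country's
#' consumption is less sustainably managed than its production, negative
#' values the opposite. Undefined (`NA`) when `fmi_p` is zero.
#'
#' @param fmi_p Production FMI (vectorized).
#' @param mean_fmi_c Mean consumption FMI over the derivations.
#' @return Signed percentage(s).
#' @export
#' @examples
#' percent_change(0.932, 0.742) # about a 20% drop
percent_change <- function(fmi_p, mean_fmi_c) {
  ifelse(fmi_p > 0, (fmi_p - mean_fmi_c) / fmi_p * 100, NA_real_)
}

#' Published FMI pairs for the largest seafood producers
#'
#' Reference values of production FMI and mean consumption FMI (over the
#' three derivations) for the 25 largest seafood-producing countries over
#' 2012--2017, as reported in the fisheries-management literature at three
#' printed decimals. Shipped as the worked example for
#' [percent_change()]: applying it to these pairs reproduces the reported
#' core-analysis disparities (about 20.4% for the USA, 7.3% for Iceland,
#' 6.9% for Norway) up to rounding of the printed inputs.
#'
#' @return Tibble with columns `country`, `fmi_p`, `mean_fmi_c`.
#' @export
worked_example_fmi <- function() {
  path <- system.file("extdata", "top_producers_fmi.csv",
                      package = "seatrace", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Production-versus-consumption disparity table
#'
#' @param summary Per-country summary tibble from [run_derivations()]
#'   (columns `country_id`, `fmi_p`, `mean_fmi_c`, `min_fmi_c`,
#'   `max_fmi_c`).
#' @return The table with a `percent_change` column, sorted by decreasing
#'   production FMI.
#' @export
disparity_table <- function(summary) {
  summary |>
    dplyr::mutate(
      percent_change = percent_change(.data$fmi_p, .data$mean_fmi_c)
    ) |>
    dplyr::arrange(dplyr::desc(.data$fmi_p))
}

#' Linear relationship between production and consumption FMI
#'
#' Ordinary least squares of the aggregate consumption FMI on the
#' production FMI (`fmi_c ~ fmi_p`), one fit per derivation, reported with
#' coefficient standard errors, the slope t statistic and p-value, and R
#' squared.
#'
#' @param aggregates Aggregate tibble from [run_derivations()] (columns
#'   `country_id`, `derivation`, `fmi_p`, `fmi_c`).
#' @return Tibble with one row per derivation: `derivation`, `intercept`,
#'   `intercept_se`, `slope`, `slope_se`, `slope_t`, `p_value`,
#'   `r_squared`, `n`.
#' @export
fit_fmi_relationship <- function(aggregates) {
  aggregates |>
    dplyr::group_by(.data$derivation) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        stop_validation(sprintf(
          "fit_fmi_relationship(): need >= 3 countries, got %d (%s)",
          nrow(df), key$derivation
        ))
      }
      fit <- lm(fmi_c ~ fmi_p, data = df)
      s <- suppressWarnings(summary(fit))
      co <- s$coefficients
      tibble::tibble(
        intercept = co[1, 1], intercept_se = co[1, 2],
        slope = co[2, 1], slope_se = co[2, 2],
        slope_t = co[2, 3], p_value = co[2, 4],
        r_squared = s$r.squared, n = nrow(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Rank countries by share of global trade volume
#'
#' Pools live-weight volumes over the year window and reports each
#' country's share of global exports and imports together with its number
#' of distinct trade partners per direction. Rankings are by volume with
#' ties broken by country id (lexicographic).
#'
#' @param trade Processed trade tibble (live weights assigned).
#' @return Tibble `country_id`, `exports_t`, `imports_t`,
#'   `share_of_global_exports`, `share_of_global_imports`,
#'   `n_export_partners`, `n_import_partners`, `export_rank`,
#'   `import_rank`, sorted by export rank.
#' @export
rank_traders <- function(trade) {
  if (!"live_weight_t" %in% names(trade)) {
    stop_schema("rank_traders(): trade records lack live_weight_t")
  }
  per_dir <- trade |>
    dplyr::filter(.data$live_weight_t > 0) |>
    dplyr::group_by(.data$direction, country_id = .data$reporter_id) |>
    dplyr::summarise(
      volume_t = sum(.data$live_weight_t),
      n_partners = dplyr::n_distinct(.data$partner_id),
      .groups = "drop"
    )
  exp <- dplyr::filter(per_dir, .data$direction == "export")
  imp <- dplyr::filter(per_dir, .data$direction == "import")
  out <- dplyr::full_join(
    dplyr::transmute(exp, .data$country_id, exports_t = .data$volume_t,
                     n_export_partners = .data$n_partners),
    dplyr::transmute(imp, .data$country_id, imports_t = .data$volume_t,
                     n_import_partners = .data$n_partners),
    by = "country_id"
  ) |>
    dplyr::mutate(dplyr::across(
      c("exports_t", "imports_t", "n_export_partners", "n_import_partners"),
      ~ dplyr::coalesce(.x, 0)
    )) |>
    dplyr::mutate(
      share_of_global_exports =
        if (sum(.data$exports_t) > 0) .data$exports_t / sum(.data$exports_t)
        else 0,
      share_of_global_imports =
        if (sum(.data$imports_t) > 0) .data$imports_t / sum(.data$imports_t)
        else 0
    ) |>
    dplyr::arrange(dplyr::desc(.data$exports_t), .data$country_id) |>
    dplyr::mutate(export_rank = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$imports_t), .data$country_id) |>
    dplyr::mutate(import_rank = dplyr::row_number()) |>
    dplyr::arrange(.data$export_rank)
  out
}

#' Partner-level trade breakdown for one country
#'
#' The top partners of one country in one direction, with each partner's
#' share of the country's total volume and production FMI — the data
#' behind partner-breakdown bar charts.
#'
#' @param trade Processed trade tibble.
#' @param country_id Country to break down.
#' @param direction `"import"` (where its imports come from) or
#'   `"export"` (where its exports go).
#' @param fmi Optional FMI estimates to annotate partners with.
#' @param top_k Number of partners to keep (by volume, ties by id).
#' @return Tibble `partner_id`, `volume_t`, `share`, `partner_fmi_p` (if
#'   `fmi` given), with attribute `coverage` = summed share of the kept
#'   partners.
#' @export
partner_breakdown <- function(trade, country_id,
                              direction = c("import", "export"),
                              fmi = NULL, top_k = 25) {
  direction <- match.arg(direction)
  dir_val <- direction
  df <- trade |>
    dplyr::filter(.data$reporter_id == country_id,
                  .data$direction == dir_val) |>
    dplyr::group_by(.data$partner_id) |>
    dplyr::summarise(volume_t = sum(.data$live_weight_t), .groups = "drop") |>
    dplyr::mutate(share = .data$volume_t / sum(.data$volume_t)) |>
    dplyr::arrange(dplyr::desc(.data$volume_t), .data$partner_id) |>
    dplyr::slice_head(n = top_k)
  if (!is.null(fmi)) {
    df$partner_fmi_p <- fmi$fmi[match(df$partner_id, fmi$country_id)]
  }
  attr(df, "coverage") <- sum(df$share)
  df
}

#' Run the complete analysis and write a report bundle
#'
#' End-to-end orchestration: ingest and filter the trade records, convert
#' product weights, classify product groups, assemble the FMI table,
#' propagate under the requested derivations, and write disparity,
#' regression, trade-summary and partner-breakdown tables plus a run
#' manifest. The analysis is restricted to countries present in both the
#' balance and the filtered trade data, and runs in two modes: `core`
#' (all food records) and `no_aquaculture` (aquaculture-associated records
#' removed) — mirroring the main and exclusion variants of the analysis.
#' The whole run is deterministic; re-running a configuration reproduces
#' byte-identical tables.
#'
#' @param inputs List with elements `balance`, `trade`, `harmonization`,
#'   `fmi`, `covariates`, `conversion`, `group_mapping`, each either a
#'   tibble or a CSV path.
#' @param out_dir Directory for the report files (created if needed).
#' @param years Inclusive year window applied to the balance table.
#' @param derivations Derivation names to run.
#' @param modes Subset of `c("core", "no_aquaculture")`.
#' @param rules [aquaculture_rules()] for the exclusion mode.
#' @param top_k Partner-breakdown depth.
#' @return Invisibly, a named list per mode with the propagation object,
#'   disparity, regression and trade tables, plus the manifest.
#' @export
run_full_analysis <- function(inputs, out_dir,
                              years = c(2012L, 2017L),
                              derivations = c("proportional", "gephart",
                                              "guillen"),
                              modes = c("core", "no_aquaculture"),
                              rules = aquaculture_rules(),
                              top_k = 25) {
  modes <- match.arg(modes, several.ok = TRUE)
  unknown <- setdiff(derivations, c("proportional", "gephart", "guillen"))
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "run_full_analysis(): unknown derivation(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  get_tbl <- function(x, loader) if (is.character(x)) loader(x) else x
  balance <- validate_balance(
    get_tbl(inputs$balance, function(p) load_balance_table(p, years)),
    years = years
  )
  trade_raw <- validate_trade(get_tbl(inputs$trade, load_trade_table))
  harmonization <- get_tbl(inputs$harmonization, load_harmonization_table)
  fmi_raw <- get_tbl(inputs$fmi, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  covariates <- get_tbl(inputs$covariates, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  conversion <- validate_conversion(
    get_tbl(inputs$conversion, load_conversion_table)
  )
  group_mapping <- get_tbl(inputs$group_mapping, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  filt <- filter_trade(trade_raw, harmonization)
  trade_core <- classify_group(
    assign_conversion(filt$records, conversion), group_mapping
  )
  write_tbl <- function(df, name, mode) {
    readr::write_csv(df, file.path(out_dir, paste0(name, "_", mode, ".csv")))
  }
  out <- list()
  for (mode in modes) {
    trade <- if (mode == "no_aquaculture") {
      exclude_aquaculture(trade_core, rules)$records
    } else {
      trade_core
    }
    analysed <- intersect(unique(balance$country_id),
                          unique(trade$reporter_id))
    bal <- dplyr::filter(balance, .data$country_id %in% analysed)
    fmi <- assemble_fmi(
      fmi_raw, covariates, harmonization,
      required_ids = unique(c(bal$country_id, trade$partner_id))
    )
    prop <- run_derivations(bal, trade, fmi, derivations = derivations,
                            harmonization = harmonization)
    disparity <- disparity_table(prop$summary)
    regression <- fit_fmi_relationship(prop$aggregates)
    traders <- rank_traders(trade)
    top_importer <- traders$country_id[traders$import_rank == 1]
    top_exporter <- traders$country_id[traders$export_rank == 1]
    breakdown <- dplyr::bind_rows(
      partner_breakdown(trade, top_importer, "import", fmi, top_k) |>
        dplyr::mutate(country_id = top_importer, direction = "import"),
      partner_breakdown(trade, top_exporter, "export", fmi, top_k) |>
        dplyr::mutate(country_id = top_exporter, direction = "export")
    )
    write_tbl(prop$results, "results", mode)
    write_tbl(disparity, "disparity", mode)
    write_tbl(regression, "regression", mode)
    write_tbl(traders, "trade_summary", mode)
    write_tbl(breakdown, "partner_breakdown", mode)
    out[[mode]] <- list(
      propagation = prop, disparity = disparity, regression = regression,
      trade_summary = traders, partner_breakdown = breakdown,
      filter_audit = filt$audit, n_countries = length(analysed)
    )
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("seatrace")),
    years = as.integer(years),
    derivations = derivations,
    modes = modes,
    top_k = top_k,
    config_hash = rlang::hash(list(
      balance = balance, trade = trade_raw, harmonization = harmonization,
      fmi = fmi_raw, covariates = covariates, conversion = conversion,
      group_mapping = group_mapping, years = years,
      derivations = derivations, modes = modes, top_k = top_k
    )),
    filter_audit = filt$audit,
    n_countries = vapply(out, function(m) m$n_countries, integer(1))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Disparity range plot data (and optional rendering)
#'
#' Builds (and, when `ggplot2` is available, renders) the
#' production-versus-consumption disparity chart: per country, the
#' production FMI, the mean consumption FMI and the across-derivation
#' range, for the `top_n` producers.
#'
#' @param disparity Disparity tibble from [disparity_table()].
#' @param top_n Number of countries to show (by production FMI).
#' @param render Return a ggplot object instead of the plot data.
#' @return A tibble of plot data, or a ggplot object when `render = TRUE`.
#' @export
plot_disparity <- function(disparity, top_n = 25, render = FALSE) {
  df <- disparity |>
    dplyr::arrange(dplyr::desc(.data$fmi_p)) |>
    dplyr::slice_head(n = top_n)
  if (!render) return(df)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("plot_disparity(render = TRUE) requires ggplot2")
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$country_id, .data$fmi_p)
  )) +
    ggplot2::geom_linerange(ggplot2::aes(
      ymin = .data$min_fmi_c, ymax = .data$max_fmi_c
    ), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fmi_p), shape = 15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_fmi_c), shape = 17,
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "FMI",
                  title = "Production vs consumption sustainability") +
    ggplot2::theme_minimal()
}
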