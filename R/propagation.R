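# Fixed domestic-consumption shares for the two literature-derived
# sensitivity derivations: a US-based estimate accounting for re-exports
# (Gephart) and a global multi-region input-output estimate (Guillen).
PPC_GEPHART <- 0.365
PPC_GUILLEN <- 0.74

#' Sensitivity derivations for the domestic share of consumption
#'
#' The share of a country's seafood consumption that is domestic in origin
#' (`pPC`) cannot be observed from trade data because re-exported products
#' are re-flagged at the point of processing. Three derivations bracket
#' it: `proportional` sets `pPC = P / (P + I)` per country and product
#' group; `gephart` fixes `pPC = 0.365` everywhere; `guillen` fixes
#' `pPC = 0.74` everywhere. The import share is always `pIC = 1 - pPC`.
#'
#' @param name One of `"proportional"`, `"gephart"`, `"guillen"`.
#' @return List of class `derivation_spec` with `name` and `fixed_ppc`
#'   (`NA` for the proportional derivation).
#' @export
#' @examples
#' derivation_spec("gephart")$fixed_ppc
derivation_spec <- function(name = c("proportional", "gephart", "guillen")) {
  name <- match.arg(name)
  fixed <- switch(name,
    proportional = NA_real_,
    gephart = PPC_GEPHART,
    guillen = PPC_GUILLEN
  )
  structure(list(name = name, fixed_ppc = fixed), class = "derivation_spec")
}

#' Consumption from the food-balance identity
#'
#' Adds the derived consumption column `consumption_t = production_t +
#' imports_t - exports_t` to a balance table. Reported balance sheets can
#' carry `E > P + I` for a cell; a negative result is floored at zero (so
#' that downstream aggregation weights stay non-negative) and the number
#' of floored rows is reported as a warning.
#'
#' @param balance Validated balance tibble.
#' @return The tibble with a `consumption_t` column.
#' @export
compute_consumption <- function(balance) {
  raw <- balance$production_t + balance$imports_t - balance$exports_t
  n_neg <- sum(raw < 0)
  if (n_neg > 0) {
    warn(sprintf(
      "compute_consumption(): %d row(s) with negative P + I - E floored at 0",
      n_neg
    ), class = "seatrace_floor_warning")
  }
  balance$consumption_t <- pmax(0, raw)
  balance
}

# Pool balance quantities over the year window, per country x group.
pool_balance <- function(balance) {
  balance <- if ("consumption_t" %in% names(balance)) {
    balance
  } else {
    suppressWarnings(compute_consumption(balance))
  }
  balance |>
    dplyr::group_by(.data$country_id, .data$product_group) |>
    dplyr::summarise(
      production_t = sum(.data$production_t),
      imports_t = sum(.data$imports_t),
      exports_t = sum(.data$exports_t),
      consumption_t = sum(.data$consumption_t),
      .groups = "drop"
    )
}

#' Import shares per reporter and product group
#'
#' Relative contribution of each trade partner to a reporter's imports of
#' a product group, from live-weight import records pooled over the year
#' window. Only these *relative* shares feed the propagation; absolute
#' trade-record magnitudes are never used downstream.
#'
#' @param trade Processed trade tibble (with `live_weight_t` and
#'   `product_group`).
#' @return Tibble `reporter_id`, `product_group`, `partner_id`, `share`;
#'   shares sum to 1 within each (reporter, group) with any imports.
#' @export
import_shares <- function(trade) {
  if (!all(c("live_weight_t", "product_group") %in% names(trade))) {
    stop_schema(
      "import_shares(): trade records need live_weight_t and product_group; run assign_conversion() and classify_group() first"
    )
  }
  trade |>
    dplyr::filter(.data$direction == "import", .data$live_weight_t > 0) |>
    dplyr::group_by(
      reporter_id = .data$reporter_id, .data$product_group,
      partner_id = .data$partner_id
    ) |>
    dplyr::summarise(live_weight_t = sum(.data$live_weight_t),
                     .groups = "drop_last") |>
    dplyr::mutate(share = .data$live_weight_t / sum(.data$live_weight_t)) |>
    dplyr::ungroup() |>
    dplyr::select("reporter_id", "product_group", "partner_id", "share")
}

#' Export composition of trade partners
#'
#' Under the proportionality assumption, the split of a partner's exports
#' between own production and re-exported imports follows its balance
#' quantities: `p_pe = P / (P + I)` and `p_ie = 1 - p_pe`, per product
#' group, pooled over the year window. For aggregate partners (kind
#' `group` in the harmonization table) the composition is the unweighted
#' mean of the members' compositions.
#'
#' @param balance Balance tibble (yearly; pooled internally).
#' @param harmonization Optional harmonization tibble; when given, group
#'   entries receive member-mean compositions.
#' @return Tibble `partner_id`, `product_group`, `p_pe`, `p_ie`; countries
#'   with `P + I = 0` in a group carry `NA` composition.
#' @export
export_composition <- function(balance, harmonization = NULL) {
  pooled <- pool_balance(balance)
  comp <- pooled |>
    dplyr::transmute(
      partner_id = .data$country_id,
      product_group = .data$product_group,
      p_pe = dplyr::if_else(
        .data$production_t + .data$imports_t > 0,
        .data$production_t / (.data$production_t + .data$imports_t),
        NA_real_
      ),
      p_ie = 1 - .data$p_pe
    )
  if (!is.null(harmonization)) {
    groups <- harmonization[harmonization$kind == "group", ]
    if (nrow(groups) > 0) {
      extra <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
        members <- harmonization_members(harmonization, groups$canonical_id[i])
        comp |>
          dplyr::filter(.data$partner_id %in% members) |>
          dplyr::group_by(.data$product_group) |>
          dplyr::summarise(p_pe = mean(.data$p_pe), .groups = "drop") |>
          dplyr::mutate(
            partner_id = groups$canonical_id[i], p_ie = 1 - .data$p_pe
          )
      })
      comp <- dplyr::bind_rows(comp, extra[names(comp)])
    }
  }
  comp
}

#' Global production-weighted FMI per product group
#'
#' The regularization target for untraceable re-exports: the mean
#' production FMI of all countries, weighted by each country's share of
#' global production of the product group (pooled over the year window).
#'
#' @param balance Balance tibble.
#' @param fmi FMI estimates tibble (`country_id`, `fmi`) covering every
#'   producing country.
#' @param weights Set `TRUE` to also return the per-country production
#'   shares.
#' @return Tibble `product_group`, `fmi_glbl`; with `weights = TRUE`, a
#'   list with elements `table` and `weights` (`product_group`,
#'   `country_id`, `p_pglbl`).
#' @export
compute_global_fmi <- function(balance, fmi, weights = FALSE) {
  pooled <- pool_balance(balance)
  producing <- dplyr::filter(pooled, .data$production_t > 0)
  miss <- setdiff(unique(producing$country_id), fmi$country_id)
  if (length(miss) > 0) {
    stop_validation(sprintf(
      "compute_global_fmi(): producing countries without FMI: %s",
      paste(miss, collapse = ", ")
    ))
  }
  w <- producing |>
    dplyr::group_by(.data$product_group) |>
    dplyr::mutate(p_pglbl = .data$production_t / sum(.data$production_t)) |>
    dplyr::ungroup() |>
    dplyr::select("product_group", "country_id", "p_pglbl")
  bad <- w |>
    dplyr::group_by(.data$product_group) |>
    dplyr::summarise(s = sum(.data$p_pglbl), .groups = "drop") |>
    dplyr::filter(abs(.data$s - 1) > WEIGHT_TOL)
  if (nrow(bad) > 0) {
    stop_validation("compute_global_fmi(): production shares do not sum to 1")
  }
  tab <- w |>
    dplyr::left_join(fmi[c("country_id", "fmi")], by = "country_id") |>
    dplyr::group_by(.data$product_group) |>
    dplyr::summarise(fmi_glbl = sum(.data$p_pglbl * .data$fmi),
                     .groups = "drop")
  if (weights) list(table = tab, weights = w) else tab
}

#' Import-weighted FMI per reporter and product group
#'
#' For each reporter and product group, the FMI of its import mix: each
#' partner contributes its import share times a blend of the partner's own
#' production FMI (for the `p_pe` share of the partner's exports that is
#' its own production) and the global production-weighted FMI (for the
#' `p_ie` share that is untraceable re-export).
#'
#' @param shares Import-share tibble from [import_shares()].
#' @param comps Export-composition tibble from [export_composition()].
#' @param fmi FMI estimates covering every partner with positive share.
#' @param glbl Global-FMI tibble from [compute_global_fmi()].
#' @return Tibble `reporter_id`, `product_group`, `fmi_i`.
#' @export
compute_fmi_imports <- function(shares, comps, fmi, glbl) {
  df <- shares |>
    dplyr::left_join(comps, by = c("partner_id", "product_group")) |>
    dplyr::left_join(fmi[c("country_id", "fmi")],
                     by = c(partner_id = "country_id")) |>
    dplyr::left_join(glbl, by = "product_group")
  bad <- df$share > 0 & (is.na(df$p_pe) | is.na(df$fmi))
  if (any(bad)) {
    stop_validation(sprintf(
      "compute_fmi_imports(): partner(s) without composition or FMI: %s",
      paste(unique(df$partner_id[bad]), collapse = ", ")
    ))
  }
  df |>
    dplyr::group_by(.data$reporter_id, .data$product_group) |>
    dplyr::summarise(
      fmi_i = sum(.data$share *
                    (.data$p_pe * .data$fmi + .data$p_ie * .data$fmi_glbl)),
      .groups = "drop"
    )
}

#' Consumption FMI per country and product group
#'
#' Blends each country's own production FMI with its import-mix FMI using
#' the domestic-consumption share of the chosen derivation:
#' `fmi_c = ppc * fmi_p + (1 - ppc) * fmi_i`. Countries with no imports
#' of a group have `ppc` forced to 1 under every derivation (there is no
#' import mix to blend; the fixed literature shares presuppose imports
#' exist), flagged in `ppc_overridden`. Cells with `P + I = 0` have no
#' consumption basis and are omitted.
#'
#' @param balance Balance tibble (yearly; pooled internally).
#' @param fmi FMI estimates covering every country in `balance`.
#' @param fmi_i Import-FMI tibble from [compute_fmi_imports()].
#' @param derivation A [derivation_spec()] or its name.
#' @return Tibble `country_id`, `product_group`, `derivation`, `ppc_used`,
#'   `ppc_overridden`, `fmi_p`, `fmi_i`, `fmi_c`, `consumption_t`.
#' @export
compute_fmi_consumption <- function(balance, fmi, fmi_i,
                                    derivation = "proportional") {
  if (!inherits(derivation, "derivation_spec")) {
    derivation <- derivation_spec(derivation)
  }
  pooled <- pool_balance(balance)
  miss <- setdiff(unique(pooled$country_id), fmi$country_id)
  if (length(miss) > 0) {
    stop_validation(sprintf(
      "compute_fmi_consumption(): countries without FMI: %s",
      paste(miss, collapse = ", ")
    ))
  }
  df <- pooled |>
    dplyr::filter(.data$production_t + .data$imports_t > 0) |>
    dplyr::left_join(fmi[c("country_id", "fmi")], by = "country_id") |>
    dplyr::left_join(fmi_i, by = c(country_id = "reporter_id",
                                   "product_group"))
  no_imports <- df$imports_t == 0 | is.na(df$fmi_i)
  ppc <- if (is.na(derivation$fixed_ppc)) {
    df$production_t / (df$production_t + df$imports_t)
  } else {
    rep(derivation$fixed_ppc, nrow(df))
  }
  overridden <- no_imports & ppc != 1
  ppc[no_imports] <- 1
  tibble::tibble(
    country_id = df$country_id,
    product_group = df$product_group,
    derivation = derivation$name,
    ppc_used = ppc,
    ppc_overridden = overridden,
    fmi_p = df$fmi,
    fmi_i = df$fmi_i,
    fmi_c = ppc * df$fmi + dplyr::if_else(
      ppc < 1, (1 - ppc) * df$fmi_i, 0
    ),
    consumption_t = df$consumption_t
  )
}

#' Aggregate consumption FMI over product groups
#'
#' One consumption FMI per country and derivation: the per-group values
#' weighted by each group's share of the country's total seafood
#' consumption (pooled over the year window). Countries with zero total
#' consumption are omitted.
#'
#' @param results Per-group tibble from [compute_fmi_consumption()] (one
#'   or several derivations).
#' @return Tibble `country_id`, `derivation`, `fmi_c`, `consumption_t`
#'   with `product_group = "AGGREGATE"`.
#' @export
aggregate_fmi_c <- function(results) {
  results |>
    dplyr::filter(.data$consumption_t > 0) |>
    dplyr::group_by(.data$country_id, .data$derivation) |>
    dplyr::summarise(
      product_group = AGGREGATE_GROUP,
      fmi_p = .data$fmi_p[1],
      fmi_c = sum(.data$consumption_t * .data$fmi_c) /
        sum(.data$consumption_t),
      consumption_t = sum(.data$consumption_t),
      .groups = "drop"
    )
}

#' Run the full propagation under all derivations
#'
#' Executes the complete score-propagation pipeline on processed inputs:
#' import shares and export compositions, the global per-group FMI, the
#' import-weighted FMI, per-group consumption FMI under each requested
#' derivation, aggregation over product groups, and a per-country summary
#' with the across-derivation mean and range of the aggregate consumption
#' FMI.
#'
#' @param balance Validated balance tibble.
#' @param trade Processed trade tibble (live weights and product groups
#'   assigned).
#' @param fmi Complete FMI estimates table.
#' @param derivations Character vector of derivation names.
#' @param harmonization Optional harmonization tibble, used for aggregate
#'   partners' export compositions.
#' @return List of class `seatrace_propagation` with elements `results`
#'   (per country x group x derivation), `aggregates` (per country x
#'   derivation), `summary` (per country: `fmi_p`, `mean_fmi_c`,
#'   `min_fmi_c`, `max_fmi_c`), `global_fmi`, and `weights` (list of
#'   `import_shares`, `composition`, `global_weights` for audit).
#' @export
run_derivations <- function(balance, trade, fmi,
                            derivations = c("proportional", "gephart",
                                            "guillen"),
                            harmonization = NULL) {
  unknown <- setdiff(derivations, c("proportional", "gephart", "guillen"))
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "run_derivations(): unknown derivation(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  shares <- import_shares(trade)
  comps <- export_composition(balance, harmonization)
  glbl <- compute_global_fmi(balance, fmi, weights = TRUE)
  fmi_i <- compute_fmi_imports(shares, comps, fmi, glbl$table)
  results <- dplyr::bind_rows(lapply(
    derivations,
    function(d) compute_fmi_consumption(balance, fmi, fmi_i, d)
  ))
  aggregates <- aggregate_fmi_c(results)
  summary <- aggregates |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(
      fmi_p = .data$fmi_p[1],
      mean_fmi_c = mean(.data$fmi_c),
      min_fmi_c = min(.data$fmi_c),
      max_fmi_c = max(.data$fmi_c),
      .groups = "drop"
    )
  structure(
    list(
      results = results, aggregates = aggregates, summary = summary,
      global_fmi = glbl$table,
      weights = list(
        import_shares = shares, composition = comps,
        global_weights = glbl$weights
      )
    ),
    class = "seatrace_propagation"
  )
}

#' @export
print.seatrace_propagation <- function(x, ...) {
  cat(sprintf(
    "<seatrace_propagation> %d countries, %d derivation(s)\n",
    nrow(x$summary), length(unique(x$results$derivation))
  ))
  print(head(x$summary, 10))
  invisible(x)
}
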