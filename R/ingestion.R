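BALANCE_COLS <- c(
  "country_id", "product_group", "year", "production_t", "imports_t",
  "exports_t", "food_supply_t"
)
TRADE_COLS <- c(
  "reporter_id", "partner_id", "direction", "product_code", "product_desc",
  "year", "product_weight_t", "is_food", "farmed_flag"
)
HARMONIZATION_COLS <- c("raw_name", "canonical_id", "kind", "members")

#' Read and validate a food-balance table
#'
#' Reads a balance-sheet-style CSV with one row per country, ISSCAAP
#' product group and year, holding production, imports, exports and food
#' supply in tonnes live weight. Rows outside the analysis year window are
#' dropped at load. Quantities must be non-negative, product groups must
#' come from [isscaap_groups()], and the (country, group, year) key must be
#' unique.
#'
#' @param path Path to a CSV file with columns `country_id`,
#'   `product_group`, `year`, `production_t`, `imports_t`, `exports_t`,
#'   `food_supply_t`.
#' @param years Length-2 integer vector giving the inclusive year window.
#' @return A validated tibble.
#' @export
load_balance_table <- function(path, years = c(2012L, 2017L)) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_balance(df, years = years)
}

#' Validate an in-memory balance table
#'
#' Same checks as [load_balance_table()] applied to a data frame, for
#' pipelines that construct their inputs in code.
#'
#' @param df Data frame with the balance schema.
#' @param years Inclusive year window, or `NULL` to keep all years.
#' @return A validated tibble restricted to the window.
#' @export
validate_balance <- function(df, years = NULL) {
  check_columns(df, BALANCE_COLS, "balance table")
  df <- tibble::as_tibble(df)[BALANCE_COLS]
  if (!is.null(years)) {
    df <- dplyr::filter(df, .data$year >= years[1], .data$year <= years[2])
  }
  check_nonneg(
    df, c("production_t", "imports_t", "exports_t", "food_supply_t"),
    "balance table"
  )
  bad_groups <- setdiff(unique(df$product_group), isscaap_groups())
  if (length(bad_groups) > 0) {
    stop_validation(sprintf(
      "balance table: unknown product group(s): %s",
      paste(bad_groups, collapse = ", ")
    ))
  }
  dup <- df |>
    dplyr::count(.data$country_id, .data$product_group, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_validation(sprintf(
      "balance table: %d duplicated (country, group, year) key(s), e.g. %s/%s/%d",
      nrow(dup), dup$country_id[1], dup$product_group[1], dup$year[1]
    ))
  }
  df
}

#' Read a bilateral trade-record table
#'
#' Reads trade records (reporter, partner, direction, product, year,
#' product weight) from CSV. No partner validation or filtering happens at
#' load; see [filter_trade()]. A non-numeric weight is a parse error
#' naming the offending line.
#'
#' @param path Path to a CSV file with columns `reporter_id`, `partner_id`,
#'   `direction`, `product_code`, `product_desc`, `year`,
#'   `product_weight_t`, `is_food`, `farmed_flag`.
#' @return A tibble of trade records.
#' @export
load_trade_table <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      reporter_id = readr::col_character(),
      partner_id = readr::col_character(),
      direction = readr::col_character(),
      product_code = readr::col_character(),
      product_desc = readr::col_character(),
      year = readr::col_integer(),
      product_weight_t = readr::col_double(),
      is_food = readr::col_logical(),
      farmed_flag = readr::col_character()
    ),
    show_col_types = FALSE, progress = FALSE
  ))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop_validation(sprintf(
      "trade table: expected %s at line %d, got \"%s\"",
      prob$expected[1], prob$row[1] + 1L, prob$actual[1]
    ), problems = prob)
  }
  validate_trade(df)
}

#' Validate an in-memory trade table
#'
#' @param df Data frame with the trade schema.
#' @return A validated tibble.
#' @export
validate_trade <- function(df) {
  check_columns(df, TRADE_COLS, "trade table")
  df <- tibble::as_tibble(df)[union(TRADE_COLS, names(df))]
  check_nonneg(df, "product_weight_t", "trade table")
  bad_dir <- setdiff(unique(df$direction), c("import", "export"))
  if (length(bad_dir) > 0) {
    stop_validation(sprintf(
      "trade table: direction must be import/export, got: %s",
      paste(bad_dir, collapse = ", ")
    ))
  }
  df
}

#' Read a name-harmonization table
#'
#' Maps every raw reporter/partner name appearing in the trade data to a
#' canonical country, territory or group identifier. Group entries carry a
#' semicolon-separated member list.
#'
#' @param path Path to a CSV file with columns `raw_name`, `canonical_id`,
#'   `kind` (country/territory/group), `members`.
#' @return A tibble; `members` stays a semicolon-separated string (see
#'   [harmonization_members()]).
#' @export
load_harmonization_table <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  check_columns(df, HARMONIZATION_COLS, "harmonization table")
  df$members[is.na(df$members)] <- ""
  bad <- df$kind == "group" & df$members == ""
  if (any(bad)) {
    stop_validation(sprintf(
      "harmonization table: group entries without members: %s",
      paste(df$raw_name[bad], collapse = ", ")
    ))
  }
  tibble::as_tibble(df)
}

#' Member ids of a harmonization-table group entry
#'
#' @param harmonization Harmonization tibble.
#' @param id Canonical id of a group entry.
#' @return Character vector of member canonical ids.
#' @export
harmonization_members <- function(harmonization, id) {
  row <- harmonization[harmonization$canonical_id == id, ]
  if (nrow(row) == 0) {
    stop_validation(sprintf("harmonization table: unknown id %s", id))
  }
  strsplit(row$members[1], ";", fixed = TRUE)[[1]]
}

#' Filter and canonicalize trade records
#'
#' Applies the record-level exclusions used before any propagation:
#' non-food products (ornamentals, oils, feed, capsules and the like) are
#' dropped; reporter and partner names are re-keyed to canonical ids, with
#' any unmapped name a hard error (a silent drop would bias import
#' shares); aggregate or duplicate reporters (harmonization kind `group`
#' on the reporter side) are dropped; flows whose reporter and partner
#' canonicalize to the same country (intra-national trade) are dropped;
#' and duplicated (reporter, partner, product, year, direction) rows are
#' summed. Counts removed by each rule are returned in an audit list.
#'
#' @param records Trade tibble (as from [load_trade_table()]).
#' @param harmonization Harmonization tibble.
#' @return List with `records` (the retained, canonicalized tibble) and
#'   `audit` (named list of per-rule removal counts: `non_food`,
#'   `aggregate_reporter`, `intra_national`, `duplicates_summed`).
#' @export
filter_trade <- function(records, harmonization) {
  records <- validate_trade(records)
  raw_names <- unique(c(records$reporter_id, records$partner_id))
  unmapped <- setdiff(raw_names, harmonization$raw_name)
  if (length(unmapped) > 0) {
    stop_validation(
      sprintf(
        "filter_trade(): raw name(s) missing from harmonization table: %s",
        paste(sort(unmapped), collapse = ", ")
      ),
      unmapped = unmapped
    )
  }
  audit <- list()
  n0 <- nrow(records)
  records <- dplyr::filter(records, .data$is_food)
  audit$non_food <- n0 - nrow(records)

  idx_r <- match(records$reporter_id, harmonization$raw_name)
  idx_p <- match(records$partner_id, harmonization$raw_name)
  records$reporter_id <- harmonization$canonical_id[idx_r]
  records$partner_id <- harmonization$canonical_id[idx_p]
  reporter_kind <- harmonization$kind[idx_r]

  n0 <- nrow(records)
  records <- records[reporter_kind != "group", , drop = FALSE]
  audit$aggregate_reporter <- n0 - nrow(records)

  n0 <- nrow(records)
  records <- dplyr::filter(records, .data$reporter_id != .data$partner_id)
  audit$intra_national <- n0 - nrow(records)

  n0 <- nrow(records)
  records <- records |>
    dplyr::group_by(
      .data$reporter_id, .data$partner_id, .data$direction,
      .data$product_code, .data$product_desc, .data$year, .data$is_food,
      .data$farmed_flag
    ) |>
    dplyr::summarise(
      product_weight_t = sum(.data$product_weight_t), .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(TRADE_COLS))
  audit$duplicates_summed <- n0 - nrow(records)

  list(records = records, audit = audit)
}

#' Compare import magnitudes between the two data sources
#'
#' Totals live-weight imports per country from the balance-sheet source
#' and from the (converted) trade-record source and reports their ratio.
#' The two sources typically disagree in magnitude; downstream propagation
#' therefore uses only the *relative* partner shares of the trade source,
#' and this table quantifies how far apart the absolute levels are.
#'
#' @param balance Validated balance tibble.
#' @param trade Trade tibble carrying `live_weight_t` (after
#'   [assign_conversion()]).
#' @return Tibble with columns `country_id`, `balance_imports_t`,
#'   `trade_imports_t`, `ratio` (`trade / balance`, `NA` when the balance
#'   total is zero).
#' @export
compare_source_magnitudes <- function(balance, trade) {
  if (!"live_weight_t" %in% names(trade)) {
    stop_schema(
      "compare_source_magnitudes(): trade records lack live_weight_t; run assign_conversion() first"
    )
  }
  b <- balance |>
    dplyr::group_by(country_id = .data$country_id) |>
    dplyr::summarise(balance_imports_t = sum(.data$imports_t), .groups = "drop")
  g <- trade |>
    dplyr::filter(.data$direction == "import") |>
    dplyr::group_by(country_id = .data$reporter_id) |>
    dplyr::summarise(trade_imports_t = sum(.data$live_weight_t), .groups = "drop")
  dplyr::full_join(b, g, by = "country_id") |>
    dplyr::mutate(
      balance_imports_t = dplyr::coalesce(.data$balance_imports_t, 0),
      trade_imports_t = dplyr::coalesce(.data$trade_imports_t, 0),
      ratio = dplyr::if_else(
        .data$balance_imports_t > 0,
        .data$trade_imports_t / .data$balance_imports_t,
        NA_real_
      )
    ) |>
    dplyr::arrange(.data$country_id)
}
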