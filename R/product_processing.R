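#' Read a conversion-factor table
#'
#' Conversion factors (CF) relate processed product weight to whole-organism
#' live weight: `live_weight = product_weight * cf`. Each entry matches
#' products either by code prefix or by a keyword in the description;
#' exactly one default entry (empty `match_key`, `cf = 1`) must be present
#' so that products with no information — confidential trade, unmatched
#' codes — fall back to a factor of 1.
#'
#' @param path CSV with columns `match_key`, `cf`, `source`
#'   (fao/proxy/default), `note`.
#' @return A validated tibble.
#' @export
load_conversion_table <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_conversion(df)
}

#' Validate a conversion-factor table
#'
#' @param df Data frame with the conversion schema.
#' @return A validated tibble.
#' @export
validate_conversion <- function(df) {
  check_columns(df, c("match_key", "cf", "source", "note"), "conversion table")
  df <- tibble::as_tibble(df)
  df$match_key[is.na(df$match_key)] <- ""
  if (any(df$cf <= 0)) {
    stop_validation("conversion table: cf must be > 0")
  }
  is_default <- df$source == "default"
  if (sum(is_default) != 1 || df$cf[is_default] != 1) {
    stop_validation(
      "conversion table: exactly one default entry with cf = 1 is required"
    )
  }
  df
}

#' Convert product weights to live weights
#'
#' Assigns each trade record the most specific conversion factor available
#' and computes `live_weight_t = product_weight_t * cf`. Matching
#' precedence encodes "most closely related product first": the longest
#' exact code-prefix match wins, then a case-insensitive keyword match on
#' the product description, then the default factor of 1. The matched
#' source is recorded per record for audit.
#'
#' @param records Trade tibble.
#' @param table Conversion-factor tibble (see [load_conversion_table()]).
#' @return The records with `live_weight_t`, `cf` and `cf_source` columns.
#' @export
assign_conversion <- function(records, table) {
  table <- validate_conversion(table)
  prefixes <- table[table$source != "default" & table$match_key != "", ]
  # longest prefix first so the first hit is the most specific
  prefixes <- prefixes[order(-nchar(prefixes$match_key)), ]
  default_cf <- table$cf[table$source == "default"]

  codes <- unique(records$product_code)
  cf_for_code <- function(code, desc) {
    hit <- which(startsWith(code, prefixes$match_key))
    if (length(hit) > 0) {
      return(c(cf = prefixes$cf[hit[1]], src = prefixes$source[hit[1]]))
    }
    kw <- which(vapply(
      tolower(prefixes$match_key),
      function(k) grepl(k, tolower(desc), fixed = TRUE),
      logical(1)
    ))
    if (length(kw) > 0) {
      return(c(cf = prefixes$cf[kw[1]], src = prefixes$source[kw[1]]))
    }
    c(cf = default_cf, src = "default")
  }
  key <- paste(records$product_code, records$product_desc, sep = "\r")
  ukey <- !duplicated(key)
  lut <- mapply(
    cf_for_code, records$product_code[ukey], records$product_desc[ukey],
    SIMPLIFY = FALSE
  )
  names(lut) <- key[ukey]
  got <- lut[key]
  records$cf <- as.numeric(vapply(got, `[[`, "", "cf"))
  records$cf_source <- unname(vapply(got, `[[`, "", "src"))
  records$live_weight_t <- records$product_weight_t * records$cf
  records
}

#' Assign ISSCAAP product groups to trade records
#'
#' @param records Trade tibble.
#' @param mapping Tibble with columns `product_code`, `product_group`; must
#'   cover every code observed in `records` (an unmapped code is an error
#'   naming the codes).
#' @return The records with a `product_group` column.
#' @export
classify_group <- function(records, mapping) {
  check_columns(mapping, c("product_code", "product_group"), "group mapping")
  unmapped <- setdiff(unique(records$product_code), mapping$product_code)
  if (length(unmapped) > 0) {
    stop_validation(sprintf(
      "classify_group(): unmapped product code(s): %s",
      paste(sort(unmapped), collapse = ", ")
    ), unmapped = unmapped)
  }
  records$product_group <-
    mapping$product_group[match(records$product_code, mapping$product_code)]
  records
}

#' Aquaculture exclusion rule set
#'
#' Rules identifying trade records potentially associated with farmed
#' production, for the parallel analysis that removes aquaculture-only
#' trade. A record is removed when its description contains a farmed
#' keyword, names a species on the aquaculture species list, or is a
#' generalized listing of a commonly farmed taxon — unless an exemption
#' phrase (e.g. "not farmed") is present, which always wins.
#'
#' @param farmed_keywords Keywords marking explicitly farmed products.
#' @param exemption_keywords Phrases that exempt a record from removal.
#' @param species_list Species/group names commonly produced by
#'   aquaculture.
#' @param generalized_listings Generic product terms whose capture mode
#'   cannot be told apart (removed outright).
#' @return A list of class `aquaculture_rules`.
#' @export
aquaculture_rules <- function(farmed_keywords = c("farmed", "cultured",
                                                  "cultivated"),
                              exemption_keywords = c("not farmed",
                                                     "excluding farmed"),
                              species_list = character(),
                              generalized_listings = character()) {
  structure(
    list(
      farmed_keywords = tolower(farmed_keywords),
      exemption_keywords = tolower(exemption_keywords),
      species_list = tolower(species_list),
      generalized_listings = tolower(generalized_listings)
    ),
    class = "aquaculture_rules"
  )
}

#' Read an aquaculture rule set from YAML
#'
#' @param path YAML file with any of the four list fields of
#'   [aquaculture_rules()].
#' @return An `aquaculture_rules` object.
#' @export
load_aquaculture_rules <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("farmed_keywords", "exemption_keywords", "species_list",
               "generalized_listings")
  extra <- setdiff(names(raw), allowed)
  if (length(extra) > 0) {
    stop_schema(sprintf(
      "aquaculture rules: unknown field(s): %s", paste(extra, collapse = ", ")
    ))
  }
  do.call(aquaculture_rules, lapply(raw, as.character))
}

#' Remove aquaculture-associated trade records
#'
#' Applies an [aquaculture_rules()] set to the product descriptions.
#' The exemption check precedes every removal rule. Matching is
#' case-insensitive substring matching on whitespace-normalized text.
#'
#' @param records Trade tibble with descriptions.
#' @param rules An `aquaculture_rules` object.
#' @return List with `records` (retained tibble) and `audit` (named list of
#'   removal counts: `farmed_keyword`, `species_list`,
#'   `generalized_listing`, plus `exempted`).
#' @export
exclude_aquaculture <- function(records, rules = aquaculture_rules()) {
  stopifnot(inherits(rules, "aquaculture_rules"))
  desc <- tolower(gsub("\\s+", " ", trimws(records$product_desc)))
  has_any <- function(terms) {
    if (length(terms) == 0) return(rep(FALSE, length(desc)))
    Reduce(`|`, lapply(terms, function(t) grepl(t, desc, fixed = TRUE)))
  }
  exempt <- has_any(rules$exemption_keywords)
  # farmed keywords must not fire on the exemption phrases that contain them
  desc_masked <- desc
  for (ex in rules$exemption_keywords) {
    desc_masked <- gsub(ex, " ", desc_masked, fixed = TRUE)
  }
  hit_farmed <- if (length(rules$farmed_keywords) == 0) {
    rep(FALSE, length(desc))
  } else {
    Reduce(`|`, lapply(
      rules$farmed_keywords,
      function(t) grepl(t, desc_masked, fixed = TRUE)
    ))
  }
  hit_species <- has_any(rules$species_list)
  hit_general <- has_any(rules$generalized_listings)
  remove <- (hit_farmed | hit_species | hit_general) & !exempt
  audit <- list(
    farmed_keyword = sum(hit_farmed & !exempt),
    species_list = sum(hit_species & !exempt),
    generalized_listing = sum(hit_general & !exempt),
    exempted = sum((hit_farmed | hit_species | hit_general) & exempt),
    removed = sum(remove)
  )
  list(records = records[!remove, , drop = FALSE], audit = audit)
}
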