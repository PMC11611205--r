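#' Fit the FMI gap-filling regression
#'
#' Ordinary least squares of FMI on the Social Progress Index (SPI) with
#' additive geo-region effects (treatment coding), the model used to
#' predict FMI for countries without a surveyed or modeled score:
#' `fmi ~ spi + geo_region`.
#'
#' @param known Tibble of countries with known FMI, columns `country_id`,
#'   `fmi`.
#' @param covariates Tibble with columns `country_id`, `spi`, `geo_region`
#'   covering the known countries.
#' @return A list of class `fmi_gapfill_model` with elements `fit` (the
#'   `lm` object), `coefficients`, `r_squared` and `regions` (the region
#'   levels seen in training).
#' @export
fit_gapfill_model <- function(known, covariates) {
  df <- dplyr::inner_join(known, covariates, by = "country_id")
  miss <- setdiff(known$country_id, covariates$country_id)
  if (length(miss) > 0) {
    stop_validation(sprintf(
      "fit_gapfill_model(): no covariates for: %s", paste(miss, collapse = ", ")
    ))
  }
  if (any(is.na(df$spi))) {
    stop_validation(sprintf(
      "fit_gapfill_model(): missing SPI for: %s",
      paste(df$country_id[is.na(df$spi)], collapse = ", ")
    ))
  }
  if (length(unique(df$spi)) < 2) {
    stop_validation(
      "fit_gapfill_model(): need at least 2 distinct SPI values (rank deficient)"
    )
  }
  df$geo_region <- factor(df$geo_region)
  # with a single training region the region term is unidentifiable and
  # folds into the intercept
  fit <- if (nlevels(df$geo_region) < 2) {
    lm(fmi ~ spi, data = df)
  } else {
    lm(fmi ~ spi + geo_region, data = df)
  }
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_validation(sprintf(
      "fit_gapfill_model(): rank-deficient fit; unidentified term(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(
      fit = fit,
      coefficients = coef(fit),
      r_squared = suppressWarnings(summary(fit))$r.squared,
      regions = levels(df$geo_region)
    ),
    class = "fmi_gapfill_model"
  )
}

#' @export
print.fmi_gapfill_model <- function(x, ...) {
  cat("<fmi_gapfill_model> fmi ~ spi + geo_region\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared: %.3f (%d regions)\n", x$r_squared,
              length(x$regions)))
  invisible(x)
}

#' Predict FMI for countries without a score
#'
#' Applies a fitted gap-filling model to the covariates of countries
#' missing FMI. Predictions are clamped to the \[0, 1\] FMI range (the
#' score is defined on that interval; an unclamped prediction would not be
#' an FMI), and any clamping is recorded. Countries with missing SPI, or
#' in a region absent from training, are an error: each such case must be
#' resolved explicitly in the harmonization table rather than silently
#' imputed.
#'
#' @param model A `fmi_gapfill_model`.
#' @param missing Covariates tibble (`country_id`, `spi`, `geo_region`)
#'   for the countries to fill.
#' @return Tibble of estimates: `country_id`, `fmi`, `provenance`
#'   (`"gapfilled"`), `se`, `clamped` (logical).
#' @export
gapfill <- function(model, missing) {
  stopifnot(inherits(model, "fmi_gapfill_model"))
  if (nrow(missing) == 0) {
    return(tibble::tibble(
      country_id = character(), fmi = numeric(), provenance = character(),
      se = numeric(), clamped = logical()
    ))
  }
  if (any(is.na(missing$spi))) {
    stop_validation(sprintf(
      "gapfill(): missing SPI for: %s",
      paste(missing$country_id[is.na(missing$spi)], collapse = ", ")
    ))
  }
  new_regions <- setdiff(unique(missing$geo_region), model$regions)
  if (length(new_regions) > 0) {
    stop_validation(sprintf(
      "gapfill(): region(s) with no training observations: %s",
      paste(new_regions, collapse = ", ")
    ))
  }
  nd <- data.frame(
    spi = missing$spi,
    geo_region = factor(missing$geo_region, levels = model$regions)
  )
  pred <- predict(model$fit, newdata = nd, se.fit = TRUE)
  raw <- unname(pred$fit)
  tibble::tibble(
    country_id = missing$country_id,
    fmi = clamp01(raw),
    provenance = "gapfilled",
    se = unname(pred$se.fit),
    clamped = raw < 0 | raw > 1
  )
}

#' FMI of a grouped trade partner
#'
#' Aggregate reporters (e.g. a customs union) and lone territories are
#' scored from their member countries: the unweighted arithmetic mean of
#' the members' FMI. A singleton member list encodes "most closely related
#' country".
#'
#' @param harmonization Harmonization tibble.
#' @param group_id Canonical id of the group entry.
#' @param estimates FMI estimates tibble (`country_id`, `fmi`) covering all
#'   members.
#' @return One-row tibble: `country_id` (the group id), `fmi`, `provenance`
#'   (`"group_mean"`), `se` (`NA`).
#' @export
group_fmi <- function(harmonization, group_id, estimates) {
  members <- harmonization_members(harmonization, group_id)
  miss <- setdiff(members, estimates$country_id)
  if (length(miss) > 0) {
    stop_validation(sprintf(
      "group_fmi(): members without estimates: %s", paste(miss, collapse = ", ")
    ))
  }
  vals <- estimates$fmi[match(members, estimates$country_id)]
  tibble::tibble(
    country_id = group_id, fmi = mean(vals), provenance = "group_mean",
    se = NA_real_
  )
}

#' Assemble a complete FMI table over every required id
#'
#' Combines released (surveyed/modeled) scores, gap-filled predictions for
#' countries with covariates but no score, and group means for aggregate
#' entries, into one table with exactly one estimate per required
#' canonical id.
#'
#' @param fmi Released FMI tibble (`country_id`, `fmi`, `provenance`,
#'   `se`).
#' @param covariates Covariates tibble for all countries.
#' @param harmonization Harmonization tibble (group entries are scored by
#'   member mean).
#' @param required_ids Canonical ids that must have an estimate; defaults
#'   to every id in the harmonization table.
#' @return Tibble with one row per required id: `country_id`, `fmi`,
#'   `provenance`, `se`.
#' @export
assemble_fmi <- function(fmi, covariates, harmonization,
                         required_ids = NULL) {
  if (is.null(required_ids)) {
    required_ids <- unique(harmonization$canonical_id)
  }
  if (any(fmi$fmi < 0 | fmi$fmi > 1, na.rm = TRUE)) {
    stop_validation("assemble_fmi(): released FMI outside [0, 1]")
  }
  kinds <- harmonization$kind[match(required_ids, harmonization$canonical_id)]
  group_ids <- required_ids[!is.na(kinds) & kinds == "group"]
  country_ids <- setdiff(required_ids, group_ids)

  have <- intersect(country_ids, fmi$country_id)
  need <- setdiff(country_ids, have)
  est <- fmi[fmi$country_id %in% have,
             c("country_id", "fmi", "provenance", "se")]
  if (length(need) > 0) {
    miss_cov <- setdiff(need, covariates$country_id)
    if (length(miss_cov) > 0) {
      stop_validation(sprintf(
        "assemble_fmi(): no FMI and no covariates for: %s",
        paste(miss_cov, collapse = ", ")
      ))
    }
    model <- fit_gapfill_model(fmi, covariates)
    filled <- gapfill(model, covariates[covariates$country_id %in% need, ])
    est <- dplyr::bind_rows(est, filled[c("country_id", "fmi", "provenance",
                                          "se")])
  }
  if (length(group_ids) > 0) {
    grp <- dplyr::bind_rows(lapply(
      group_ids, function(g) group_fmi(harmonization, g, est)
    ))
    est <- dplyr::bind_rows(est, grp)
  }
  est <- dplyr::arrange(est, .data$country_id)
  stopifnot(
    setequal(est$country_id, required_ids),
    !anyDuplicated(est$country_id)
  )
  est
}
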