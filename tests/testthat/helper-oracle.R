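# Independent brute-force expansion of the propagation equations, written
# as plain base-R loops with no shared code with the package internals.
# Pools the balance over years, computes per-group global FMI, partner
# compositions and import shares, then expands the consumption FMI sum
# term by term.
oracle_propagation <- function(balance, trade, fmi,
                               derivations = c("proportional", "gephart",
                                               "guillen")) {
  fmi_v <- setNames(fmi$fmi, fmi$country_id)
  imp <- trade[trade$direction == "import" & trade$live_weight_t > 0, ]
  countries <- sort(unique(balance$country_id))
  groups <- unique(balance$product_group)
  fixed <- c(proportional = NA, gephart = 0.365, guillen = 0.74)

  per_group <- list()
  for (g in groups) {
    bg <- balance[balance$product_group == g, ]
    P <- I <- E <- C <- setNames(numeric(length(countries)), countries)
    for (k in seq_len(nrow(bg))) {
      cc <- bg$country_id[k]
      P[cc] <- P[cc] + bg$production_t[k]
      I[cc] <- I[cc] + bg$imports_t[k]
      E[cc] <- E[cc] + bg$exports_t[k]
      C[cc] <- C[cc] + max(0, bg$production_t[k] + bg$imports_t[k] -
                             bg$exports_t[k])
    }
    glbl <- 0
    tot_p <- sum(P)
    for (k in countries) glbl <- glbl + P[[k]] / tot_p * fmi_v[[k]]
    ig <- imp[imp$product_group == g, ]
    for (r in countries) {
      if (P[[r]] + I[[r]] == 0) next
      rows <- ig[ig$reporter_id == r, ]
      if (nrow(rows) > 0) {
        m <- tapply(rows$live_weight_t, rows$partner_id, sum)
        fmi_i <- 0
        for (j in names(m)) {
          share <- m[[j]] / sum(m)
          ppe <- P[[j]] / (P[[j]] + I[[j]])
          fmi_i <- fmi_i + share * (ppe * fmi_v[[j]] + (1 - ppe) * glbl)
        }
      } else {
        fmi_i <- NA_real_
      }
      for (d in derivations) {
        ppc <- if (is.na(fixed[[d]])) P[[r]] / (P[[r]] + I[[r]]) else fixed[[d]]
        if (I[[r]] == 0 || nrow(rows) == 0) ppc <- 1
        fmi_c <- if (ppc == 1) fmi_v[[r]] else {
          ppc * fmi_v[[r]] + (1 - ppc) * fmi_i
        }
        per_group[[length(per_group) + 1L]] <- data.frame(
          country_id = r, product_group = g, derivation = d,
          fmi_c = fmi_c, consumption_t = C[[r]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  per_group <- do.call(rbind, per_group)
  agg <- list()
  for (d in derivations) {
    for (r in unique(per_group$country_id)) {
      rows <- per_group[per_group$country_id == r &
                          per_group$derivation == d &
                          per_group$consumption_t > 0, ]
      if (nrow(rows) == 0) next
      w <- rows$consumption_t / sum(rows$consumption_t)
      agg[[length(agg) + 1L]] <- data.frame(
        country_id = r, derivation = d, fmi_c = sum(w * rows$fmi_c),
        stringsAsFactors = FALSE
      )
    }
  }
  list(per_group = per_group, aggregates = do.call(rbind, agg))
}

# Compare pipeline and oracle aggregate FMI_C on one world; returns the
# maximum absolute difference over countries x derivations.
oracle_max_diff <- function(world) {
  inputs <- seatrace::prepare_world_inputs(world)
  res <- seatrace::run_derivations(inputs$balance, inputs$trade, inputs$fmi)
  orc <- oracle_propagation(inputs$balance, inputs$trade, inputs$fmi)
  cmp <- merge(
    as.data.frame(res$aggregates)[c("country_id", "derivation", "fmi_c")],
    orc$aggregates,
    by = c("country_id", "derivation"), suffixes = c("", "_oracle")
  )
  stopifnot(nrow(cmp) == nrow(res$aggregates))
  max(abs(cmp$fmi_c - cmp$fmi_c_oracle))
}

# Straight-line fit by explicit normal equations, independent of lm().
normal_equation_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
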