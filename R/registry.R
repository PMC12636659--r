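#' Default variable registry for the 22-indicator hemodialysis panel
#'
#' The registry describes every clinical indicator handled by the package:
#' 17 base laboratory/dialysis measurements plus 5 composite indicators
#' derived from them. Each entry carries its measurement unit, its clinical
#' domain group, whether it is a base or composite variable, a skewness hint
#' (variables that are right-skewed in dialysis populations and therefore
#' candidates for Yeo-Johnson transformation), a non-negativity flag, and,
#' for composites, the names of the base inputs.
#'
#' Domain groups follow the five-domain organisation of routine hemodialysis
#' monitoring: inflammation/nutrition, anemia, mineral metabolism, dialysis
#' efficiency, and intradialytic electrolyte fluctuation.
#'
#' @return A data.frame with one row per indicator and columns
#'   `name`, `unit`, `domain_group`, `kind` (`"base"`/`"composite"`),
#'   `skewed` (logical transformation hint), `nonneg` (logical),
#'   `inputs` (comma-separated base inputs, `""` for base variables).
#' @export
#' @examples
#' reg <- default_registry()
#' nrow(reg)            # 22
#' sum(reg$kind == "base")  # 17
default_registry <- function() {
  reg <- rbind(
    # inflammation / nutrition
    c("wbc",         "1e9/L",     "inflammation_nutrition", "base", TRUE,  TRUE, ""),
    c("crp",         "mg/L",      "inflammation_nutrition", "base", TRUE,  TRUE, ""),
    c("albumin",     "g/L",       "inflammation_nutrition", "base", FALSE, TRUE, ""),
    # anemia
    c("hemoglobin",  "g/L",       "anemia",  "base", FALSE, TRUE, ""),
    c("ferritin",    "ng/mL",     "anemia",  "base", TRUE,  TRUE, ""),
    c("tsat",        "%",         "anemia",  "base", TRUE,  TRUE, ""),
    # mineral metabolism
    c("calcium",     "mmol/L",    "mineral", "base", FALSE, TRUE, ""),
    c("phosphorus",  "mmol/L",    "mineral", "base", FALSE, TRUE, ""),
    c("ipth",        "pg/mL",     "mineral", "base", TRUE,  TRUE, ""),
    c("alp",         "U/L",       "mineral", "base", TRUE,  TRUE, ""),
    # dialysis efficiency
    c("ktv",         "dimensionless", "dialysis", "base", FALSE, TRUE, ""),
    c("b2m_pre",     "mg/L",      "dialysis", "base", TRUE,  TRUE, ""),
    c("b2m_rr",      "%",         "dialysis", "base", FALSE, TRUE, ""),
    c("bun_pre",     "mmol/L",    "dialysis", "base", FALSE, TRUE, ""),
    # electrolyte fluctuation (per-session absolute changes)
    c("hco3_delta",  "mmol/L",    "electrolyte", "base", FALSE, TRUE, ""),
    c("k_delta",     "mmol/L",    "electrolyte", "base", FALSE, TRUE, ""),
    c("na_delta",    "mmol/L",    "electrolyte", "base", FALSE, TRUE, ""),
    # composites (derived, never measured)
    c("ca_p_product", "mmol2/L2", "mineral", "composite", FALSE, TRUE,
      "calcium,phosphorus"),
    c("inflammation_nutrition_ratio", "(mg/L)/(g/L)", "inflammation_nutrition",
      "composite", TRUE, TRUE, "crp,albumin"),
    c("ferritin_hb_ratio", "(ng/mL)/(g/L)", "anemia", "composite", TRUE, TRUE,
      "ferritin,hemoglobin"),
    c("msmci", "percent*dimensionless", "dialysis", "composite", FALSE, TRUE,
      "b2m_rr,ktv"),
    c("edi",  "mmol/L", "electrolyte", "composite", FALSE, TRUE,
      "na_delta,k_delta,hco3_delta")
  )
  reg <- data.frame(
    name = reg[, 1], unit = reg[, 2], domain_group = reg[, 3],
    kind = reg[, 4], skewed = as.logical(reg[, 5]),
    nonneg = as.logical(reg[, 6]), inputs = reg[, 7],
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$name))
  reg
}

#' Names of the base (measured) indicators in registry order
#' @param registry A registry data.frame, defaults to [default_registry()].
#' @return Character vector of base indicator names.
#' @export
base_indicator_names <- function(registry = default_registry()) {
  registry$name[registry$kind == "base"]
}

#' Names of the composite (derived) indicators in registry order
#' @inheritParams base_indicator_names
#' @return Character vector of composite indicator names.
#' @export
composite_indicator_names <- function(registry = default_registry()) {
  registry$name[registry$kind == "composite"]
}

#' Write the variable registry as CSV
#' @param registry Registry data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE)
  invisible(path)
}
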