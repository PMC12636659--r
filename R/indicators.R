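#' Composite clinical indicators
#'
#' Five composite indicators integrate complementary pathophysiological
#' domains of the hemodialysis panel: calcium-phosphorus product (vascular
#' calcification driving force), CRP/albumin inflammation-nutrition ratio
#' (malnutrition-inflammation complex syndrome), ferritin/hemoglobin ratio
#' (functional iron deficiency), the Middle-Small Molecule Clearance Index
#' (MSMCI, beta2-microglobulin reduction ratio x Kt/V), and the Electrolyte
#' Disturbance Index (EDI, total intradialytic electrolyte flux).
#'
#' The default unit system follows the units in which cohort summaries are
#' reported: calcium/phosphorus in mmol/L (so the product is mmol^2/L^2) and
#' hemoglobin in g/L for the ferritin ratio. A mg/dL mode is provided for
#' the calcium-phosphorus product (conversion factors 4.008 mg/dL per mmol/L
#' for calcium, 3.097 for phosphorus); no unit is ever converted silently.
#'
#' @name composites
NULL

# mg/dL per mmol/L
.CA_MGDL <- 4.008
.P_MGDL <- 3.097

#' Calcium-phosphorus product
#' @param calcium Serum calcium, mmol/L.
#' @param phosphorus Serum phosphorus, mmol/L.
#' @param unit_mode `"mmol"` (default, result mmol^2/L^2) or `"mgdl"`
#'   (inputs converted to mg/dL first, result mg^2/dL^2).
#' @return Numeric vector of products.
#' @export
#' @examples ca_p_product(2.29, 1.81)  # 4.1449
ca_p_product <- function(calcium, phosphorus, unit_mode = c("mmol", "mgdl")) {
  unit_mode <- match.arg(unit_mode)
  if (any(calcium < 0, na.rm = TRUE) || any(phosphorus < 0, na.rm = TRUE))
    stop("calcium and phosphorus must be non-negative")
  if (unit_mode == "mgdl")
    (calcium * .CA_MGDL) * (phosphorus * .P_MGDL)
  else
    calcium * phosphorus
}

#' Inflammation-nutrition ratio (CRP/albumin)
#' @param crp C-reactive protein, mg/L.
#' @param albumin Serum albumin, g/L; must be positive.
#' @return crp/albumin.
#' @export
inflammation_nutrition_ratio <- function(crp, albumin) {
  if (any(albumin <= 0, na.rm = TRUE)) stop("albumin must be positive")
  crp / albumin
}

#' Ferritin-hemoglobin ratio
#' @param ferritin Serum ferritin, ng/mL.
#' @param hemoglobin Hemoglobin, g/L; must be positive.
#' @return ferritin/hemoglobin.
#' @export
ferritin_hb_ratio <- function(ferritin, hemoglobin) {
  if (any(hemoglobin <= 0, na.rm = TRUE)) stop("hemoglobin must be positive")
  ferritin / hemoglobin
}

#' Middle-Small Molecule Clearance Index (MSMCI)
#'
#' beta2-microglobulin reduction ratio (percent, 0-100 scale) times Kt/V,
#' integrating middle- and small-molecule clearance in one adequacy index.
#'
#' @param b2m_rr Reduction ratio in percent, within \[0, 100\].
#' @param ktv Single-pool Kt/V, non-negative.
#' @return The product.
#' @export
#' @examples msmci(83.09, 2.00)  # 166.18
msmci <- function(b2m_rr, ktv) {
  if (any(b2m_rr < 0 | b2m_rr > 100, na.rm = TRUE))
    stop("b2m_rr must lie in [0, 100] (percent scale)")
  if (any(ktv < 0, na.rm = TRUE)) stop("ktv must be non-negative")
  b2m_rr * ktv
}

#' Electrolyte Disturbance Index (EDI)
#' @param delta_na,delta_k,delta_hco3 Signed per-session changes, mmol/L.
#' @return |dNa| + |dK| + |dHCO3|.
#' @export
edi <- function(delta_na, delta_k, delta_hco3) {
  abs(delta_na) + abs(delta_k) + abs(delta_hco3)
}

#' Derive all five composite indicators on a cohort table
#'
#' Appends (or overwrites) the composite columns of the 22-indicator panel.
#' A composite is missing wherever any of its inputs is missing. The
#' operation is idempotent.
#'
#' @param table An `hd_cohort` containing at least the 17 base indicators.
#' @param registry Full registry describing the composites (default
#'   [default_registry()]).
#' @return An `hd_cohort` with the full 22-column panel in registry order.
#' @export
derive_all <- function(table, registry = default_registry()) {
  need <- base_indicator_names(registry)
  have <- colnames(table$values)
  if (!all(need %in% have))
    stop("missing base columns: ", paste(setdiff(need, have), collapse = ", "))
  v <- function(nm) table$values[, nm]
  comp <- cbind(
    ca_p_product = ca_p_product(v("calcium"), v("phosphorus")),
    inflammation_nutrition_ratio = inflammation_nutrition_ratio(v("crp"), v("albumin")),
    ferritin_hb_ratio = ferritin_hb_ratio(v("ferritin"), v("hemoglobin")),
    msmci = msmci(v("b2m_rr"), v("ktv")),
    edi = edi(v("na_delta"), v("k_delta"), v("hco3_delta"))
  )
  if (nrow(table$values) == 0)
    comp <- matrix(NA_real_, 0, 5, dimnames = list(NULL, composite_indicator_names(registry)))
  vals <- cbind(table$values[, need, drop = FALSE], comp)
  vals <- vals[, registry$name, drop = FALSE]
  cohort_table(vals, registry, ids = table$ids)
}
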