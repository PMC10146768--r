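#' Hazard quotient of a monitoring concentration against a criterion
#'
#' `HQ = EEC / AWQC` after converting the monitoring concentration from
#' ng/L to ug/L. Units are fixed (monitoring data in ng/L, criteria in
#' ug/L) to prevent silent unit errors.
#'
#' @param eec_ng_per_L Environmental exposure concentration(s), ng/L,
#'   >= 0.
#' @param awqc_ug_per_L Ambient water quality criterion, ug/L, > 0.
#' @return Dimensionless hazard quotient(s).
#' @export
hazard_quotient <- function(eec_ng_per_L, awqc_ug_per_L) {
  if (awqc_ug_per_L <= 0) stop("awqc must be positive")
  if (any(eec_ng_per_L < 0)) stop("eec must be non-negative")
  (eec_ng_per_L / 1000) / awqc_ug_per_L
}

risk_levels <- c("no_risk", "low", "intermediate", "high")

#' Classify a hazard quotient into a risk category
#'
#' Bins: `[0, 0.1)` no risk; `[0.1, 1)` low; `[1, 10]` intermediate;
#' `(10, Inf)` high. The published bin edges overlap at 1 and 10; ties
#' are resolved to the more protective (higher) category, so HQ = 1 is
#' intermediate.
#'
#' @param hq Hazard quotient(s), >= 0.
#' @return Ordered factor with levels no_risk < low < intermediate <
#'   high.
#' @export
classify_risk <- function(hq) {
  if (any(hq < 0)) stop("hq must be non-negative")
  idx <- ifelse(hq < 0.1, 1L, ifelse(hq < 1, 2L, ifelse(hq <= 10, 3L, 4L)))
  factor(risk_levels[idx], levels = risk_levels, ordered = TRUE)
}

#' Summarize monitoring sites against a criterion
#'
#' Computes per-site hazard quotients and categories, category fractions
#' over sites, and a headline HQ from the median monitored concentration
#' (midpoint convention for even counts).
#'
#' @param samples Data frame with columns `site_id` and `eec_ng_per_L`.
#' @param awqc_ug_per_L Criterion, ug/L.
#' @return List with `per_site` (site_id, eec_ng_per_L, hq, category),
#'   `fractions` (named, sums to 1), `median_eec_ng_per_L`, `median_hq`,
#'   `median_category`, and `binning` (rule identifier).
#' @export
summarize_sites <- function(samples, awqc_ug_per_L) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L,
            all(c("site_id", "eec_ng_per_L") %in% names(samples)))
  hq <- hazard_quotient(samples$eec_ng_per_L, awqc_ug_per_L)
  cat_ <- classify_risk(hq)
  frac <- table(cat_) / nrow(samples)
  med <- median(samples$eec_ng_per_L)
  med_hq <- hazard_quotient(med, awqc_ug_per_L)
  list(per_site = data.frame(site_id = samples$site_id,
                             eec_ng_per_L = samples$eec_ng_per_L,
                             hq = hq, category = as.character(cat_),
                             stringsAsFactors = FALSE),
       fractions = setNames(as.numeric(frac), names(frac)),
       median_eec_ng_per_L = med,
       median_hq = med_hq,
       median_category = as.character(classify_risk(med_hq)),
       binning = "halfopen_0.1_1_10_ties_up")
}
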