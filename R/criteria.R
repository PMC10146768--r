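#' Freely dissolved fraction of a chemical in water
#'
#' Organic-carbon partitioning leaves only part of a hydrophobic chemical
#' freely dissolved:
#' \deqn{f_{fd} = \frac{1}{1 + POC \cdot K_{ow} + DOC \cdot 0.08 \cdot K_{ow}}}
#' with \eqn{K_{ow} = 10^{lgK_{ow}}}. The 0.08 factor discounts the
#' sorptive capacity of dissolved relative to particulate organic carbon.
#'
#' @param lg_kow log10 octanol-water partition coefficient.
#' @param poc Particulate organic carbon concentration, kg/L.
#' @param doc Dissolved organic carbon concentration, kg/L.
#' @return Fraction in (0, 1]; 1 in organic-carbon-free water.
#' @export
free_dissolved_fraction <- function(lg_kow, poc, doc) {
  stopifnot(is.finite(lg_kow), poc >= 0, doc >= 0)
  kow <- 10^lg_kow
  1 / (1 + poc * kow + doc * 0.08 * kow)
}

#' Back-solve the organic-carbon sorption term from a known fraction
#'
#' Returns `C = POC + 0.08 * DOC` (kg/L) such that
#' [free_dissolved_fraction()] reproduces `f_fd` at the given `lg_kow`.
#' Useful when only a published freely dissolved fraction, not the water
#' chemistry, is available.
#'
#' @param lg_kow log10 Kow.
#' @param f_fd Known freely dissolved fraction in (0, 1].
#' @return The combined organic-carbon term, kg/L.
#' @export
solve_organic_carbon_term <- function(lg_kow, f_fd) {
  stopifnot(f_fd > 0, f_fd <= 1)
  (1 / f_fd - 1) / 10^lg_kow
}

#' Trophic-level bioaccumulation parameters
#'
#' @param level Trophic level, one of 2, 3, 4.
#' @param f_l Lipid fraction of organisms at this level, in (0, 1).
#' @param fcm Food chain multiplication factor, >= 1.
#' @param bcf Laboratory bioconcentration factor, L/kg, > 0 (may be `NA`
#'   when it is to be back-solved from a published baseline BAF).
#' @return A `trophic_level_params` list.
#' @export
trophic_level_params <- function(level, f_l, fcm, bcf = NA_real_) {
  stopifnot(level %in% 2:4, f_l > 0, f_l < 1, fcm >= 1,
            is.na(bcf) || bcf > 0)
  structure(list(level = as.integer(level), f_l = f_l, fcm = fcm,
                 bcf = bcf), class = "trophic_level_params")
}

#' Baseline bioaccumulation factor
#'
#' Lipid- and freely-dissolved-normalized BAF for a trophic level:
#' \deqn{BL\_BAF = FCM \cdot \left(\frac{BCF}{f_{fd}} - 1\right) \cdot
#'   \frac{1}{f_l}}
#'
#' @param tl A [trophic_level_params()] with a finite `bcf`.
#' @param f_fd Freely dissolved fraction in (0, 1].
#' @return Baseline BAF, L/kg.
#' @export
baseline_baf <- function(tl, f_fd) {
  stopifnot(f_fd > 0, f_fd <= 1, is.finite(tl$bcf))
  if (tl$bcf / f_fd <= 1) {
    stop("BCF/f_fd must exceed 1; baseline BAF would be non-positive")
  }
  tl$fcm * (tl$bcf / f_fd - 1) / tl$f_l
}

#' Back-solve a BCF from a published baseline BAF
#'
#' Inverts [baseline_baf()]: `BCF = f_fd * (BL_BAF * f_l / FCM + 1)`.
#' A single chemical-specific BCF obtained this way from one trophic
#' level should reproduce the baseline BAFs of the other levels.
#'
#' @param bl_baf Baseline BAF, L/kg.
#' @param tl A [trophic_level_params()].
#' @param f_fd Freely dissolved fraction.
#' @return The implied BCF, L/kg.
#' @export
solve_bcf_from_baseline <- function(bl_baf, tl, f_fd) {
  stopifnot(bl_baf > 0, f_fd > 0, f_fd <= 1)
  f_fd * (bl_baf * tl$f_l / tl$fcm + 1)
}

#' Final trophic-level bioaccumulation factor
#'
#' Converts a baseline BAF back to a wet-weight, total-water basis:
#' \deqn{F\_BAF = (BL\_BAF \cdot f_l + 1) \cdot f_{fd}}
#'
#' @param bl_baf Baseline BAF, L/kg, >= 0.
#' @param tl A [trophic_level_params()] providing the lipid fraction.
#' @param f_fd Freely dissolved fraction.
#' @return Final BAF, L/kg; always >= `f_fd`.
#' @export
final_baf <- function(bl_baf, tl, f_fd) {
  stopifnot(bl_baf >= 0, f_fd > 0, f_fd <= 1)
  (bl_baf * tl$f_l + 1) * f_fd
}

#' Exposure parameters for criteria derivation
#'
#' @param bw Adult body weight, kg.
#' @param di Drinking water intake, L/d.
#' @param fi Named or ordered numeric vector of aquatic-product intake
#'   (kg/d) for trophic levels 2, 3, 4.
#' @param rsc Relative source contribution in (0, 1]; the fraction of the
#'   RfD allocated to waterborne exposure (0.2 default in guideline
#'   practice).
#' @return An `exposure_params` list.
#' @export
exposure_params <- function(bw, di, fi, rsc) {
  stopifnot(bw > 0, di > 0, length(fi) == 3L, all(fi >= 0),
            rsc > 0, rsc <= 1)
  structure(list(bw = bw, di = di, fi = setNames(as.numeric(fi), 2:4),
                 rsc = rsc), class = "exposure_params")
}

#' Human health ambient water quality criterion
#'
#' Aggregates drinking-water and fish-consumption exposure routes:
#' \deqn{AWQC = \frac{RfD \cdot RSC \cdot BW}{DI + \sum_{i=2}^{4}
#'   FI_i \cdot BAF_i}}
#' Numerator mg/d, denominator L/d, quotient mg/L; the adopted value is
#' converted to ug/L and rounded to `report_sig_figs` significant
#' figures (one, by regulatory convention).
#'
#' @param rfd Reference dose, mg/kg/d (rounded or unrounded at the
#'   caller's discretion; published criteria mix both).
#' @param exposure An [exposure_params()].
#' @param bafs Numeric vector of final BAFs (L/kg) for trophic levels
#'   2, 3, 4.
#' @param report_sig_figs Significant figures for the adopted ug/L value.
#' @return List with `awqc_mg_per_L` (exact) and `awqc_ug_per_L_adopted`.
#' @export
derive_awqc <- function(rfd, exposure, bafs, report_sig_figs = 1L) {
  stopifnot(rfd > 0, inherits(exposure, "exposure_params"),
            length(bafs) == 3L, all(bafs >= 0), report_sig_figs >= 1L)
  mg_per_L <- rfd * exposure$rsc * exposure$bw /
    (exposure$di + sum(exposure$fi * bafs))
  list(awqc_mg_per_L = mg_per_L,
       awqc_ug_per_L_adopted = signif(mg_per_L * 1000, report_sig_figs))
}

#' Full criteria derivation for one chemical from a parameter list
#'
#' Convenience wrapper running the whole Kow -> f_fd -> baseline BAF ->
#' final BAF -> AWQC chain from a nested parameter list, typically read
#' from a YAML/JSON file (see `inst/extdata` for worked fixtures).
#'
#' The list needs: `chemical` (`id`, `lg_kow`, `rfd`), `water` (`poc` and
#' `doc`, or a published `f_fd` directly when the water chemistry is
#' unknown), `trophic_levels` (per level: `f_l`, `fcm`, and `bcf` or
#' `bl_baf`), `exposure` (`bw`, `di`, `fi2`, `fi3`, `fi4`, `rsc`).
#'
#' @param params Nested parameter list.
#' @param report_sig_figs Significant figures for the adopted criterion.
#' @return List with `chem_id`, `f_fd`, a per-level data frame `bafs`
#'   (`level`, `bl_baf`, `f_baf`), `awqc_mg_per_L`,
#'   `awqc_ug_per_L_adopted`.
#' @export
derive_criteria <- function(params, report_sig_figs = 1L) {
  ch <- params$chemical
  f_fd <- if (!is.null(params$water$f_fd)) params$water$f_fd else
    free_dissolved_fraction(ch$lg_kow, params$water$poc, params$water$doc)
  rows <- lapply(params$trophic_levels, function(tlp) {
    tl <- trophic_level_params(tlp$level, tlp$f_l, tlp$fcm,
                               tlp$bcf %||% NA_real_)
    bl <- if (!is.null(tlp$bl_baf)) tlp$bl_baf else baseline_baf(tl, f_fd)
    data.frame(level = tl$level, bl_baf = bl,
               f_baf = final_baf(bl, tl, f_fd))
  })
  bafs <- do.call(rbind, rows)
  bafs <- bafs[order(bafs$level), , drop = FALSE]
  stopifnot(identical(bafs$level, 2:4))
  ex <- params$exposure
  awqc <- derive_awqc(ch$rfd,
                      exposure_params(ex$bw, ex$di,
                                      c(ex$fi2, ex$fi3, ex$fi4), ex$rsc),
                      bafs$f_baf, report_sig_figs)
  c(list(chem_id = ch$id, f_fd = f_fd, bafs = bafs), awqc)
}
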