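#' The published 12-descriptor reference-dose model
#'
#' Returns the reported stepwise MLR equation for pesticide-class
#' chemicals as a ready-to-use `mlr_model`:
#'
#' \deqn{-\log_{10} RfD = 1.468 - 0.483\,Ui + 0.361\,ATS1m - 0.195\,MAXDP
#'   + 0.265\,xp9 - 0.312\,SdssC\_acnt + 1.516\,ssi - 0.108\,SHHBd
#'   - 0.559\,MATS8e - 1.162\,MATS2m + 0.76\,MATS2e
#'   + 0.097\,SsssCH\_acnt + 0.108\,piPC08}
#'
#' Coefficients are stored exactly as printed (three decimals; MATS2e as
#' 0.76) and apply to raw, unstandardized descriptor values as produced
#' by the T.E.S.T. descriptor generator. Descriptors: Ui unsaturation
#' index; ATS1m Broto-Moreau autocorrelation lag 1 (mass-weighted);
#' MAXDP maximal electrotopological positive variation; xp9 9th-order
#' path chi index; SdssC_acnt count of =C<; ssi standardized Shannon
#' information; SHHBd E-state sum for H-bond donors; MATS8e / MATS2m /
#' MATS2e Moran autocorrelations; SsssCH_acnt count of >CH-; piPC08
#' multiple path count of order 8.
#'
#' @return An `mlr_model` with intercept 1.468 and the 12 printed slopes.
#' @examples
#' m <- published_rfd_model()
#' predict_neg_log_rfd(m, setNames(rep(0, 12), names(m$coefficients)))
#' @export
published_rfd_model <- function() {
  coefs <- c(
    Ui = -0.483, ATS1m = 0.361, MAXDP = -0.195, xp9 = 0.265,
    SdssC_acnt = -0.312, ssi = 1.516, SHHBd = -0.108, MATS8e = -0.559,
    MATS2m = -1.162, MATS2e = 0.76, SsssCH_acnt = 0.097, piPC08 = 0.108
  )
  structure(list(intercept = 1.468, coefficients = coefs,
                 n_train = 80L, residuals = numeric(), fitted = numeric(),
                 t_values = setNames(rep(NA_real_, 12L), names(coefs))),
            class = "mlr_model")
}
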