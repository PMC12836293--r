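# Radiobiological models: linear-quadratic fractionation correction,
# generalized equivalent uniform dose, and the four organ-specific NTCP
# models (LKB probit for hippocampus and scalp, a multivariate parametric
# endocrine model, and a logistic cochlear model), plus the Niemierko
# EUD/TCP pair for the target.
#
# All models are forward-evaluation only; parameters ship in a YAML
# registry (inst/extdata/ntcp_params.yaml) keyed by organ.

#' Fractionation scheme
#'
#' @param n_fractions number of (equal) fractions.
#' @param alpha_beta_Gy tissue alpha/beta ratio (Gy).
#' @return An object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(n_fractions, alpha_beta_Gy) {
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (alpha_beta_Gy <= 0) stop("alpha/beta must be > 0")
  structure(list(n_fractions = as.integer(n_fractions),
                 alpha_beta_Gy = alpha_beta_Gy),
            class = "fractionation_scheme")
}

#' Equivalent dose in 2-Gy fractions
#'
#' Linear-quadratic conversion: with per-fraction dose `d = D / n`,
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`. When d = 2 Gy the
#' conversion is the identity.
#'
#' @param total_dose_Gy total physical dose (Gy), delivered in
#'   `scheme$n_fractions` equal fractions. Vectorised.
#' @param scheme a [fractionation_scheme()].
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(total_dose_Gy, scheme) {
  if (any(total_dose_Gy < 0)) stop("dose must be >= 0")
  d <- total_dose_Gy / scheme$n_fractions
  total_dose_Gy * (d + scheme$alpha_beta_Gy) / (2 + scheme$alpha_beta_Gy)
}

#' Generalized equivalent uniform dose
#'
#' `gEUD = (sum_i v_i * D_i^(1/n))^n` over the differential dose
#' distribution, with relative subvolumes `v_i` summing to 1. `n = 1`
#' gives the mean dose; small positive `n` approaches the maximum dose;
#' negative `n` (tumor convention, `n = 1/a` with a < 0) approaches the
#' minimum dose.
#'
#' @param dvh a `dvh` (equal-volume voxel sample), or a numeric vector of
#'   doses interpreted as equal subvolumes.
#' @param n volume-effect exponent; must be non-zero (use `D_max`/`D_min`
#'   limits explicitly instead of n = 0).
#' @return gEUD in Gy.
#' @export
geud <- function(dvh, n) {
  if (n == 0) stop("n = 0 is not defined; use the max-dose limit explicitly")
  d <- if (inherits(dvh, "dvh")) dvh$doses else as.numeric(dvh)
  if (any(d < 0)) stop("doses must be >= 0")
  if (n < 0 && any(d == 0))
    stop("gEUD with negative n is undefined when any subvolume has zero dose")
  mean(d^(1 / n))^n
}

#' Lyman-Kutcher-Burman NTCP
#'
#' Probit dose-response: `NTCP = Phi((D_eff - TD50) / (m * TD50))` with
#' `Phi` the standard normal CDF. `D_eff` is the model's effective dose
#' (gEUD, or EQD2(D40%) for the hippocampal model).
#'
#' @param effective_dose_Gy effective dose (Gy). Vectorised.
#' @param TD50_Gy tolerance dose for 50% complication risk.
#' @param m slope parameter.
#' @return complication probability in \[0, 1\].
#' @export
lkb_ntcp <- function(effective_dose_Gy, TD50_Gy, m) {
  if (TD50_Gy <= 0) stop("TD50 must be > 0")
  if (m <= 0) stop("m must be > 0")
  if (any(effective_dose_Gy < 0)) stop("effective dose must be >= 0")
  stats::pnorm((effective_dose_Gy - TD50_Gy) / (m * TD50_Gy))
}

#' Hippocampal neurocognitive-impairment NTCP
#'
#' LKB probit with the EQD2 of the dose to 40% of the hippocampal volume
#' in place of gEUD; defaults TD50 = 14.88 Gy, m = 0.54, alpha/beta = 2.
#'
#' @param d40_total_Gy hippocampal D40% as a total physical dose (Gy).
#' @param scheme a [fractionation_scheme()]; default 13 fractions,
#'   alpha/beta = 2.
#' @param TD50_Gy,m LKB parameters.
#' @return probability of neurocognitive impairment.
#' @export
hippocampal_ntcp <- function(d40_total_Gy,
                             scheme = fractionation_scheme(13, 2),
                             TD50_Gy = 14.88, m = 0.54) {
  lkb_ntcp(eqd2(d40_total_Gy, scheme), TD50_Gy, m)
}

#' Scalp acute grade-2 alopecia NTCP
#'
#' LKB probit on the scalp gEUD with volume exponent n = 0.14;
#' defaults TD50 = 22 Gy, m = 0.54.
#'
#' @param dvh scalp `dvh`, or a precomputed gEUD via `geud_Gy`.
#' @param TD50_Gy,m,n model parameters.
#' @param geud_Gy optional: bypass the DVH and supply gEUD directly.
#' @return probability of acute grade-2 alopecia.
#' @export
scalp_ntcp <- function(dvh = NULL, TD50_Gy = 22, m = 0.54, n = 0.14,
                       geud_Gy = NULL) {
  eff <- if (!is.null(geud_Gy)) geud_Gy else geud(dvh, n)
  lkb_ntcp(eff, TD50_Gy, m)
}

#' Endocrine-dysfunction NTCP (hypothalamic-pituitary axis)
#'
#' Multivariate parametric model in dose, age and follow-up time:
#' `phi = exp(-(const + b_age*age + b_age2*age^2 + b_dose*dose))`,
#' `NTCP = 1 - 1 / (1 + (phi * t)^(1/gamma))`, where `dose` is the mean
#' of the hypothalamic and pituitary D50% values. Defaults: gamma = 0.56,
#' const = 3.13, b_age = -0.106, b_age2 = 0.007, b_dose = -0.049,
#' t = 5 years.
#'
#' @param hypothalamus_d50_Gy,pituitary_d50_Gy median doses (Gy).
#' @param age_years age at treatment (years, continuous).
#' @param gamma,const,beta_age,beta_age2,beta_dose model coefficients.
#' @param t_years post-treatment follow-up time (years).
#' @return probability of endocrine dysfunction at `t_years`.
#' @export
endocrine_ntcp <- function(hypothalamus_d50_Gy, pituitary_d50_Gy, age_years,
                           gamma = 0.56, const = 3.13, beta_age = -0.106,
                           beta_age2 = 0.007, beta_dose = -0.049,
                           t_years = 5) {
  if (t_years < 0) stop("follow-up time must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(c(hypothalamus_d50_Gy, pituitary_d50_Gy) < 0))
    stop("doses must be >= 0")
  if (age_years <= 0) stop("age must be > 0")
  dose <- (hypothalamus_d50_Gy + pituitary_d50_Gy) / 2
  phi <- exp(-(const + beta_age * age_years + beta_age2 * age_years^2 +
                 beta_dose * dose))
  1 - 1 / (1 + (phi * t_years)^(1 / gamma))
}

#' Cochlear hearing-loss NTCP
#'
#' Logistic model on the median cochlear dose:
#' `NTCP = exp(b0 + b1*dose) / (1 + exp(b0 + b1*dose))`;
#' defaults b0 = -5.3, b1 = 0.085.
#'
#' @param median_dose_Gy median cochlear dose (Gy). Vectorised.
#' @param b0,b1 logistic coefficients.
#' @return probability of hearing loss.
#' @export
cochlear_ntcp <- function(median_dose_Gy, b0 = -5.3, b1 = 0.085) {
  if (any(median_dose_Gy < 0)) stop("dose must be >= 0")
  stats::plogis(b0 + b1 * median_dose_Gy)
}

#' Target EUD and tumor control probability
#'
#' EUD of the target via [geud()] with tumor exponent `a` (`n = 1/a`);
#' TCP by the Niemierko logistic form
#' `TCP = 1 / (1 + (TCD50/EUD)^(4*gamma50))`.
#'
#' There is no single published parameter set for pediatric
#' medulloblastoma; values must be supplied explicitly or through the
#' registry (the shipped registry carries illustrative defaults that are
#' documented as such).
#'
#' @param dvh target `dvh`.
#' @param eud_exponent_a tumor gEUD exponent (negative; min-dose weighted).
#' @param TCD50_Gy dose giving 50% control.
#' @param gamma50 normalized slope at TCD50.
#' @return list with `EUD_Gy` and `TCP`.
#' @export
ptv_eud_tcp <- function(dvh, eud_exponent_a = NULL, TCD50_Gy = NULL,
                        gamma50 = NULL) {
  if (is.null(eud_exponent_a) || is.null(TCD50_Gy) || is.null(gamma50))
    stop(paste("TCP parameters are not built in: supply eud_exponent_a,",
               "TCD50_Gy and gamma50 (e.g. from the 'tcp' entry of",
               "load_ntcp_registry())"))
  if (TCD50_Gy <= 0) stop("TCD50 must be > 0")
  eud <- geud(dvh, 1 / eud_exponent_a)
  list(EUD_Gy = eud, TCP = 1 / (1 + (TCD50_Gy / eud)^(4 * gamma50)))
}

#' Load the NTCP model-parameter registry
#'
#' Reads a YAML registry keyed by organ; the shipped default carries the
#' LKB hippocampus and scalp parameter sets, the endocrine multivariate
#' model coefficients, the cochlear logistic coefficients, and an
#' illustrative target EUD/TCP set.
#'
#' @param path YAML file; defaults to the registry shipped with the
#'   package.
#' @return named list of per-organ parameter lists.
#' @export
load_ntcp_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ntcp_params.yaml", package = "csieval")
  if (!nzchar(path) || !file.exists(path))
    stop("NTCP parameter registry not found: ", path)
  yaml::read_yaml(path)
}
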