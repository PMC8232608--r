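# RBE and OER endpoints: yield-ratio RBE for (enzymatic) DSB induction,
# isoeffect dose solving under the LQ model, survival-level RBE, and the
# oxygen enhancement ratio.

#' RBE for DSB induction
#'
#' DSB induction is linear in dose, so the RBE at this endpoint is the ratio
#' of DSB yields, test radiation over reference:
#' \eqn{\mathrm{RBE} = D_\gamma / D_P = \Sigma_P / \Sigma_\gamma}.
#' Units cancel; per-Gbp and per-cell yields are both accepted as long as the
#' two arguments match.
#'
#' @param sigma_test DSB yield of the test radiation (>= 0).
#' @param sigma_ref DSB yield of the reference radiation (> 0), cobalt-60
#'   gamma-rays throughout the packaged tables.
#' @return The RBE (dimensionless); vectorised over `sigma_test`.
#' @examples
#' rbe_dsb(12.4, 8.14)    # Bragg-peak distal position, 21% O2
#' @export
rbe_dsb <- function(sigma_test, sigma_ref) {
  if (any(sigma_ref <= 0))
    stop("'sigma_ref' must be > 0", call. = FALSE)
  sigma_test / sigma_ref
}

#' RBE for enzymatic DSB
#'
#' Ratio of enzymatic-DSB yields, test over reference (6.00 per Gy per Gbp
#' for the packaged cobalt-60 reference).
#'
#' @param enzymatic_yield Enzymatic-DSB yield of the test radiation.
#' @param reference_yield Enzymatic-DSB yield of the reference (> 0).
#' @return The RBE (dimensionless).
#' @export
rbe_enzymatic <- function(enzymatic_yield, reference_yield) {
  if (any(reference_yield <= 0))
    stop("'reference_yield' must be > 0", call. = FALSE)
  enzymatic_yield / reference_yield
}

#' Dose producing a given survival level
#'
#' Solves \eqn{\alpha D + \beta D^2 = -\ln S} for the unique non-negative
#' root:
#' \deqn{D = \frac{-\alpha + \sqrt{\alpha^2 - 4\beta \ln S}}{2\beta},}
#' with the linear limit \eqn{D = -\ln S / \alpha} at \eqn{\beta = 0}.
#'
#' @param coeffs An [lq_coefficients()] object with `alpha + beta > 0`.
#' @param S Target surviving fraction in (0, 1].
#' @return Dose in Gy (0 at S = 1).
#' @export
dose_for_survival <- function(coeffs, S) {
  if (any(S <= 0) || any(S > 1))
    stop("'S' must be in (0, 1]", call. = FALSE)
  alpha <- coeffs$alpha
  beta <- coeffs$beta
  if (alpha + beta <= 0)
    stop("no solution: alpha and beta are both zero", call. = FALSE)
  effect <- -log(S)
  if (beta == 0) return(effect / alpha)
  (-alpha + sqrt(alpha^2 + 4 * beta * effect)) / (2 * beta)
}

#' RBE for cell survival at a given proton dose
#'
#' The ratio \eqn{D_\gamma / D_P} where \eqn{D_\gamma} is the reference dose
#' producing the same LQ effect as dose `dose_test` of the test radiation:
#' \deqn{\mathrm{RBE} = \frac{\sqrt{\alpha_\gamma^2 + 4\beta_\gamma D_P
#'   (\alpha_P + \beta_P D_P)} - \alpha_\gamma}{2 \beta_\gamma D_P},}
#' with the analytic limit \eqn{(\alpha_P D_P + \beta_P D_P^2) /
#' (\alpha_\gamma D_P)} when \eqn{\beta_\gamma = 0}.
#'
#' @param ref_coeffs Reference-radiation [lq_coefficients()]
#'   (`alpha + beta > 0`).
#' @param test_coeffs Test-radiation [lq_coefficients()].
#' @param dose_test Test-radiation dose in Gy (> 0).
#' @return The RBE (dimensionless).
#' @export
rbe_survival <- function(ref_coeffs, test_coeffs, dose_test) {
  if (any(dose_test <= 0))
    stop("'dose_test' must be > 0 (Gy)", call. = FALSE)
  ag <- ref_coeffs$alpha
  bg <- ref_coeffs$beta
  if (ag + bg <= 0)
    stop("reference coefficients are degenerate", call. = FALSE)
  effect <- test_coeffs$alpha * dose_test + test_coeffs$beta * dose_test^2
  if (bg == 0) return(effect / (ag * dose_test))
  (sqrt(ag^2 + 4 * bg * effect) - ag) / (2 * bg * dose_test)
}

#' RBE for cell survival at an isoeffect survival level
#'
#' Solves the test-radiation dose reaching survival `S`, then forms
#' \eqn{D_\gamma(S) / D_P(S)}.
#'
#' @inheritParams rbe_survival
#' @param S Survival level in (0, 1), e.g. 0.1.
#' @return The RBE (dimensionless).
#' @export
rbe_survival_iso <- function(ref_coeffs, test_coeffs, S = 0.1) {
  if (any(S <= 0) || any(S >= 1))
    stop("'S' must be in (0, 1)", call. = FALSE)
  dose_for_survival(ref_coeffs, S) / dose_for_survival(test_coeffs, S)
}

#' Oxygen enhancement ratio for cell survival
#'
#' The ratio of the hypoxic to the aerobic dose reaching the same survival
#' level: \eqn{\mathrm{OER} = D_h / D_a} with each dose the non-negative LQ
#' root for its coefficient set.
#'
#' @param aerobic [lq_coefficients()] under the aerobic condition.
#' @param hypoxic [lq_coefficients()] under hypoxia.
#' @param S Survival level in (0, 1); default 0.1.
#' @return An `oer_result` object: list with `value`, `S`, `dose_aerobic`,
#'   `dose_hypoxic`.
#' @export
oer_survival <- function(aerobic, hypoxic, S = 0.1) {
  if (any(S <= 0) || any(S >= 1))
    stop("'S' must be in (0, 1)", call. = FALSE)
  d_a <- dose_for_survival(aerobic, S)
  d_h <- dose_for_survival(hypoxic, S)
  structure(
    list(value = d_h / d_a, S = S, dose_aerobic = d_a, dose_hypoxic = d_h),
    class = "oer_result"
  )
}

#' @export
print.oer_result <- function(x, ...) {
  cat("<oer_result> OER = ", signif(x$value, 4), " at S = ", x$S,
      " (D_a = ", signif(x$dose_aerobic, 4), " Gy, D_h = ",
      signif(x$dose_hypoxic, 4), " Gy)\n", sep = "")
  invisible(x)
}

#' OER for DSB induction
#'
#' DSB induction is linear in dose, so the OER at this endpoint is the ratio
#' of the aerobic to the hypoxic yield at matched dose.
#'
#' @param sigma_aerobic,sigma_hypoxic DSB yields under the two conditions
#'   (same units; hypoxic > 0).
#' @return The OER (dimensionless).
#' @export
oer_dsb <- function(sigma_aerobic, sigma_hypoxic) {
  if (any(sigma_hypoxic <= 0))
    stop("'sigma_hypoxic' must be > 0", call. = FALSE)
  sigma_aerobic / sigma_hypoxic
}
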