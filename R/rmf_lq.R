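# Repair-misrepair-fixation (RMF) model core: rejoinable fraction,
# frequency-mean specific energy, and the mapping from DSB yield to
# linear-quadratic survival coefficients.
#
# alpha = [1 - f_R (1 - theta)] Sigma + kappa zF (f_R Sigma)^2   (Gy^-1)
# beta  = (kappa / 2) (f_R Sigma)^2                              (Gy^-2)
#
# with Sigma the DSB yield per cell per Gy, f_R the fraction of initial DSBs
# that are potentially rejoinable, theta the fraction undergoing lethal
# first-order misrepair/fixation, kappa the fraction undergoing pairwise
# interactions, and zF the frequency-mean specific energy. At f_R = 1 alpha
# reduces to the standard RMF form theta*Sigma + kappa*zF*Sigma^2.

#' RMF model parameters
#'
#' Packaged sets (see [fixture_rmf_parameters()]): theta = 5.79e-3 and
#' kappa = 5.59e-5 with j = 9 at 21% O2 (j = 8 at 2% O2); theta = 4.1e-3,
#' kappa = 3e-5, j = 7 under severe hypoxia (0.1% O2). Nuclear diameter 8 um
#' (a typical V79 nucleus) and 6 Gbp per mammalian cell.
#'
#' @param theta Fraction of DSBs undergoing lethal first-order misrepair and
#'   damage fixation (>= 0).
#' @param kappa Fraction of initial DSBs undergoing pairwise damage
#'   interactions (>= 0).
#' @param j Least lesion multiplicity per DSB that cannot be rejoined
#'   (integer >= 2).
#' @param nuclear_diameter Nuclear diameter in micrometres (> 0).
#' @param genome_gbp Genome size per cell in Gbp (> 0), used to convert
#'   per-Gbp yields to per-cell yields.
#' @return An `rmf_parameters` object (list).
#' @export
rmf_parameters <- function(theta, kappa, j, nuclear_diameter = 8,
                           genome_gbp = 6) {
  if (theta < 0 || kappa < 0)
    stop("'theta' and 'kappa' must be >= 0", call. = FALSE)
  if (j < 2 || j != floor(j))
    stop("'j' must be an integer >= 2", call. = FALSE)
  if (nuclear_diameter <= 0)
    stop("'nuclear_diameter' must be > 0 (um)", call. = FALSE)
  if (genome_gbp <= 0)
    stop("'genome_gbp' must be > 0", call. = FALSE)
  structure(
    list(theta = theta, kappa = kappa, j = as.integer(j),
         nuclear_diameter = nuclear_diameter, genome_gbp = genome_gbp),
    class = "rmf_parameters"
  )
}

#' Rejoinable fraction of initial DSBs
#'
#' The fraction of DSBs with lesion multiplicity below the rejoining cutoff:
#' \deqn{f_R = \frac{1}{\Sigma} \sum_{i=2}^{j-1} \Sigma_i}
#' where \eqn{\Sigma_i} is the yield of DSBs composed of exactly \eqn{i}
#' lesions and \eqn{\Sigma = \sum_i \Sigma_i}.
#'
#' @param sigma_i Named numeric vector; names = multiplicity \eqn{i} (>= 2),
#'   values = per-multiplicity DSB yields with positive total.
#' @param j Rejoining cutoff (integer >= 2); DSBs with \eqn{i \ge j} cannot
#'   be rejoined.
#' @return The rejoinable fraction in \[0, 1\].
#' @examples
#' rejoinable_fraction(c("2" = 50, "9" = 50), j = 9)    # 0.5
#' rejoinable_fraction(c("2" = 50, "9" = 50), j = 10)   # 1
#' @export
rejoinable_fraction <- function(sigma_i, j) {
  if (length(sigma_i) == 0L || is.null(names(sigma_i)))
    stop("'sigma_i' must be a named vector of per-multiplicity DSB yields",
         call. = FALSE)
  i <- as.numeric(names(sigma_i))
  if (any(is.na(i)) || any(i < 2))
    stop("multiplicities must be numeric and >= 2", call. = FALSE)
  if (j < 2) stop("'j' must be >= 2", call. = FALSE)
  total <- sum(sigma_i)
  if (total <= 0)
    stop("total DSB yield must be > 0", call. = FALSE)
  sum(sigma_i[i <= j - 1]) / total
}

#' Frequency-mean specific energy of single events
#'
#' For a spherical water target of diameter `d` (micrometres) crossed by a
#' track of the given LET (keV/um):
#' \deqn{\bar z_F = 0.204 \, \mathrm{LET} / d^2 \quad (\mathrm{Gy}).}
#'
#' @param let Linear energy transfer in keV/um (>= 0).
#' @param d Target (nuclear) diameter in micrometres (> 0); default 8.
#' @return Specific energy in Gy.
#' @examples
#' specific_energy(2.4, 8)    # 0.00765 Gy (cobalt-60 reference)
#' @export
specific_energy <- function(let, d = 8) {
  if (d <= 0) stop("'d' must be > 0 (um)", call. = FALSE)
  if (any(let < 0)) stop("'let' must be >= 0", call. = FALSE)
  0.204 * let / d^2
}

#' Linear-quadratic coefficients
#'
#' @param alpha Linear coefficient in 1/Gy (>= 0).
#' @param beta Quadratic coefficient in 1/Gy^2 (>= 0).
#' @return An `lq_coefficients` object (list).
#' @export
lq_coefficients <- function(alpha, beta) {
  if (alpha < 0 || beta < 0)
    stop("'alpha' and 'beta' must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "lq_coefficients")
}

#' @export
print.lq_coefficients <- function(x, ...) {
  cat("<lq_coefficients> alpha = ", signif(x$alpha, 4), " Gy^-1, beta = ",
      signif(x$beta, 4), " Gy^-2, alpha/beta = ",
      signif(x$alpha / x$beta, 4), " Gy\n", sep = "")
  invisible(x)
}

#' RMF linear coefficient alpha
#'
#' `form = "fixation"` (default) uses
#' \eqn{\alpha = [1 - f_R(1-\theta)]\Sigma + \kappa \bar z_F (f_R \Sigma)^2},
#' in which unrejoinable DSBs (fraction \eqn{1 - f_R}) are lethal at first
#' order. `form = "rmf"` is the classic limit \eqn{\theta\Sigma + \kappa \bar
#' z_F \Sigma^2}, identical to the default at \eqn{f_R = 1}.
#'
#' @param sigma DSB yield per cell per Gy (>= 0).
#' @param f_R Rejoinable fraction in \[0, 1\].
#' @param params An [rmf_parameters()] object.
#' @param z_F Frequency-mean specific energy in Gy; see [specific_energy()].
#' @param form Strategy for the alpha expression; see Details.
#' @return alpha in 1/Gy.
#' @export
lq_alpha <- function(sigma, f_R, params, z_F, form = c("fixation", "rmf")) {
  form <- match.arg(form)
  if (sigma < 0 || z_F < 0)
    stop("'sigma' and 'z_F' must be >= 0", call. = FALSE)
  if (f_R < 0 || f_R > 1)
    stop("'f_R' must be in [0, 1]", call. = FALSE)
  if (form == "rmf")
    return(params$theta * sigma + params$kappa * z_F * sigma^2)
  (1 - f_R * (1 - params$theta)) * sigma +
    params$kappa * z_F * (f_R * sigma)^2
}

#' RMF quadratic coefficient beta
#'
#' \eqn{\beta = (\kappa / 2)(f_R \Sigma)^2}.
#'
#' @inheritParams lq_alpha
#' @param kappa Pairwise-interaction fraction (>= 0).
#' @return beta in 1/Gy^2.
#' @export
lq_beta <- function(sigma, f_R, kappa) {
  if (sigma < 0 || kappa < 0)
    stop("'sigma' and 'kappa' must be >= 0", call. = FALSE)
  if (f_R < 0 || f_R > 1)
    stop("'f_R' must be in [0, 1]", call. = FALSE)
  (kappa / 2) * (f_R * sigma)^2
}

#' RMF linear-quadratic coefficients from a DSB yield
#'
#' Convenience wrapper: converts a per-Gbp DSB induction yield to per-cell
#' units with the genome size in `params`, evaluates the specific energy from
#' the LET and nuclear diameter, and returns both coefficients.
#'
#' @param dsb_yield_gbp DSB induction yield per Gy per Gbp.
#' @param let LET in keV/um.
#' @param params An [rmf_parameters()] object.
#' @param f_R Rejoinable fraction; defaults to the `f_R` attribute of
#'   `params` when present (as set by [fixture_rmf_parameters()]), else 1.
#' @param form Passed to [lq_alpha()].
#' @return An [lq_coefficients()] object.
#' @export
rmf_lq_coefficients <- function(dsb_yield_gbp, let, params, f_R = NULL,
                                form = "fixation") {
  if (is.null(f_R)) {
    f_R <- attr(params, "f_R")
    if (is.null(f_R)) f_R <- 1
  }
  sigma <- dsb_yield_gbp * params$genome_gbp
  z_F <- specific_energy(let, params$nuclear_diameter)
  lq_coefficients(
    alpha = lq_alpha(sigma, f_R, params, z_F, form = form),
    beta = lq_beta(sigma, f_R, params$kappa)
  )
}

#' Linear-quadratic survival fraction
#'
#' \eqn{S = \exp(-(\alpha D + \beta D^2))}.
#'
#' @param coeffs An [lq_coefficients()] object.
#' @param dose Absorbed dose in Gy (>= 0); vectorised.
#' @return Surviving fraction in (0, 1].
#' @export
survival_fraction <- function(coeffs, dose) {
  if (any(dose < 0)) stop("'dose' must be >= 0 (Gy)", call. = FALSE)
  exp(-(coeffs$alpha * dose + coeffs$beta * dose^2))
}
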