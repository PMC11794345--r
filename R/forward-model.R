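#' Diffuse reflectance in the spatial frequency domain
#'
#' Closed-form diffusion-approximation forward model for the diffuse
#' reflectance of a semi-infinite homogeneous turbid medium illuminated by a
#' sinusoidal pattern of spatial frequency `fx`. This is the forward model
#' behind both the scene renderer and the look-up-table inversion.
#'
#' With transport coefficient \eqn{\mu_{tr} = \mu_a + \mu_s'}, reduced albedo
#' \eqn{a' = \mu_s'/\mu_{tr}} and the frequency-dependent effective
#' attenuation \eqn{\mu_{eff}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}},
#' the reflectance is
#' \deqn{R_d = \frac{3Aa'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' where \eqn{A} is the internal-reflection parameter obtained from the
#' Groenhuis polynomial approximation of the effective Fresnel reflection
#' coefficient, \eqn{R_{eff} \approx 0.0636 n + 0.668 + 0.710/n - 1.440/n^2}.
#'
#' The model is smooth, strictly decreasing in `mu_a` and in `fx`, and
#' strictly increasing in `mu_s_prime` over the tissue-like range
#' (\eqn{\mu_a} 0.005--0.05 mm\eqn{^{-1}}, \eqn{\mu_s'} 0.5--3
#' mm\eqn{^{-1}}), which guarantees invertibility of tables built from it.
#'
#' @param mu_a absorption coefficient, mm^-1 (scalar, vector or matrix; > 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0), recycled
#'   against `mu_a`.
#' @param fx spatial frequency of the illumination pattern, mm^-1 (>= 0).
#' @param n refractive index of the medium (default 1.4, soft tissue).
#' @return Diffuse reflectance in (0, 1), same shape as `mu_a`.
#' @examples
#' diffuse_reflectance_forward(0.01, 1.0, 0)
#' diffuse_reflectance_forward(0.01, 1.0, 0.2)
#' @export
diffuse_reflectance_forward <- function(mu_a, mu_s_prime, fx, n = 1.4) {
  if (any(mu_a <= 0, na.rm = TRUE) || any(mu_s_prime <= 0, na.rm = TRUE))
    stop("optical properties must be strictly positive", call. = FALSE)
  if (any(fx < 0)) stop("fx must be >= 0", call. = FALSE)
  mu_tr <- mu_a + mu_s_prime
  a_prime <- mu_s_prime / mu_tr
  mu_eff <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2)
  r_eff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - r_eff) / (2 * (1 + r_eff))
  q <- mu_eff / mu_tr
  3 * A * a_prime / ((q + 1) * (q + 3 * A))
}
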