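# Cromer-Mann 4-Gaussian parameterization of the non-anomalous atomic
# scattering factor f0(s) = sum_i a_i exp(-b_i s^2) + c, s = sin(theta)/lambda
# = |Q|/2 (with |Q| = 1/d). International Tables Vol. C coefficients for the
# small element set bundled with the toy model.
.cm_table <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Mn = list(a = c(11.2819, 7.35730, 3.01930, 2.24410),
            b = c(5.34090, 0.343200, 17.8674, 83.7543), c = 1.08960),
  Fe = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690)
)

#' Elements with bundled form-factor coefficients
#' @return character vector of element symbols.
#' @export
ff_elements <- function() names(.cm_table)

#' Non-anomalous atomic scattering factor f0
#'
#' Evaluates the Cromer-Mann Gaussian-sum parameterization of the
#' wavelength-independent scattering factor at scattering-vector magnitude
#' `q_mag` (convention |Q| = 1/d, so sin(theta)/lambda = |Q|/2). At |Q| = 0
#' the value equals the element's electron count to the accuracy of the
#' parameterization; f0 decreases monotonically with |Q|.
#'
#' @param element element symbol; one of [ff_elements()].
#' @param q_mag scattering-vector magnitude(s) in 1/Angstrom, >= 0.
#' @return f0 in electron units, same length as `q_mag`.
#' @export
eval_f0 <- function(element, q_mag) {
  cf <- .cm_table[[element]]
  if (is.null(cf))
    stop("unknown element '", element, "'; available: ",
         paste(ff_elements(), collapse = ", "))
  if (any(q_mag < 0)) stop("q_mag must be >= 0")
  s2 <- (q_mag / 2)^2
  out <- rep(cf$c, length(q_mag))
  for (i in 1:4) out <- out + cf$a[i] * exp(-cf$b[i] * s2)
  out
}
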