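#' Simulate octanol/water partition measurements
#'
#' Generates \eqn{(pH, K_{ow})} pairs from a ground-truth two-species
#' model with multiplicative lognormal noise:
#' \eqn{K_{ow} = Q(pH)\,e^\varepsilon}, \eqn{\varepsilon \sim
#' N(0, \mathrm{cv}^2)}. Lognormal noise keeps the simulated ratios
#' positive and mimics the multiplicative error structure of
#' chromatographic concentration ratios.
#'
#' @param true_model A `partition_model` holding the ground truth.
#' @param pH_points pH values at which measurements are taken (default:
#'   the two experimental points, pH 2 and 8).
#' @param noise_cv Coefficient of variation of the noise; 0 gives exact
#'   model values.
#' @param seed RNG seed for reproducibility (caller's RNG state is
#'   restored); `NULL` uses the current RNG stream.
#' @return A data frame with columns `pH`, `Kow`.
#' @examples
#' truth <- new_partition_model(2.01, 0.00034, 4.65)
#' simulate_partition_measurements(truth, noise_cv = 0)
#' @export
simulate_partition_measurements <- function(true_model,
                                            pH_points = c(2, 8),
                                            noise_cv = 0, seed = NULL) {
  .check_model(true_model)
  stopifnot(noise_cv >= 0, length(pH_points) >= 1)
  .with_seed(seed, {
    q <- distribution_coefficient(true_model, pH_points)
    eps <- if (noise_cv > 0)
      stats::rnorm(length(pH_points), 0, noise_cv) else 0
    data.frame(pH = pH_points, Kow = q * exp(eps))
  })
}

#' Simulate a PAMPA concentration time course
#'
#' Forward model of passive transfer between a donor and an acceptor
#' well through a membrane of permeability `P_true`:
#' \deqn{C_A(t) = C_{eq}\,\bigl(1 - e^{-P S (1/V_D + 1/V_A) t}\bigr),
#'   \quad C_{eq} = C_0 V_D/(V_D + V_A),}
#' with the donor concentration following from mass balance
#' \eqn{C_0 V_D = C_D V_D + C_A V_A}. The model assumes no membrane
#' retention and no evaporation, so [effective_permeability()] is its
#' exact single-timepoint inverse. Optional additive Gaussian noise
#' (truncated at zero) is applied to both concentrations.
#'
#' @param P_true Ground-truth permeability, cm/s.
#' @param C0 Initial donor concentration, uM.
#' @param VD,VA Donor/acceptor volumes, mL.
#' @param S Filter area, cm^2.
#' @param times Readout times, s (one simulated well per time).
#' @param noise_sd Standard deviation of additive concentration noise,
#'   uM.
#' @param seed RNG seed (caller's RNG state restored); `NULL` uses the
#'   current stream.
#' @param pH Assay pH recorded in the generated wells.
#' @return A data frame of wells with the columns of [pampa_well()].
#' @examples
#' w <- simulate_pampa_timecourse(1.12e-5, C0 = 3700.9)
#' effective_permeability(w)  # recovers 1.12e-5 exactly when noiseless
#' @export
simulate_pampa_timecourse <- function(P_true, C0, VD = 0.2, VA = 0.3,
                                      S = 0.3, times = 18000,
                                      noise_sd = 0, seed = NULL,
                                      pH = 7.4) {
  stopifnot(P_true > 0, C0 > 0, VD > 0, VA > 0, S > 0, all(times > 0),
            noise_sd >= 0)
  .with_seed(seed, {
    ceq <- C0 * VD / (VD + VA)
    kx <- P_true * S * (1 / VD + 1 / VA)
    CA <- ceq * (1 - exp(-kx * times))
    CD <- (C0 * VD - CA * VA) / VD
    if (noise_sd > 0) {
      CA <- pmax(0, CA + stats::rnorm(length(times), 0, noise_sd))
      CD <- pmax(0, CD + stats::rnorm(length(times), 0, noise_sd))
    }
    data.frame(pH = pH, C0 = C0, CD_t = CD, CA_t = CA,
               VD = VD, VA = VA, S = S, t = times)
  })
}
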