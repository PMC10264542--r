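#' Construct a PAMPA well record
#'
#' One row of a parallel artificial membrane permeability assay (PAMPA)
#' plate: donor/acceptor concentrations at readout plus the well
#' geometry. Default geometry matches the standard pre-coated 96-well
#' sandwich used for the azide measurements: donor 0.2 mL, acceptor
#' 0.3 mL, filter area 0.3 cm^2, 5 h (18,000 s) incubation.
#'
#' @param pH Assay pH.
#' @param C0 Initial donor concentration, uM.
#' @param CD_t Donor concentration at readout, uM.
#' @param CA_t Acceptor concentration at readout, uM.
#' @param VD,VA Donor and acceptor volumes, mL (= cm^3).
#' @param S Filter area, cm^2.
#' @param t Incubation time, s.
#' @return A one-row data frame with the eight well columns.
#' @export
pampa_well <- function(pH, C0, CD_t, CA_t, VD = 0.2, VA = 0.3,
                       S = 0.3, t = 18000) {
  w <- data.frame(pH = pH, C0 = C0, CD_t = CD_t, CA_t = CA_t,
                  VD = VD, VA = VA, S = S, t = t)
  .check_wells(w)
  w
}

.check_wells <- function(wells) {
  need <- c("pH", "C0", "CD_t", "CA_t", "VD", "VA", "S", "t")
  if (!is.data.frame(wells) || !all(need %in% names(wells)))
    stop("wells must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(wells$VD <= 0 | wells$VA <= 0 | wells$S <= 0 | wells$t <= 0))
    stop("volumes, filter area and incubation time must all be positive")
  if (any(wells$C0 < 0 | wells$CD_t < 0 | wells$CA_t < 0))
    stop("concentrations must be non-negative")
  invisible(wells)
}

#' Closed-system equilibrium concentration of a PAMPA well
#'
#' The concentration both wells would reach if transfer ran to
#' completion, from the mass present at readout:
#' \eqn{C_{eq} = (C_D V_D + C_A V_A)/(V_D + V_A)}.
#'
#' @param well A well data frame ([pampa_well()] or a full plate); the
#'   computation is vectorized over rows.
#' @return Equilibrium concentration(s), uM.
#' @examples
#' equilibrium_concentration(pampa_well(7.4, 3700.9, 3247.7, 675.5))
#' @export
equilibrium_concentration <- function(well) {
  .check_wells(well)
  (well$CD_t * well$VD + well$CA_t * well$VA) / (well$VD + well$VA)
}

#' Effective permeability from a single-timepoint PAMPA readout
#'
#' Inverts the two-compartment passive-transfer kinetics at one readout
#' time:
#' \deqn{P_e = \frac{-\ln(1 - C_A(t)/C_{eq})}
#'   {S\,(1/V_D + 1/V_A)\,t}}
#' with volumes in mL (= cm^3), area in cm^2 and time in s, so that
#' \eqn{P_e} is in cm/s.
#'
#' @inheritParams equilibrium_concentration
#' @return Effective permeability(ies), cm/s. Zero when `CA_t` is 0.
#' @examples
#' effective_permeability(pampa_well(7.4, 3700.9, 3247.7, 675.5))
#' @export
effective_permeability <- function(well) {
  .check_wells(well)
  ceq <- equilibrium_concentration(well)
  if (any(well$CA_t >= ceq & well$CA_t > 0))
    stop("acceptor concentration at or beyond equilibrium ",
         "(CA_t >= C_eq): the single-timepoint estimator is undefined")
  -log(1 - well$CA_t / ceq) / (well$S * (1 / well$VD + 1 / well$VA) * well$t)
}

#' Mass retention of a PAMPA well
#'
#' Fraction of the initially loaded solute unaccounted for in donor plus
#' acceptor at readout (membrane retention and other losses; negative
#' when the recovered mass exceeds the nominal load):
#' \eqn{1 - (C_D V_D + C_A V_A)/(C_0 V_0)} with \eqn{V_0 = V_D}, the
#' volume the sample was loaded into.
#'
#' @inheritParams equilibrium_concentration
#' @return Retention fraction(s), unitless (not percent).
#' @export
mass_retention <- function(well) {
  .check_wells(well)
  if (any(well$C0 <= 0)) stop("C0 must be positive for mass retention")
  1 - (well$CD_t * well$VD + well$CA_t * well$VA) / (well$C0 * well$VD)
}

#' Analyze a PAMPA plate
#'
#' Computes equilibrium concentration, effective permeability, log10
#' permeability and mass retention for every well, preserving input
#' order. A well whose readout is unusable (acceptor at or past
#' equilibrium) is flagged rather than aborting the plate. Per-pH mean
#' permeabilities over the valid wells are attached as the `"ph_means"`
#' attribute.
#'
#' @param wells A data frame of wells (columns as in [pampa_well()]).
#' @return A data frame of class `pampa_results` with columns `pH`,
#'   `Ceq`, `Pe`, `logPe`, `retention`, `ok`, `note`.
#' @examples
#' plate <- read_pampa_plate(system.file("extdata", "pampa_table2.csv",
#'                                       package = "azperm"))
#' analyze_plate(plate)
#' @export
analyze_plate <- function(wells) {
  .check_wells(wells)
  if (nrow(wells) == 0L) stop("empty plate")
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, , drop = FALSE]
    ceq <- equilibrium_concentration(w)
    res <- tryCatch({
      pe <- effective_permeability(w)
      data.frame(pH = w$pH, Ceq = ceq, Pe = pe, logPe = log10(pe),
                 retention = mass_retention(w), ok = TRUE, note = "")
    }, error = function(e) {
      data.frame(pH = w$pH, Ceq = ceq, Pe = NA_real_, logPe = NA_real_,
                 retention = tryCatch(mass_retention(w),
                                      error = function(e2) NA_real_),
                 ok = FALSE, note = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  okv <- out$ok & is.finite(out$Pe)
  means <- if (any(okv)) {
    agg <- stats::aggregate(Pe ~ pH, data = out[okv, , drop = FALSE], FUN = mean)
    agg$logPe <- log10(agg$Pe)
    agg
  } else data.frame(pH = numeric(), Pe = numeric(), logPe = numeric())
  structure(out, ph_means = means, class = c("pampa_results", "data.frame"))
}

#' @export
print.pampa_results <- function(x, ...) {
  shown <- data.frame(pH = x$pH,
                      `Ceq (uM)` = round(x$Ceq, 1),
                      `retention` = round(x$retention, 2),
                      `Pe (cm/s)` = signif(x$Pe, 3),
                      `logPe` = round(x$logPe, 2),
                      ok = x$ok, check.names = FALSE)
  cat("PAMPA effective permeability\n")
  print.data.frame(shown, row.names = FALSE, ...)
  m <- attr(x, "ph_means")
  if (!is.null(m) && nrow(m)) {
    cat("\nPer-pH mean permeability:\n")
    print.data.frame(data.frame(pH = m$pH, `Pe (cm/s)` = signif(m$Pe, 3),
                                logPe = round(m$logPe, 2),
                                check.names = FALSE), row.names = FALSE)
  }
  invisible(x)
}
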