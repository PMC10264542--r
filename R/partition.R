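#' Fit the two-species octanol/water partition model
#'
#' An ionizable weak acid distributes between water and octanol (or a
#' membrane) with a pH-dependent distribution coefficient
#' \deqn{Q(\mathrm{pH}) = \frac{P^0\,10^{\mathrm{p}K_a-\mathrm{pH}} + P^-}
#'   {1 + 10^{\mathrm{p}K_a-\mathrm{pH}}}}
#' where \eqn{P^0} and \eqn{P^-} are the partition coefficients of the
#' neutral and deprotonated species. `fit_partition` determines
#' \eqn{P^0} and \eqn{P^-} from exactly two measured \eqn{(pH, K_{ow})}
#' pairs.
#'
#' Two fitting modes are available:
#' \describe{
#'   \item{`"direct"`}{Requires one clearly acidic point
#'     (\eqn{pH \le pK_a - 2}) and one clearly basic point
#'     (\eqn{pH \ge pK_a + 2}); the measured \eqn{K_{ow}} values are
#'     assigned to \eqn{P^0} and \eqn{P^-} unchanged. At two pH units from
#'     the pKa the minority-species correction is below 1%, so this is
#'     the robust default for measurements taken far from the pKa.}
#'   \item{`"exact"`}{Solves the 2x2 linear system obtained by writing
#'     \eqn{Q(1+\beta) = P^0\beta + P^-} at both measured pH values
#'     (\eqn{\beta = 10^{pK_a - pH}}). Exact when the data are consistent
#'     with the two-species model; fails loudly (rather than clamping)
#'     when the solved coefficients are not positive.}
#' }
#'
#' @param measurements A data frame with columns `pH` and `Kow` and
#'   exactly two rows, e.g. from [read_partition_measurements()].
#' @param pKa Acid dissociation constant of the solute (4.65 for
#'   hydrazoic acid).
#' @param mode `"direct"` (default) or `"exact"`; see Details.
#' @param thermo A [thermo_context()] (or bare kBT in kcal/mol) stored in
#'   the model and used by its free-energy methods.
#' @return An object of class `partition_model`: a list with elements
#'   `P0`, `Pminus`, `pKa`, `kBT`, `mode`, `measurements` and `call`.
#' @seealso [distribution_coefficient()], [transfer_free_energy()],
#'   [q_table()], [predict.partition_model()]
#' @examples
#' meas <- data.frame(pH = c(2, 8), Kow = c(2.01, 0.00034))
#' fit <- fit_partition(meas, pKa = 4.65)
#' fit
#' predict(fit, pH = 7.4)
#' @export
fit_partition <- function(measurements, pKa = 4.65,
                          mode = c("direct", "exact"),
                          thermo = thermo_context()) {
  mode <- match.arg(mode)
  kBT <- .kbt(thermo)
  if (!is.data.frame(measurements) ||
      !all(c("pH", "Kow") %in% names(measurements)))
    stop("'measurements' must be a data frame with columns 'pH' and 'Kow'")
  if (nrow(measurements) != 2L)
    stop("exactly two (pH, Kow) measurements are required")
  if (any(measurements$Kow <= 0))
    stop("measured Kow values must be positive")
  pH <- .check_ph(measurements$pH)
  Kow <- measurements$Kow

  if (mode == "direct") {
    i_acid <- which(pH <= pKa - 2)
    i_base <- which(pH >= pKa + 2)
    if (length(i_acid) != 1L || length(i_base) != 1L)
      stop(sprintf(paste0(
        "mode = 'direct' needs one acidic (pH <= %.2f) and one basic ",
        "(pH >= %.2f) measurement; got pH = %s"),
        pKa - 2, pKa + 2, paste(format(pH), collapse = ", ")))
    P0 <- Kow[i_acid]
    Pminus <- Kow[i_base]
  } else {
    if (abs(pH[1] - pH[2]) < .Machine$double.eps^0.5)
      stop("mode = 'exact' needs two distinct pH values")
    beta <- 10^(pKa - pH)
    A <- cbind(beta, 1)
    y <- Kow * (1 + beta)
    sol <- unname(solve(A, y))
    if (any(sol <= 0))
      stop(sprintf(paste0(
        "exact solve gives non-positive partition coefficients ",
        "(P0 = %.6g, Pminus = %.6g): the measurements are inconsistent ",
        "with the two-species model at pKa = %g; consider mode = 'direct'"),
        sol[1], sol[2], pKa))
    P0 <- sol[1]
    Pminus <- sol[2]
  }
  new_partition_model(P0, Pminus, pKa, kBT, mode = mode,
                      measurements = data.frame(pH = pH, Kow = Kow),
                      call = match.call())
}

#' Construct a partition model from known coefficients
#'
#' Lower-level constructor used by [fit_partition()]; also handy when the
#' species partition coefficients are already known.
#'
#' @param P0,Pminus Partition coefficients of the neutral and deprotonated
#'   species (both > 0). A diagnostic warning is emitted if
#'   `P0 < Pminus` (the neutral species is expected to be the more
#'   lipophilic for an acid like HN3).
#' @param pKa Acid dissociation constant.
#' @param kBT Thermal energy, kcal/mol.
#' @param mode,measurements,call Provenance fields filled by
#'   [fit_partition()]; defaults are fine for manual construction.
#' @return A `partition_model` object.
#' @export
new_partition_model <- function(P0, Pminus, pKa, kBT = 0.593,
                                mode = "manual", measurements = NULL,
                                call = NULL) {
  stopifnot(is.numeric(P0), is.numeric(Pminus), is.numeric(pKa),
            length(P0) == 1L, length(Pminus) == 1L, length(pKa) == 1L)
  if (!is.finite(P0) || P0 <= 0 || !is.finite(Pminus) || Pminus <= 0)
    stop("P0 and Pminus must be positive and finite")
  if (P0 < Pminus)
    warning("P0 < Pminus: the neutral species is less lipophilic than the ",
            "anion, which is unusual for a weak acid; check the inputs")
  structure(list(P0 = P0, Pminus = Pminus, pKa = pKa, kBT = .kbt(kBT),
                 mode = mode, measurements = measurements, call = call),
            class = "partition_model")
}

.check_model <- function(model) {
  if (!inherits(model, "partition_model"))
    stop("'model' must be a partition_model (see fit_partition())")
  invisible(model)
}

#' pH-dependent distribution coefficient Q(pH)
#'
#' Evaluates the two-species distribution coefficient
#' \eqn{Q(pH) = (P^0 10^{pK_a-pH} + P^-)/(1 + 10^{pK_a-pH})}, the ratio of
#' total (neutral + anionic) solute concentration in the organic phase to
#' that in the aqueous phase.
#'
#' @param model A `partition_model`.
#' @param pH Numeric vector of pH values. Values outside \[0, 14\] are
#'   clamped with a warning.
#' @return Numeric vector of distribution coefficients, one per pH.
#' @examples
#' m <- new_partition_model(2.01, 0.00034, 4.65)
#' distribution_coefficient(m, 7.4)  # 0.00391 at 5 dp
#' @export
distribution_coefficient <- function(model, pH) {
  .check_model(model)
  pH <- .check_ph(pH)
  beta <- 10^(model$pKa - pH)
  # beta overflows only for absurd pH; guard the Inf/Inf limit anyway
  q <- (model$P0 * beta + model$Pminus) / (1 + beta)
  q[is.infinite(beta)] <- model$P0
  q
}

#' Water-to-organic transfer free energy
#'
#' \eqn{\Delta G(pH) = -k_B T \ln Q(pH)}, the free energy of transferring
#' the solute (all protonation states pooled) from the aqueous phase at
#' the given pH into the organic phase. Negative values mean the organic
#' phase (octanol or membrane) is favoured.
#'
#' @inheritParams distribution_coefficient
#' @param kBT Thermal energy in kcal/mol; defaults to the value stored in
#'   the model.
#' @return Numeric vector, kcal/mol.
#' @examples
#' m <- new_partition_model(2.01, 0.00034, 4.65)
#' transfer_free_energy(m, c(2, 7.4, 10))
#' @export
transfer_free_energy <- function(model, pH, kBT = model$kBT) {
  -.kbt(kBT) * log(distribution_coefficient(model, pH))
}

#' Free energy of forming the neutral species from the anion
#'
#' For an acid with the given pKa in water at the given pH, the free
#' energy of protonating the anion (forming the neutral species) is
#' \deqn{\Delta G = \ln 10 \cdot k_B T \cdot (\mathrm{p}K_a - \mathrm{pH}).}
#' Negative above the pKa, positive below it. For HN3 (pKa 4.65) this
#' gives -3.75 kcal/mol at pH 7.4 (reported as the protonation free
#' energy at physiological pH) and +3.62 kcal/mol at pH 2.0 (reported
#' as the deprotonation cost in acid).
#'
#' @param pKa Acid dissociation constant.
#' @param pH Numeric vector of pH values.
#' @param thermo A [thermo_context()] or bare kBT (kcal/mol).
#' @return Numeric vector, kcal/mol.
#' @export
neutral_formation_free_energy <- function(pKa, pH, thermo = thermo_context()) {
  kBT <- .kbt(thermo)
  log(10) * kBT * (pKa - pH)
}

#' Equilibrium concentration ratio between two aqueous compartments
#'
#' Two aqueous compartments at different pH separated by a membrane in
#' equilibrium with both hold total solute concentrations in the ratio of
#' their distribution coefficients:
#' \eqn{[A]_{dest}/[A]_{source} = Q(pH_{source})/Q(pH_{dest})}.
#'
#' `mode = "approx"` returns the neutral-dominant closed-form limit
#' \eqn{10^{pH_{dest} - pH_{source}}}, valid when the anionic term
#' \eqn{P^-} is negligible and both pH values are well above the pKa; it
#' warns that the anionic contribution is ignored.
#'
#' @param model A `partition_model`.
#' @param pH_source,pH_dest pH of the source and destination compartments.
#' @param mode `"exact"` (ratio of Q values, default) or `"approx"`.
#' @return The destination/source concentration ratio (unitless).
#' @examples
#' m <- new_partition_model(2.01, 0.00034, 4.65)
#' compartment_ratio(m, 7.4, 7.2)            # 0.6525
#' @export
compartment_ratio <- function(model, pH_source, pH_dest,
                              mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  .check_model(model)
  if (mode == "exact") {
    distribution_coefficient(model, pH_source) /
      distribution_coefficient(model, pH_dest)
  } else {
    warning("approx mode ignores the anionic partition coefficient P-; ",
            "valid only for pH well above pKa")
    10^(pH_dest - pH_source)
  }
}

#' Distribution coefficients and free energies over a pH grid
#'
#' Tabulates Q, log10 Q and the transfer free energy over a set of pH
#' values. The default grid spans pH 1-10 including the pKa and the
#' physiologically relevant points (cytoplasm 7.2, extracellular fluid
#' 7.4, mitochondria 8).
#'
#' @inheritParams transfer_free_energy
#' @param pH Numeric vector of pH values (nonempty).
#' @return A data frame of class `q_table` with full-precision columns
#'   `pH`, `Q`, `logQ`, `dG` (kcal/mol). The print method rounds to the
#'   conventional reporting precision (Q to 5 decimals, logQ and dG to 3).
#' @examples
#' m <- new_partition_model(2.01, 0.00034, 4.65)
#' q_table(m)
#' @export
q_table <- function(model,
                    pH = c(1, 2, 3, 4, 4.65, 6, 6.8, 7.1, 7.2, 7.4,
                           8, 9, 10),
                    kBT = model$kBT) {
  .check_model(model)
  if (length(pH) == 0L) stop("'pH' must be nonempty")
  q <- distribution_coefficient(model, pH)
  out <- data.frame(pH = pH, Q = q, logQ = log10(q),
                    dG = -.kbt(kBT) * log(q))
  class(out) <- c("q_table", "data.frame")
  out
}

#' @export
print.q_table <- function(x, ...) {
  shown <- data.frame(pH = x$pH, Q = round(x$Q, 5),
                      logQ = round(x$logQ, 3),
                      `dG (kcal/mol)` = round(x$dG, 3),
                      check.names = FALSE)
  print.data.frame(shown, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.partition_model <- function(x, digits = 5, ...) {
  cat("Two-species octanol/water partition model\n")
  cat(sprintf("  P0 (neutral) = %.*g   P- (anion) = %.*g   pKa = %g\n",
              digits, x$P0, digits, x$Pminus, x$pKa))
  cat(sprintf("  kBT = %g kcal/mol   fit mode: %s\n", x$kBT, x$mode))
  invisible(x)
}

#' @export
coef.partition_model <- function(object, ...) {
  c(P0 = object$P0, Pminus = object$Pminus, pKa = object$pKa)
}

#' Summarize a fitted partition model
#'
#' @param object A `partition_model`.
#' @param pH pH values at which Q and the transfer free energy are
#'   reported (default: the standard grid of [q_table()]).
#' @param ... Unused.
#' @return An object of class `summary.partition_model`.
#' @export
summary.partition_model <- function(object,
                                    pH = c(1, 2, 3, 4, 4.65, 6, 6.8,
                                           7.1, 7.2, 7.4, 8, 9, 10),
                                    ...) {
  structure(list(model = object, table = q_table(object, pH)),
            class = "summary.partition_model")
}

#' @export
print.summary.partition_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$measurements)) {
    cat("  fitted to measurements:\n")
    print.data.frame(x$model$measurements, row.names = FALSE)
  }
  cat("\nDistribution coefficients and transfer free energies:\n")
  print(x$table)
  invisible(x)
}

#' Predict from a partition model
#'
#' @param object A `partition_model`.
#' @param pH pH values at which to predict.
#' @param type `"Q"` (distribution coefficient, default), `"logQ"`, or
#'   `"dG"` (transfer free energy, kcal/mol).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.partition_model <- function(object, pH,
                                    type = c("Q", "logQ", "dG"), ...) {
  type <- match.arg(type)
  q <- distribution_coefficient(object, pH)
  switch(type, Q = q, logQ = log10(q), dG = -object$kBT * log(q))
}

#' Plot the pH-dependence of the distribution coefficient
#'
#' Draws log10 Q(pH) over a pH grid with the fitted measurements (if any)
#' overplotted.
#'
#' @param x A `partition_model`.
#' @param from,to pH range.
#' @param n Number of curve points.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.partition_model <- function(x, from = 1, to = 13, n = 200, ...) {
  ph <- seq(from, to, length.out = n)
  q <- distribution_coefficient(x, ph)
  graphics::plot(ph, log10(q), type = "l", xlab = "pH",
                 ylab = expression(log[10] ~ Q), ...)
  graphics::abline(v = x$pKa, lty = 3)
  if (!is.null(x$measurements))
    graphics::points(x$measurements$pH, log10(x$measurements$Kow), pch = 19)
  invisible(x)
}

#' Simulate noisy partition measurements from a fitted model
#'
#' Draws replicate \eqn{(pH, K_{ow})} data sets from the model with
#' multiplicative lognormal noise, via
#' [simulate_partition_measurements()].
#'
#' @param object A `partition_model`.
#' @param nsim Number of replicate measurement sets.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @param pH pH values at which measurements are simulated.
#' @param noise_cv Coefficient of variation of the lognormal measurement
#'   noise (0 = noiseless).
#' @param ... Unused.
#' @return A data frame with columns `replicate`, `pH`, `Kow`.
#' @export
simulate.partition_model <- function(object, nsim = 1, seed = NULL,
                                     pH = c(2, 8), noise_cv = 0, ...) {
  .with_seed(seed, {
    reps <- lapply(seq_len(nsim), function(i) {
      cbind(replicate = i,
            simulate_partition_measurements(object, pH_points = pH,
                                            noise_cv = noise_cv,
                                            seed = NULL))
    })
    do.call(rbind, reps)
  })
}
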