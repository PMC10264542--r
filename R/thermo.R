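#' Thermal-energy context
#'
#' Bundles the thermal energy \eqn{k_B T} used by every free-energy
#' conversion in the package. The default, 0.593 kcal/mol, corresponds to
#' approximately 298 K and is the value consistent with the tabulated
#' transfer free energies and the protonation arithmetic this package
#' reproduces.
#'
#' @param kBT Thermal energy in kcal/mol. Must be positive.
#' @return An object of class `thermo_context`: a list with elements
#'   `kBT` (kcal/mol) and `ln10` (the natural log of 10).
#' @examples
#' th <- thermo_context()
#' th$kBT
#' @export
thermo_context <- function(kBT = 0.593) {
  if (!is.numeric(kBT) || length(kBT) != 1L || !is.finite(kBT) || kBT <= 0)
    stop("'kBT' must be a single positive number (kcal/mol)")
  structure(list(kBT = kBT, ln10 = log(10)), class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("Thermal energy kBT = %g kcal/mol (T ~ %.0f K)\n",
              x$kBT, x$kBT / 0.0019872))
  invisible(x)
}

# Resolve a kBT value from either a thermo_context or a bare number.
.kbt <- function(thermo) {
  if (inherits(thermo, "thermo_context")) return(thermo$kBT)
  if (is.numeric(thermo) && length(thermo) == 1L && is.finite(thermo) &&
      thermo > 0) return(as.numeric(thermo))
  stop("'thermo' must be a thermo_context or a single positive number")
}

# pH sanity: clamp to [0, 14] (warning), warn outside [1, 13].
.check_ph <- function(pH, what = "pH") {
  if (!is.numeric(pH) || any(!is.finite(pH)))
    stop(sprintf("'%s' must be finite numeric", what))
  out_hard <- pH < 0 | pH > 14
  if (any(out_hard)) {
    warning(sprintf("%s outside [0, 14]; clamping", what))
    pH <- pmin(pmax(pH, 0), 14)
  } else if (any(pH < 1 | pH > 13)) {
    warning(sprintf("%s outside the usual [1, 13] range", what))
  }
  pH
}

# Run an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards (same convention as stats::simulate).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
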