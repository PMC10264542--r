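#' Aqueous compartment specification
#'
#' @param name Compartment label, e.g. `"ECF"` (extracellular fluid) or
#'   `"CYT"` (cytoplasm).
#' @param pH Compartment pH in \[0, 14\].
#' @return An object of class `compartment`.
#' @examples
#' compartment("ECF", 7.4)
#' @export
compartment <- function(name, pH) {
  pH <- .check_ph(pH)
  structure(list(name = as.character(name), pH = pH), class = "compartment")
}

#' @export
print.compartment <- function(x, ...) {
  cat(sprintf("Compartment %s (pH %g)\n", x$name, x$pH))
  invisible(x)
}

#' Free-energy plateaus for donor -> membrane -> acceptor transfer
#'
#' Converts the pH-dependent partition model into the three plateau
#' free energies of a piecewise-constant 1-D profile. The donor aqueous
#' phase is the reference (G = 0); the membrane plateau is the
#' water-to-membrane transfer free energy at the donor pH,
#' \eqn{-k_B T \ln Q(pH_{donor})}; and the acceptor plateau sits at the
#' difference of the two transfer free energies, so that the
#' donor-to-acceptor drop equals the net free energy of moving the
#' solute between the two aqueous compartments.
#'
#' @param model A `partition_model`.
#' @param donor,acceptor [compartment()] objects (or lists with `name`
#'   and `pH`).
#' @param kBT Thermal energy, kcal/mol (default: the model's).
#' @return Named numeric vector `c(donor, membrane, acceptor)` in
#'   kcal/mol, with the compartment specs attached as attributes.
#' @examples
#' m <- new_partition_model(2.01, 0.00034, 4.65)
#' build_compartment_profile(m, compartment("ECF", 7.4),
#'                           compartment("CYT", 7.2))
#' @export
build_compartment_profile <- function(model, donor, acceptor,
                                      kBT = model$kBT) {
  .check_model(model)
  if (is.list(donor) && !is.null(donor$pH)) donor_pH <- donor$pH
  else stop("'donor' must be a compartment()")
  if (is.list(acceptor) && !is.null(acceptor$pH)) acceptor_pH <- acceptor$pH
  else stop("'acceptor' must be a compartment()")
  gd <- transfer_free_energy(model, donor_pH, kBT = kBT)
  ga <- transfer_free_energy(model, acceptor_pH, kBT = kBT)
  out <- c(donor = 0, membrane = gd, acceptor = gd - ga)
  attr(out, "donor") <- donor
  attr(out, "acceptor") <- acceptor
  attr(out, "kBT") <- .kbt(kBT)
  out
}

#' Discretize plateau free energies onto a 1-D grid
#'
#' Builds a cell-centered uniform grid spanning an explicit donor water
#' reservoir, the membrane, and an acceptor water reservoir. x = 0 is
#' the donor-side membrane face and the membrane occupies \[0, d). The
#' interface steps may be spread linearly over `ramp_width` (measured
#' into the membrane from each face); `ramp_width = 0` gives an abrupt
#' step between adjacent cells.
#'
#' The explicit reservoirs close the system for Dirichlet boundary
#' conditions and stand in for the unstirred water layers adjacent to a
#' real membrane; their depth is configurable for sensitivity analysis.
#'
#' @param plateaus Named or positional numeric of length 3
#'   `(G_donor, G_membrane, G_acceptor)` in kcal/mol, e.g. from
#'   [build_compartment_profile()].
#' @param d Membrane thickness, cm.
#' @param dx Grid spacing, cm; `d/dx` must be integral (to 1e-9
#'   relative).
#' @param reservoir_depth Depth of each explicit water reservoir, cm
#'   (default 5 cells).
#' @param ramp_width Width over which each interface step is linearly
#'   ramped, cm; must lie in \[0, d/2\].
#' @return An object of class `energy_profile`: a list with `x` (cell
#'   centers, cm), `G` (kcal/mol), `region` (factor donor/membrane/
#'   acceptor), `d`, `dx`, and the plateau values.
#' @examples
#' pl <- c(donor = 0, membrane = 3.288, acceptor = 0.253)
#' pr <- discretize_profile(pl, d = 125e-4, dx = 1e-4)
#' table(pr$region)
#' @export
discretize_profile <- function(plateaus, d, dx,
                               reservoir_depth = 5 * dx, ramp_width = 0) {
  p <- as.numeric(plateaus)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("'plateaus' must be three finite free energies (kcal/mol)")
  if (d <= 0 || dx <= 0) stop("'d' and 'dx' must be positive")
  ncells <- d / dx
  n_mem <- round(ncells)
  if (n_mem < 1L || abs(ncells - n_mem) > 1e-9 * max(1, ncells))
    stop(sprintf("membrane thickness d = %g is not an integral number of grid cells (d/dx = %.12g)", d, ncells))
  if (ramp_width < 0 || ramp_width > d / 2)
    stop("'ramp_width' must lie in [0, d/2]")
  n_res <- max(1L, round(reservoir_depth / dx))

  g_don <- p[1]; g_mem <- p[2]; g_acc <- p[3]
  x_mem <- (seq_len(n_mem) - 0.5) * dx
  G_mem <- rep(g_mem, n_mem)
  if (ramp_width > 0) {
    lo <- x_mem < ramp_width
    G_mem[lo] <- g_don + (g_mem - g_don) * x_mem[lo] / ramp_width
    hi <- x_mem > d - ramp_width
    G_mem[hi] <- g_mem + (g_acc - g_mem) * (x_mem[hi] - (d - ramp_width)) /
      ramp_width
  }
  x <- c(-rev(seq_len(n_res) - 0.5) * dx, x_mem,
         d + (seq_len(n_res) - 0.5) * dx)
  G <- c(rep(g_don, n_res), G_mem, rep(g_acc, n_res))
  region <- factor(c(rep("donor", n_res), rep("membrane", n_mem),
                     rep("acceptor", n_res)),
                   levels = c("donor", "membrane", "acceptor"))
  structure(list(x = x, G = G, region = region, d = d, dx = dx,
                 n_membrane = n_mem, n_reservoir = n_res,
                 plateaus = c(donor = g_don, membrane = g_mem,
                              acceptor = g_acc)),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("1-D free-energy profile\n")
  cat(sprintf("  membrane: %g cm (%d cells of %g cm), reservoirs: %d cells each\n",
              x$d, x$n_membrane, x$dx, x$n_reservoir))
  cat(sprintf("  plateaus (kcal/mol): donor %.4g, membrane %.4g, acceptor %.4g\n",
              x$plateaus[1], x$plateaus[2], x$plateaus[3]))
  invisible(x)
}

#' @export
plot.energy_profile <- function(x, ...) {
  graphics::plot(x$x * 1e4, x$G, type = "s", xlab = "x (um)",
                 ylab = "G (kcal/mol)", ...)
  graphics::abline(v = c(0, x$d * 1e4), lty = 3)
  invisible(x)
}

#' Write / read an energy profile as CSV
#'
#' Columns `x_cm`, `G_kcal_mol`, `region`. The membrane thickness and
#' grid spacing are recovered from the data on read.
#'
#' @param profile An `energy_profile`.
#' @param path File path.
#' @return `write_energy_profile`: the path, invisibly.
#'   `read_energy_profile`: an `energy_profile`.
#' @export
write_energy_profile <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  write.csv(data.frame(x_cm = profile$x, G_kcal_mol = profile$G,
                       region = as.character(profile$region)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_profile
#' @export
read_energy_profile <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_cm", "G_kcal_mol", "region")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  region <- factor(df$region, levels = c("donor", "membrane", "acceptor"))
  mem <- region == "membrane"
  dxs <- diff(df$x_cm)
  if (any(abs(dxs - dxs[1]) > 1e-9 * dxs[1]))
    stop("profile grid is not uniform")
  dx <- dxs[1]
  n_mem <- sum(mem)
  structure(list(x = df$x_cm, G = df$G_kcal_mol, region = region,
                 d = n_mem * dx, dx = dx, n_membrane = n_mem,
                 n_reservoir = sum(region == "donor"),
                 plateaus = c(donor = df$G_kcal_mol[1],
                              membrane = max(df$G_kcal_mol[mem]),
                              acceptor = df$G_kcal_mol[length(df$G_kcal_mol)])),
            class = "energy_profile")
}
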