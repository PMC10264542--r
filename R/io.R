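#' Read and write partition measurements
#'
#' Delimited-text interface for \eqn{(pH, K_{ow})} measurement tables:
#' CSV with header `pH,Kow`.
#'
#' @param path File path.
#' @param measurements A data frame with columns `pH`, `Kow`.
#' @return `read_partition_measurements`: a data frame with columns
#'   `pH`, `Kow`. `write_partition_measurements`: the path, invisibly.
#' @export
read_partition_measurements <- function(path) {
  df <- read.csv(path)
  if (!all(c("pH", "Kow") %in% names(df)))
    stop("measurement CSV must have columns 'pH' and 'Kow'")
  df[c("pH", "Kow")]
}

#' @rdname read_partition_measurements
#' @export
write_partition_measurements <- function(measurements, path) {
  stopifnot(all(c("pH", "Kow") %in% names(measurements)))
  write.csv(measurements[c("pH", "Kow")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Serialize a partition model to JSON
#'
#' The model is stored as a flat JSON object
#' `{"P0": ..., "Pminus": ..., "pKa": ..., "kBT": ...}`.
#'
#' @param model A `partition_model`.
#' @param path File path.
#' @return `write_partition_model`: the path, invisibly.
#'   `read_partition_model`: a `partition_model`.
#' @export
write_partition_model <- function(model, path) {
  .check_model(model)
  jsonlite::write_json(list(P0 = model$P0, Pminus = model$Pminus,
                            pKa = model$pKa, kBT = model$kBT),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_model
#' @export
read_partition_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("P0", "Pminus", "pKa", "kBT")
  if (!all(need %in% names(obj)))
    stop("model JSON must contain ", paste(need, collapse = ", "))
  new_partition_model(obj$P0, obj$Pminus, obj$pKa, obj$kBT,
                      mode = "deserialized")
}

#' Read a PAMPA plate from CSV
#'
#' Expects a header with at least `pH,C0,CD_t,CA_t`; missing geometry
#' columns (`VD`, `VA`, `S`, `t`) are filled with the standard plate
#' values 0.2 mL, 0.3 mL, 0.3 cm^2 and 18,000 s.
#'
#' @param path File path.
#' @return A wells data frame with the columns of [pampa_well()].
#' @export
read_pampa_plate <- function(path) {
  df <- read.csv(path)
  need <- c("pH", "C0", "CD_t", "CA_t")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns ", paste(need, collapse = ", "))
  defaults <- c(VD = 0.2, VA = 0.3, S = 0.3, t = 18000)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  .check_wells(df)
  df[c(need, names(defaults))]
}

#' Write PAMPA plate results to CSV
#'
#' Mirrors the assay result table (equilibrium concentration, mass
#' retention as a fraction, permeability and its log10) at full
#' precision.
#'
#' @param results A `pampa_results` data frame from [analyze_plate()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_pampa_results <- function(results, path) {
  stopifnot(inherits(results, "pampa_results") || is.data.frame(results))
  write.csv(as.data.frame(results), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
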