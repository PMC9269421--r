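# Species parameters: the 15-value CLIMEX-style parameter vector for
# Urochloa panicoides, plus the low/high bounds used by the sensitivity
# protocol.

# Adjusted values with the low/high sensitivity bounds for every parameter.
# Temperature thresholds vary by +/- 1 degree C, moisture/rate parameters by
# +/- 10%, degree-days by +/- 20 degree C days.
.param_table <- data.frame(
  code = c("DV0", "DV1", "DV2", "DV3",
           "SM0", "SM1", "SM2", "SM3",
           "TTCS", "THCS", "TTHS", "THHS",
           "SMDS", "HDS", "PPD"),
  low      = c(3, 24, 34, 44, 0.09, 0.18, 7.2, 9,
               3, -0.0018, 44, 0.018, 0.09, -0.009, 1497),
  adjusted = c(4, 25, 35, 45, 0.10, 0.20, 8.0, 10,
               4, -0.0020, 45, 0.020, 0.10, -0.010, 1517),
  high     = c(5, 26, 36, 46, 0.11, 0.22, 8.8, 11,
               5, -0.0022, 46, 0.022, 0.11, -0.011, 1537),
  stringsAsFactors = FALSE
)

#' Species parameter set for the ecoclimatic-index model
#'
#' Constructs and validates the 15-parameter vector driving the suitability
#' engine: the temperature trapezoid `DV0 < DV1 <= DV2 < DV3` (deg C), the
#' soil-moisture trapezoid `SM0 < SM1 <= SM2 < SM3` (fractions of bucket
#' holding capacity), cold/heat stress thresholds (`TTCS`, `TTHS`, deg C)
#' with weekly accumulation rates (`THCS <= 0`, `THHS >= 0`, per week), the
#' dry-stress threshold `SMDS` with rate `HDS <= 0`, and the degree-day
#' persistence requirement `PPD` (deg C days per generation above `DV0`).
#'
#' Defaults are the adjusted values fitted for *Urochloa panicoides*
#' (liverseed grass): DV0 = 4, DV1 = 25, DV2 = 35, DV3 = 45; SM0 = 0.1,
#' SM1 = 0.2, SM2 = 8, SM3 = 10; TTCS = 4, THCS = -0.002, TTHS = 45,
#' THHS = 0.02, SMDS = 0.1, HDS = -0.01, PPD = 1517.
#'
#' @param ... named overrides of individual parameters, e.g. `SMDS = 0.01`.
#' @return An object of class `ecx_params`: a named list of the 15 values.
#' @examples
#' p <- species_params()
#' p$DV1
#' species_params(SMDS = 0.01)$SMDS
#' @export
species_params <- function(...) {
  p <- as.list(stats::setNames(.param_table$adjusted, .param_table$code))
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      ecx_stop("parameter overrides must be named")
    }
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      ecx_stop("unknown parameter code(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(over)) {
      check_number(over[[nm]], nm)
      p[[nm]] <- as.numeric(over[[nm]])
    }
  }
  validate_params(p)
  structure(p, class = "ecx_params")
}

validate_params <- function(p) {
  need <- .param_table$code
  miss <- setdiff(need, names(p))
  if (length(miss)) ecx_stop("missing parameter(s): ", paste(miss, collapse = ", "))
  with(p, {
    if (!(DV0 < DV1 && DV1 <= DV2 && DV2 < DV3)) {
      ecx_stop("temperature thresholds must satisfy DV0 < DV1 <= DV2 < DV3")
    }
    if (!(SM0 < SM1 && SM1 <= SM2 && SM2 < SM3)) {
      ecx_stop("moisture thresholds must satisfy SM0 < SM1 <= SM2 < SM3")
    }
    if (THCS > 0) ecx_stop("THCS (cold stress rate) must be <= 0")
    if (HDS > 0) ecx_stop("HDS (dry stress rate) must be <= 0")
    if (THHS < 0) ecx_stop("THHS (heat stress rate) must be >= 0")
    if (PPD < 0) ecx_stop("PPD (degree-days per generation) must be >= 0")
  })
  invisible(p)
}

#' @export
print.ecx_params <- function(x, ...) {
  cat("Ecoclimatic-index species parameters (15 values)\n")
  df <- data.frame(code = names(x), value = unlist(x), row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Reference table of adjusted and sensitivity-bound parameter values
#'
#' The fitted parameter set with the low/high values used by the
#' one-at-a-time sensitivity protocol: temperature parameters vary by
#' plus/minus 1 deg C, moisture and rate parameters by plus/minus 10%,
#' degree-days by plus/minus 20 deg C days.
#'
#' @return data.frame with columns `code`, `low`, `adjusted`, `high`.
#' @export
param_bounds <- function() .param_table

#' Read a species parameter config file
#'
#' Flat `key = value` text format, one parameter per line; `#` starts a
#' comment. Keys absent from the file keep their *U. panicoides* defaults.
#'
#' @param path file path.
#' @return `ecx_params` object.
#' @seealso [write_params()]
#' @export
read_params <- function(path) {
  if (!file.exists(path)) ecx_stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad)) ecx_stop("malformed parameter line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) {
    ecx_stop("non-numeric value for: ", paste(keys[is.na(vals)], collapse = ", "))
  }
  do.call(species_params, as.list(stats::setNames(vals, keys)))
}

#' Write a species parameter config file
#'
#' @param p `ecx_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  writeLines(
    c("# ecoclimex species parameters",
      sprintf("%s = %.6g", names(p), unlist(p))),
    path
  )
  invisible(path)
}
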