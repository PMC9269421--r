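# Climate grid I/O, monthly-to-weekly interpolation, scenario transforms,
# and suitability-map export.
#
# Canonical climate CSV: long format, one row per cell-month, columns
# lat, lon, month, tmin, tmax, precip, rh09, rh15 (+ optional logical land).

CLIMATE_COLS <- c("lat", "lon", "month", "tmin", "tmax", "precip", "rh09", "rh15")

#' Construct a validated monthly climate grid
#'
#' @param df data.frame with the canonical long-format columns: `lat`, `lon`
#'   (decimal degrees), `month` (1-12), `tmin`, `tmax` (deg C), `precip`
#'   (mm/month), `rh09`, `rh15` (relative humidity fractions in `[0,1]`;
#'   percentage inputs with values > 1.5 are auto-detected and divided by
#'   100). An optional logical `land` column marks cells that enter
#'   area-share computations (all TRUE when absent).
#' @return data.frame of class `ecx_climate`, sorted by (lat, lon, month).
#' @export
climate_grid <- function(df) {
  miss <- setdiff(CLIMATE_COLS, names(df))
  if (length(miss)) {
    ecx_stop("climate data missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) ecx_stop("climate data has no rows")
  num <- CLIMATE_COLS
  for (cl in num) {
    if (!is.numeric(df[[cl]])) ecx_stop("column ", cl, " must be numeric")
  }
  if (anyNA(df[num])) {
    bad <- df[!stats::complete.cases(df[num]), c("lat", "lon", "month")]
    ecx_stop("missing values in climate rows; first offending cell: lat=",
             bad$lat[1], " lon=", bad$lon[1], " month=", bad$month[1])
  }
  if (any(df$month != as.integer(df$month)) || any(df$month < 1 | df$month > 12)) {
    ecx_stop("month must be an integer in 1..12")
  }
  if (any(df$lat < -90 | df$lat > 90)) ecx_stop("lat outside [-90, 90]")
  if (any(df$lon < -180 | df$lon >= 180)) ecx_stop("lon outside [-180, 180)")
  # percent-style humidity auto-detection
  for (cl in c("rh09", "rh15")) {
    if (any(df[[cl]] > 1.5)) df[[cl]] <- df[[cl]] / 100
    if (any(df[[cl]] < 0 | df[[cl]] > 1)) {
      ecx_stop(cl, " outside [0, 1] after unit detection")
    }
  }
  if (any(df$precip < 0)) ecx_stop("precip must be >= 0")
  bad <- df$tmin > df$tmax
  if (any(bad)) {
    i <- which(bad)[1]
    ecx_stop("tmin > tmax at cell lat=", df$lat[i], " lon=", df$lon[i],
             " month=", df$month[i])
  }
  key <- paste(df$lat, df$lon, df$month)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    ecx_stop("duplicate cell-month: lat=", df$lat[i], " lon=", df$lon[i],
             " month=", df$month[i])
  }
  if (is.null(df$land)) df$land <- TRUE
  df$land <- as.logical(df$land)
  cells <- unique(df[c("lat", "lon")])
  n12 <- table(paste(df$lat, df$lon))
  if (any(n12 != 12L)) {
    ecx_stop("every cell needs exactly 12 months; offending cell: ",
             names(n12)[which(n12 != 12L)[1]])
  }
  df <- df[order(df$lat, df$lon, df$month), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ecx_climate", "data.frame"))
}

#' Read the canonical climate CSV
#'
#' Lines starting with `#` are metadata comments and are skipped. Rows with
#' any missing variable are rejected, naming the offending cell.
#'
#' @param path CSV file path.
#' @return `ecx_climate` grid.
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) ecx_stop("climate file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#"),
    error = function(e) ecx_stop("cannot parse climate CSV: ", conditionMessage(e))
  )
  if (nrow(df) == 0L) ecx_stop("climate file has an empty data section: ", path)
  climate_grid(df)
}

#' Write the canonical climate CSV
#'
#' @param grid `ecx_climate` grid.
#' @param path output path.
#' @param seed optional seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(grid, path, seed = NULL) {
  stopifnot(inherits(grid, "ecx_climate"))
  cols <- c(CLIMATE_COLS, if (!all(grid$land)) "land")
  write_csv_with_header(as.data.frame(grid)[cols], path,
                        ecx_metadata_header(seed, "climate grid"))
}

# Linear map from 12 monthly midpoint values to 52 weekly midpoint values,
# circular over a 364-day year. Returned as a 12 x 52 weight matrix whose
# columns sum to 1, so interpolation is monthly %*% W.
month_week_weights <- function() {
  year <- 364
  m_mid <- (seq_len(12) - 0.5) * year / 12
  w_mid <- (seq_len(52) - 0.5) * 7
  W <- matrix(0, 12, 52)
  for (w in seq_len(52)) {
    t <- w_mid[w]
    if (t < m_mid[1]) {
      lo <- 12; hi <- 1; t0 <- m_mid[12] - year; t1 <- m_mid[1]
    } else if (t >= m_mid[12]) {
      lo <- 12; hi <- 1; t0 <- m_mid[12]; t1 <- m_mid[1] + year
    } else {
      lo <- findInterval(t, m_mid); hi <- lo + 1L
      t0 <- m_mid[lo]; t1 <- m_mid[hi]
    }
    f <- (t - t0) / (t1 - t0)
    W[lo, w] <- W[lo, w] + (1 - f)
    W[hi, w] <- W[hi, w] + f
  }
  W
}

#' Interpolate monthly climate normals to a 52-week year
#'
#' Each variable is linearly interpolated between consecutive month
#' midpoints, circular across the December-January boundary, over a 364-day
#' (52 x 7) year. Weekly precipitation is rescaled per cell so the annual
#' total equals the sum of the monthly totals. The weekly humidity is the
#' mean of the 09:00 and 15:00 observations; `tmean = (tmin + tmax)/2`.
#'
#' @param grid `ecx_climate` grid.
#' @return Object of class `ecx_weekly`: a list with `cells` (data.frame
#'   `lat`, `lon`, `land`) and n_cells x 52 matrices `tmin`, `tmax`, `tmean`,
#'   `precip` (mm/week), `rh`.
#' @export
monthly_to_weekly <- function(grid) {
  stopifnot(inherits(grid, "ecx_climate"))
  cells <- unique(as.data.frame(grid)[c("lat", "lon", "land")])
  rownames(cells) <- NULL
  n <- nrow(cells)
  # grid is sorted by (lat, lon, month): reshape each variable to n x 12
  shape <- function(v) matrix(v, nrow = n, ncol = 12, byrow = TRUE)
  W <- month_week_weights()
  tmin <- shape(grid$tmin) %*% W
  tmax <- shape(grid$tmax) %*% W
  rh <- (shape(grid$rh09) %*% W + shape(grid$rh15) %*% W) / 2
  pm <- shape(grid$precip)                  # mm per month
  pw <- (pm * 12 / 52) %*% W                # interpolated mm per week
  annual <- rowSums(pm)
  wsum <- rowSums(pw)
  scale <- ifelse(wsum > 0, annual / wsum, 1)
  pw <- pw * scale
  structure(
    list(cells = cells, tmin = tmin, tmax = tmax, tmean = (tmin + tmax) / 2,
         precip = pw, rh = rh),
    class = "ecx_weekly"
  )
}

#' Climate-change scenario transform
#'
#' A uniform temperature shift plus a multiplicative precipitation scaling,
#' the form in which global-model projections are summarised here (e.g. the
#' CSIRO-Mk3.0 A2 full-century change: +2.11 deg C, precipitation x 0.86).
#' Humidity is left unchanged.
#'
#' @param delta_t deg C added to `tmin` and `tmax`.
#' @param precip_scale multiplicative precipitation factor (>= 0).
#' @param label scenario label, e.g. a year.
#' @return `ecx_scenario` object.
#' @export
scenario_transform <- function(delta_t = 0, precip_scale = 1, label = "scenario") {
  check_number(delta_t, "delta_t")
  check_number(precip_scale, "precip_scale", lo = 0)
  structure(list(delta_t = delta_t, precip_scale = precip_scale,
                 label = as.character(label)),
            class = "ecx_scenario")
}

#' Default projection scenarios for 2050, 2080 and 2100
#'
#' The full-century change (+2.11 deg C and a 14% precipitation reduction by
#' 2100 relative to the 1975-centred baseline) scaled linearly with elapsed
#' time: fractions 0.60, 0.84 and 1.00 for 2050, 2080 and 2100.
#'
#' @param delta_t_full full-century temperature increase (deg C).
#' @param precip_drop_full full-century fractional precipitation reduction.
#' @return list of three `ecx_scenario` objects.
#' @export
default_scenarios <- function(delta_t_full = 2.11, precip_drop_full = 0.14) {
  frac <- c("2050" = 0.60, "2080" = 0.84, "2100" = 1.00)
  lapply(stats::setNames(names(frac), names(frac)), function(yr) {
    f <- frac[[yr]]
    scenario_transform(delta_t = delta_t_full * f,
                       precip_scale = 1 - precip_drop_full * f,
                       label = yr)
  })
}

#' Apply a scenario transform to a climate grid
#'
#' Shifts `tmin` and `tmax` by `delta_t`, multiplies precipitation by
#' `precip_scale`, leaves humidity and grid geometry unchanged.
#'
#' @param grid `ecx_climate` grid.
#' @param s `ecx_scenario` transform.
#' @return transformed `ecx_climate` grid.
#' @export
apply_scenario <- function(grid, s) {
  stopifnot(inherits(grid, "ecx_climate"), inherits(s, "ecx_scenario"))
  out <- as.data.frame(grid)
  out$tmin <- out$tmin + s$delta_t
  out$tmax <- out$tmax + s$delta_t
  out$precip <- out$precip * s$precip_scale
  climate_grid(out)
}

#' Write a suitability map
#'
#' CSV export with columns `lat, lon, EI, class, class_code, GI_A, CS, HS,
#' DS, DD` and a metadata header. Class codes 0/1/2 encode
#' unsuitable/low/high. Only `format = "csv"` is supported; requests for
#' raster formats raise a structured unsupported-format error.
#'
#' @param map `ecx_map` suitability map.
#' @param path output path.
#' @param format `"csv"`.
#' @param seed optional seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_suitability <- function(map, path, format = "csv", seed = NULL) {
  stopifnot(inherits(map, "ecx_map"))
  if (!identical(tolower(format), "csv")) {
    ecx_stop("unsupported suitability export format: ", format,
             class = "ecx_unsupported_format")
  }
  df <- as.data.frame(map)
  df$class_code <- class_code(df$class)
  df$EI <- round(df$EI, 6)
  cols <- c("lat", "lon", "EI", "class", "class_code", "GI_A", "CS", "HS",
            "DS", "DD", if (!all(df$land)) "land")
  write_csv_with_header(df[cols], path,
                        ecx_metadata_header(seed, "suitability map"))
}

#' Read a suitability map written by [write_suitability()]
#'
#' @param path CSV path.
#' @return `ecx_map` suitability map.
#' @export
read_suitability <- function(path) {
  if (!file.exists(path)) ecx_stop("suitability file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("lat", "lon", "EI", "class", "GI_A", "CS", "HS", "DS", "DD")
  miss <- setdiff(need, names(df))
  if (length(miss)) ecx_stop("suitability CSV missing: ", paste(miss, collapse = ", "))
  if (is.null(df$land)) df$land <- TRUE
  df$class <- factor(df$class, levels = EI_CLASSES)
  df$class_code <- NULL
  structure(df, class = c("ecx_map", "data.frame"))
}
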