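# One-at-a-time sensitivity protocol over the 15 species parameters, and
# climate-change scenario projection with per-cell deltas.

#' Default perturbation rules for the sensitivity protocol
#'
#' One rule per parameter, with the low/high values of the published
#' sensitivity design: temperature thresholds (DV0-DV3, TTCS, TTHS) vary by
#' plus/minus 1 deg C, moisture and rate parameters (SM0-SM3, THCS, THHS,
#' SMDS, HDS) by plus/minus 10%, and degree-days (PPD) by plus/minus
#' 20 deg C days.
#'
#' @param p `ecx_params` adjusted vector (rules are checked to bracket it).
#' @return data.frame of class `ecx_rules` with columns `parameter`,
#'   `mode`, `low`, `adjusted`, `high` (15 rows).
#' @export
default_rules <- function(p = species_params()) {
  validate_params(p)
  tab <- param_bounds()
  mode <- ifelse(tab$code %in% c("DV0", "DV1", "DV2", "DV3", "TTCS", "TTHS"),
                 "absolute",
                 ifelse(tab$code == "PPD", "absolute-degree-days", "relative"))
  rules <- data.frame(parameter = tab$code, mode = mode,
                      low = tab$low, adjusted = unlist(p[tab$code]),
                      high = tab$high, row.names = NULL)
  # low/high bracket the adjusted value; for negative rates (THCS, HDS) the
  # "high" column holds the larger-magnitude (more negative) perturbation
  span_ok <- (abs(rules$low) < abs(rules$adjusted) &
                abs(rules$adjusted) < abs(rules$high)) |
             (rules$low < rules$adjusted & rules$adjusted < rules$high)
  if (!all(span_ok)) {
    ecx_stop("perturbation rule does not bracket the adjusted value: ",
             paste(rules$parameter[!span_ok], collapse = ", "))
  }
  structure(rules, class = c("ecx_rules", "data.frame"))
}

#' Area share of each suitability class
#'
#' `share_c = 100 * sum_{land cells in class c} cos(lat) / sum_{land cells}
#' cos(lat)`. Cosine-latitude weighting approximates true cell area on an
#' equal-angle grid, where cells shrink poleward; unweighted cell-count
#' shares are attached as attribute `"count_share"`.
#'
#' @param map `ecx_map` suitability map.
#' @return named numeric vector of percentages (`unsuitable`, `low`,
#'   `high`), summing to 100.
#' @export
area_shares <- function(map) {
  stopifnot(inherits(map, "ecx_map"))
  land <- map[map$land, , drop = FALSE]
  if (nrow(land) == 0L) ecx_stop("map has no land cells")
  w <- cos(land$lat * pi / 180)
  cls <- factor(land$class, levels = EI_CLASSES)
  tot <- sum(w)
  shares <- vapply(EI_CLASSES, function(cl) 100 * sum(w[cls == cl]) / tot, 0)
  counts <- vapply(EI_CLASSES, function(cl) 100 * sum(cls == cl) / nrow(land), 0)
  structure(shares, count_share = counts)
}

#' Run the one-at-a-time sensitivity protocol
#'
#' 30 perturbed engine runs (15 parameters x low/high), each differing from
#' the adjusted vector in exactly one parameter, against a common baseline.
#' Reports area shares per suitability class and their change. The weekly
#' climate and soil-moisture spin-up are computed once and shared across
#' runs (no species parameter enters the water balance).
#'
#' @param grid `ecx_climate` monthly grid.
#' @param p `ecx_params` adjusted vector.
#' @param rules `ecx_rules` perturbation table (default [default_rules()]).
#' @param cfg `ecx_sm_config`.
#' @return `ecx_sensitivity`: data.frame with one row per parameter x
#'   direction x class: `parameter, direction, value, class,
#'   baseline_share, perturbed_share, delta_pp` (percentage points) and
#'   `delta_rel_pct` (relative %, NA where the baseline share is 0).
#' @export
run_sensitivity <- function(grid, p = species_params(),
                            rules = default_rules(p),
                            cfg = soil_moisture_config()) {
  stopifnot(inherits(grid, "ecx_climate"), inherits(rules, "data.frame"))
  validate_params(p)
  wk <- prepare_climate(grid, cfg)
  base_share <- area_shares(evaluate_params(wk, p))
  out <- list()
  for (i in seq_len(nrow(rules))) {
    par <- rules$parameter[i]
    for (dir in c("low", "high")) {
      pp <- p
      pp[[par]] <- rules[[dir]][i]
      validate_params(pp)
      sh <- area_shares(evaluate_params(wk, pp))
      out[[length(out) + 1L]] <- data.frame(
        parameter = par, direction = dir, value = rules[[dir]][i],
        class = EI_CLASSES,
        baseline_share = as.numeric(base_share),
        perturbed_share = as.numeric(sh),
        delta_pp = as.numeric(sh) - as.numeric(base_share),
        delta_rel_pct = ifelse(base_share > 0,
                               100 * (as.numeric(sh) - as.numeric(base_share)) /
                                 as.numeric(base_share), NA_real_)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("ecx_sensitivity", "data.frame"))
}

#' Project suitability under climate-change scenarios
#'
#' Runs the engine on the baseline grid and on each transformed grid,
#' returning per-scenario maps, class area shares, and per-cell ecoclimatic
#' index and cold-stress deltas (scenario minus baseline) for mapping where
#' warming relieves cold limitation.
#'
#' @param grid `ecx_climate` baseline grid.
#' @param p `ecx_params`.
#' @param transforms list of `ecx_scenario` (default [default_scenarios()]).
#' @param cfg `ecx_sm_config`.
#' @return `ecx_scenarios` list: `baseline` (`ecx_map`), `maps` (named list
#'   of `ecx_map`), `shares` (data.frame `scenario, class, share`),
#'   `deltas` (data.frame `scenario, lat, lon, dEI, dCS`).
#' @export
run_scenarios <- function(grid, p = species_params(),
                          transforms = default_scenarios(),
                          cfg = soil_moisture_config()) {
  stopifnot(inherits(grid, "ecx_climate"))
  if (inherits(transforms, "ecx_scenario")) transforms <- list(transforms)
  base <- run_grid(grid, p, cfg)
  labels <- vapply(transforms, function(s) s$label, "")
  if (anyDuplicated(labels)) ecx_stop("scenario labels must be unique")
  maps <- list(); shares <- list(); deltas <- list()
  shares[["baseline"]] <- data.frame(scenario = "baseline", class = EI_CLASSES,
                                     share = as.numeric(area_shares(base)))
  for (s in transforms) {
    m <- run_grid(apply_scenario(grid, s), p, cfg)
    maps[[s$label]] <- m
    shares[[s$label]] <- data.frame(scenario = s$label, class = EI_CLASSES,
                                    share = as.numeric(area_shares(m)))
    deltas[[s$label]] <- data.frame(scenario = s$label, lat = m$lat,
                                    lon = m$lon, dEI = m$EI - base$EI,
                                    dCS = m$CS - base$CS)
  }
  structure(
    list(baseline = base, maps = maps,
         shares = do.call(rbind, c(shares, list(make.row.names = FALSE))),
         deltas = do.call(rbind, c(deltas, list(make.row.names = FALSE)))),
    class = "ecx_scenarios"
  )
}

#' Write a sensitivity report
#'
#' @param sens `ecx_sensitivity`.
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(sens, path) {
  stopifnot(inherits(sens, "ecx_sensitivity"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(sens), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    write_csv_with_header(as.data.frame(sens), path,
                          ecx_metadata_header(NULL, "sensitivity report"))
  }
  invisible(path)
}
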