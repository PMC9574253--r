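#' Temperature-humidity index (THI)
#'
#' Combines dry-bulb temperature and relative humidity into the standard
#' livestock heat-load index
#' \deqn{THI = F - 0.55 \cdot (RH/100) \cdot (F - 58), \quad F = 1.8\,DBT + 32,}
#' i.e. the dry-bulb temperature in Fahrenheit discounted by a humidity
#' correction that vanishes at F = 58. Values above roughly 72 indicate
#' heat stress in sheep; above ~90, severe stress.
#'
#' @param dbt Dry-bulb temperature, degrees Celsius (vectorized).
#' @param rh Relative humidity, percent (0-100; vectorized).
#' @return THI values (dimensionless), full precision. Round to one
#'   decimal for reporting.
#' @examples
#' round(thi(28.5, 53.8), 1)  # 75.8
#' @export
thi <- function(dbt, rh) {
  if (!is.numeric(dbt) || !is.numeric(rh)) stop_validation("dbt and rh must be numeric")
  if (any(is.na(rh)) || any(rh < 0 | rh > 100)) {
    stop_validation("rh must be within [0, 100]")
  }
  f <- 1.8 * dbt + 32
  f - 0.55 * (rh / 100) * (f - 58)
}

#' Tidal volume from minute gas volume and respiration rate
#'
#' @param gv Gas volume (minute ventilation), L/min.
#' @param rr Respiration rate, breaths/min; must be > 0.
#' @return Tidal volume, L/breath (`gv / rr`).
#' @export
tidal_volume <- function(gv, rr) {
  if (any(is.na(rr)) || any(rr <= 0)) stop_validation("rr must be > 0")
  if (any(gv < 0, na.rm = TRUE)) stop_validation("gv must be >= 0")
  gv / rr
}

#' Metabolic rate from gas exchange, per metabolic body size
#'
#' Energy expenditure from oxygen consumption and carbon-dioxide
#' production via the abbreviated Weir equation
#' (3.941 VO2 + 1.106 VCO2 kcal/min), scaled to a day and normalized by
#' metabolic body weight BW^0.75. The calorimetric coefficients are
#' exposed for other conventions (e.g. Brouwer).
#'
#' @param vo2 Oxygen consumption, L/min.
#' @param vco2 Carbon-dioxide production, L/min.
#' @param bw Body weight, kg; must be > 0.
#' @param coef Two calorimetric coefficients (kcal per litre of O2 and
#'   CO2 respectively).
#' @return Metabolic rate, kcal per kg^0.75 per day.
#' @examples
#' round(metabolic_rate(0.05, 0.04, 40), 2)  # 21.85
#' @export
metabolic_rate <- function(vo2, vco2, bw, coef = c(3.941, 1.106)) {
  if (any(is.na(bw)) || any(bw <= 0)) stop_validation("bw must be > 0")
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    stop_validation("vo2 and vco2 must be >= 0")
  }
  1440 * (coef[1L] * vo2 + coef[2L] * vco2) / bw^0.75
}

# The five scored physiological parameters, in reporting order.
.ahti_params <- c("RT", "ET", "RR", "TV", "MR")

#' Add derived columns (TV, MR) to a physiology panel
#'
#' @param panel Data frame with columns `animal_id`, `timepoint`
#'   (`"rest"`/`"stress"`), `RT`, `ET`, `RR`, `GV`, `VO2`, `VCO2`, `BW`.
#' @return The panel with `TV` (L/breath) and `MR`
#'   (kcal kg^-0.75 day^-1) columns appended.
#' @export
derive_physio <- function(panel) {
  req <- c("animal_id", "timepoint", "RT", "ET", "RR", "GV", "VO2", "VCO2", "BW")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop_validation("panel lacks columns: ", paste(miss, collapse = ", "))
  panel$TV <- tidal_volume(panel$GV, panel$RR)
  panel$MR <- metabolic_rate(panel$VO2, panel$VCO2, panel$BW)
  panel
}

#' Animal heat-tolerance index (AHTI)
#'
#' Scores each animal 0-5 by counting, over the five parameters RT, ET,
#' RR, TV and MR, those whose rest-to-stress change is at least twice the
#' parameter's at-rest standard deviation. 0 is the most heat-tolerant
#' animal, 5 the least.
#'
#' The rest SD is the cross-animal SD of rest values (the only estimable
#' baseline when each animal is measured once at rest); a pre-computed
#' per-parameter SD can be supplied instead. By default the absolute
#' change is compared to the threshold, so parameters that fall under
#' stress (typically TV) can still flag; set `signed = TRUE` to count
#' only changes in the direction of the stress response's sign.
#'
#' @param panel Physiology panel (see [derive_physio()]; TV/MR are derived
#'   on the fly if absent). Exactly one rest and one stress row per animal.
#' @param sd_baseline `"compute"` (default) or a named numeric vector of
#'   rest SDs for RT, ET, RR, TV, MR.
#' @param signed Use the signed change instead of its absolute value.
#' @return Data frame with `animal_id`, one logical flag column per
#'   parameter (`flag_RT`, ...), and the integer `ahti` (0-5).
#' @export
ahti_score <- function(panel, sd_baseline = "compute", signed = FALSE) {
  if (!all(c("TV", "MR") %in% names(panel))) panel <- derive_physio(panel)
  panel$timepoint <- as.character(panel$timepoint)
  if (!all(panel$timepoint %in% c("rest", "stress"))) {
    stop_validation("timepoint must be 'rest' or 'stress'")
  }
  rest <- panel[panel$timepoint == "rest", , drop = FALSE]
  stress <- panel[panel$timepoint == "stress", , drop = FALSE]
  ids <- sort(unique(panel$animal_id))
  if (!setequal(rest$animal_id, ids) || !setequal(stress$animal_id, ids) ||
      anyDuplicated(rest$animal_id) || anyDuplicated(stress$animal_id)) {
    stop_validation("every animal needs exactly one rest and one stress row")
  }
  rest <- rest[match(ids, rest$animal_id), , drop = FALSE]
  stress <- stress[match(ids, stress$animal_id), , drop = FALSE]

  if (identical(sd_baseline, "compute")) {
    if (length(ids) < 2L) {
      stop_validation("need >= 2 animals to compute the rest SD baseline")
    }
    sds <- vapply(.ahti_params, function(p) stats::sd(rest[[p]]), numeric(1))
  } else {
    if (!all(.ahti_params %in% names(sd_baseline))) {
      stop_validation("sd_baseline must name all of ", paste(.ahti_params, collapse = ", "))
    }
    sds <- unlist(sd_baseline[.ahti_params])
  }

  flags <- matrix(FALSE, length(ids), length(.ahti_params),
                  dimnames = list(NULL, paste0("flag_", .ahti_params)))
  for (k in seq_along(.ahti_params)) {
    p <- .ahti_params[k]
    delta <- stress[[p]] - rest[[p]]
    if (!signed) delta <- abs(delta)
    if (sds[k] > 0) {
      flags[, k] <- delta >= 2 * sds[k]
    } else {
      warning("zero rest SD for ", p, "; flagging any nonzero change")
      flags[, k] <- delta > 0
    }
  }
  out <- data.frame(animal_id = ids, flags, ahti = as.integer(rowSums(flags)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate THI for a meteorological table
#'
#' @param meteo Data frame with columns `location`, `clock_time`, `DBT`,
#'   `RH` (e.g. from [simulate_meteo()]).
#' @return The table with a `THI` column appended (full precision).
#' @export
thi_table <- function(meteo) {
  req <- c("location", "clock_time", "DBT", "RH")
  miss <- setdiff(req, names(meteo))
  if (length(miss)) stop_validation("meteo lacks columns: ", paste(miss, collapse = ", "))
  meteo$THI <- thi(meteo$DBT, meteo$RH)
  meteo
}
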