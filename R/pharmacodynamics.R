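#' Tumor volume from caliper measurements
#'
#' `TV (mm^3) = length * width^2 * pi / 6`, with length and width the
#' longest and shortest tumor diameters. If a width exceeds its length the
#' two are swapped with a warning.
#'
#' @param length_mm,width_mm Caliper diameters in mm (vectorized).
#' @return Tumor volumes in mm^3.
#' @examples
#' tumor_volume(10, 10) # 523.6
#' tumor_volume(12, 6)  # 226.2
#' @export
tumor_volume <- function(length_mm, width_mm) {
  stopifnot(all(length_mm >= 0), all(width_mm >= 0))
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length: swapped")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 * pi / 6
}

add_tumor_volume <- function(study) {
  stopifnot(all(c("animal", "day", "length_mm", "width_mm") %in%
                  names(study)))
  study$tv <- tumor_volume(study$length_mm, study$width_mm)
  study
}

# Arm mean tumor volume at a day, linearly interpolating each animal within
# its observed range (never extrapolating; animals without coverage at the
# day are dropped).
arm_mean_tv <- function(study, arm, day) {
  s <- study[study$arm == arm, , drop = FALSE]
  if (!nrow(s)) stop("no measurements for arm '", arm, "'")
  vals <- vapply(split(s, s$animal), function(d) {
    d <- d[order(d$day), ]
    approx(d$day, d$tv, xout = day, rule = 1)$y
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Treated-to-control tumor growth ratio (deltaT/deltaC)
#'
#' `100 * (meanTV_T(day) - meanTV_T(0)) / (meanTV_C(day) - meanTV_C(0))`:
#' tumor-volume changes relative to the initial arm means, treated over
#' control, at a specific day. Undefined (error) when the control arm has
#' not grown by that day.
#'
#' @param study Measurement data.frame (`arm`, `animal`, `day`,
#'   `length_mm`, `width_mm`).
#' @param day Evaluation day; missing measurement days are interpolated
#'   within each animal's observed range.
#' @param treated_arm,control_arm Arm labels.
#' @return Percentage (negative under regression below baseline).
#' @export
delta_t_over_c <- function(study, day, treated_arm = "treated",
                           control_arm = "vehicle") {
  study <- add_tumor_volume(study)
  dT <- arm_mean_tv(study, treated_arm, day) -
    arm_mean_tv(study, treated_arm, 0)
  dC <- arm_mean_tv(study, control_arm, day) -
    arm_mean_tv(study, control_arm, 0)
  if (!is.finite(dC) || dC <= 0) {
    stop("control arm did not grow by day ", day,
         " (deltaC = ", format(dC), "): deltaT/deltaC undefined")
  }
  100 * dT / dC
}

#' Tumor-growth-inhibition band from deltaT/deltaC
#'
#' Response when deltaT/deltaC < 0%, partial response in the closed band
#' 0-50%, no response above 50%.
#'
#' @param dtc deltaT/deltaC percentage (vectorized, finite).
#' @return Character vector: `"response"`, `"partial"`, `"none"`.
#' @examples
#' classify_tgi(c(-10, 50, 75))
#' @export
classify_tgi <- function(dtc) {
  stopifnot(all(is.finite(dtc)))
  ifelse(dtc < 0, "response", ifelse(dtc <= 50, "partial", "none"))
}

#' Per-animal response statistics (BestResponse, BestAvgResponse)
#'
#' From the percent volume change series `dV%(t) = 100 (TV(t) - TV(0)) /
#' TV(0)` over post-baseline measurements. The default `minimum` mode
#' follows the mRECIST framework convention: BestResponse is the minimum
#' dV% at `t >= t_min`, BestAvgResponse the minimum over t of the running
#' mean of dV% up to t. The `last_day` mode uses only the final measurement
#' for both, matching the simpler "change at the last day of treatment"
#' reading; the mode used is recorded in the output.
#'
#' @param days,volumes Measurement days (including day 0) and tumor
#'   volumes.
#' @param mode `"minimum"` or `"last_day"`.
#' @param t_min Earliest day eligible for BestResponse / BestAvgResponse.
#' @return list: `best_response`, `best_avg_response`, `mode`.
#' @export
response_statistics <- function(days, volumes,
                                mode = c("minimum", "last_day"),
                                t_min = 0) {
  mode <- match.arg(mode)
  stopifnot(length(days) == length(volumes), all(volumes >= 0))
  o <- order(days)
  days <- days[o]
  volumes <- volumes[o]
  if (days[1] != 0) stop("series needs a day-0 baseline measurement")
  if (length(days) < 2) stop("need at least one post-baseline measurement")
  v0 <- volumes[1]
  post <- days > 0
  dv <- 100 * (volumes[post] - v0) / v0
  tpost <- days[post]
  if (mode == "last_day") {
    last <- dv[length(dv)]
    return(list(best_response = last, best_avg_response = last,
                mode = mode))
  }
  elig <- tpost >= t_min
  if (!any(elig)) stop("no measurement at or after t_min = ", t_min)
  running_mean <- cumsum(dv) / seq_along(dv)
  list(best_response = min(dv[elig]),
       best_avg_response = min(running_mean[elig]),
       mode = mode)
}

#' mRECIST response category
#'
#' Categories are tested in order and the first satisfied wins: complete
#' response when BestResponse < -95 and BestAvgResponse < -40; partial
#' response when BestResponse < -50 and BestAvgResponse < -20; stable
#' disease when BestResponse < 35 and BestAvgResponse < 30; otherwise
#' progressive disease. Total on all finite inputs.
#'
#' @param best,bestavg BestResponse and BestAvgResponse percentages
#'   (vectorized).
#' @return Character vector: `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @examples
#' mrecist_classify(-97, -45) # CR
#' mrecist_classify(0, 0)     # SD
#' @export
mrecist_classify <- function(best, bestavg) {
  stopifnot(all(is.finite(best)), all(is.finite(bestavg)))
  ifelse(best < -95 & bestavg < -40, "CR",
  ifelse(best < -50 & bestavg < -20, "PR",
  ifelse(best < 35 & bestavg < 30, "SD", "PD")))
}

#' Truncate a study at the ethical tumor-volume cap
#'
#' Studies run until one animal exceeds the ethical limit, at which point
#' the whole study stops; all arms are truncated at that first measurement
#' day (the capped day itself is kept — it was measured).
#'
#' @param study Measurement data.frame.
#' @param cap_mm3 Ethical tumor-volume limit (mm^3).
#' @return list: `study` (truncated), `stop_day` (NA if never capped).
#' @export
apply_ethical_censoring <- function(study, cap_mm3 = 1500) {
  study <- add_tumor_volume(study)
  over <- study$day[study$tv > cap_mm3]
  stop_day <- if (length(over)) min(over) else NA_real_
  if (!is.na(stop_day)) study <- study[study$day <= stop_day, , drop = FALSE]
  study$tv <- NULL
  list(study = study, stop_day = stop_day)
}

#' End-to-end analysis of a caliper growth study
#'
#' Applies ethical censoring, computes per-animal response statistics and
#' mRECIST categories, and per treated arm the deltaT/deltaC at the
#' evaluation day (last day with measurements in both arms unless given)
#' with its TGI band and an mRECIST tally.
#'
#' @param study Measurement data.frame (`study`, `arm`, `animal`, `day`,
#'   `length_mm`, `width_mm`).
#' @param control_arm Control arm label.
#' @param mode,t_min See [response_statistics()].
#' @param cap_mm3 Ethical cap; see [apply_ethical_censoring()].
#' @param eval_day deltaT/deltaC evaluation day (default: last common day).
#' @return list of class `pdx_response`: `per_animal`, `per_arm`,
#'   `stop_day`, `eval_day`, `mode`.
#' @examples
#' d <- growth_study_design(n_per_arm = 4, treatment_effect = 0,
#'                          noise_cv = 0, seed = 3)
#' analyze_growth_study(gen_growth_study(d))
#' @export
analyze_growth_study <- function(study, control_arm = "vehicle",
                                 mode = "minimum", cap_mm3 = 1500,
                                 t_min = 0, eval_day = NULL) {
  cens <- apply_ethical_censoring(study, cap_mm3)
  study <- add_tumor_volume(cens$study)
  arms <- unique(study$arm)
  if (!control_arm %in% arms) {
    stop("control arm '", control_arm, "' absent from study")
  }
  per_animal <- do.call(rbind, lapply(split(study, study$animal),
                                      function(d) {
    st <- response_statistics(d$day, d$tv, mode = mode, t_min = t_min)
    data.frame(animal = d$animal[1], arm = d$arm[1],
               best_response = st$best_response,
               best_avg_response = st$best_avg_response,
               mrecist = mrecist_classify(st$best_response,
                                          st$best_avg_response))
  }))
  rownames(per_animal) <- NULL
  treated_arms <- setdiff(arms, control_arm)
  per_arm <- do.call(rbind, lapply(treated_arms, function(a) {
    common <- intersect(study$day[study$arm == a],
                        study$day[study$arm == control_arm])
    ed <- if (is.null(eval_day)) max(common) else eval_day
    dtc <- delta_t_over_c(study, ed, treated_arm = a,
                          control_arm = control_arm)
    tally <- table(factor(per_animal$mrecist[per_animal$arm == a],
                          levels = c("CR", "PR", "SD", "PD")))
    data.frame(arm = a, eval_day = ed, dtc = dtc,
               tgi_band = classify_tgi(dtc),
               CR = as.integer(tally["CR"]), PR = as.integer(tally["PR"]),
               SD = as.integer(tally["SD"]), PD = as.integer(tally["PD"]))
  }))
  rownames(per_arm) <- NULL
  structure(list(per_animal = per_animal, per_arm = per_arm,
                 stop_day = cens$stop_day,
                 eval_day = if (is.null(per_arm)) NA else per_arm$eval_day,
                 mode = mode),
            class = "pdx_response")
}

#' @export
print.pdx_response <- function(x, ...) {
  cat("PDX growth study (", x$mode, " mode)\n", sep = "")
  if (!is.null(x$per_arm)) print(x$per_arm)
  invisible(x)
}
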