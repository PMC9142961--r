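# Tumor-volume computation, doubling-time fitting with the shrinking-tumor
# exclusion rule, humane-endpoint event construction, and Kaplan-Meier /
# log-rank survival analysis (product-limit machinery via the survival
# package).

#' Ellipsoid tumor volume from caliper radii
#'
#' `V = 4/3 * pi * a * b * c` with `a`, `b`, `c` the tumor radii in mm.
#'
#' @param a,b,c tumor radii, mm (all > 0); vectorised.
#' @return volume in mm^3.
#' @examples
#' ellipsoid_volume(1, 1, 1) # unit sphere, 4*pi/3
#' @export
ellipsoid_volume <- function(a, b, c) {
  if (any(!is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    stop("all radii must be positive", call. = FALSE)
  4 / 3 * pi * a * b * c
}

#' Fit an exponential growth curve and report the doubling time
#'
#' Log-linear least squares of `ln V` against study day; the doubling time is
#' `ln 2 / slope`. Exact on noiseless exponentials for any sampling grid.
#' Animals whose fitted slope is not positive (shrinking tumors) are flagged
#' `included = FALSE` with an undefined doubling time -- an exclusion, not an
#' error.
#'
#' @param day measurement days.
#' @param volume tumor volumes, mm^3 (> 0).
#' @param animal_id optional label.
#' @return object of class `"growth_fit"`: `animal_id`, `V0`, `rate` (1/day),
#'   `doubling_time` (days), `r_squared`, `included`, `reason`, `n_points`.
#' @export
fit_doubling_time <- function(day, volume, animal_id = NA_character_) {
  if (length(day) != length(volume))
    stop("`day` and `volume` lengths differ", call. = FALSE)
  if (length(day) < 3L)
    stop("at least 3 measurements are required", call. = FALSE)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volumes must be positive", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, day), log(volume))
  slope <- fit$coefficients[[2L]]
  lv <- log(volume)
  r2 <- if (stats::var(lv) > 0) 1 - sum(fit$residuals^2) / sum((lv - mean(lv))^2)
        else NA_real_
  included <- is.finite(slope) && slope > 0
  structure(list(animal_id = animal_id,
                 V0 = exp(fit$coefficients[[1L]]),
                 rate = slope,
                 doubling_time = if (included) log(2) / slope else NA_real_,
                 r_squared = r2, included = included,
                 reason = if (included) NA_character_ else "tumor size decreased",
                 n_points = length(day)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$included)
    cat(sprintf("<growth_fit> %s Td = %.3g d (rate %.4g /d, R2 %.3f, %d pts)\n",
                x$animal_id, x$doubling_time, x$rate, x$r_squared, x$n_points))
  else
    cat(sprintf("<growth_fit> %s excluded (%s)\n", x$animal_id, x$reason))
  invisible(x)
}

#' Per-animal growth fits for a cohort
#'
#' @param tumors data.frame with `animal_id`, `group`, `day` and either
#'   radii `a`, `b`, `c` or a `volume` column.
#' @param min_points animals with fewer measurements are skipped.
#' @return data.frame of per-animal fits (one row per animal).
#' @export
fit_growth_cohort <- function(tumors, min_points = 3L) {
  if (!"volume" %in% names(tumors))
    tumors$volume <- ellipsoid_volume(tumors$a, tumors$b, tumors$c)
  sp <- split(tumors, tumors$animal_id)
  out <- lapply(sp, function(d) {
    if (nrow(d) < min_points) return(NULL)
    f <- fit_doubling_time(d$day, d$volume, animal_id = d$animal_id[1L])
    data.frame(animal_id = f$animal_id, group = d$group[1L], V0 = f$V0,
               rate = f$rate, doubling_time = f$doubling_time,
               r_squared = f$r_squared, included = f$included,
               n_points = f$n_points, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Humane-endpoint thresholds
#'
#' Defaults: tumor volume >= 2 cm^3, acute weight loss > 15% within 2 days,
#' chronic weight loss > 20% from baseline, study end at day 150
#' post-inoculation.
#'
#' @param volume_mm3 tumor-volume endpoint, mm^3.
#' @param acute_loss fractional acute weight-loss threshold.
#' @param acute_window_days window of the acute rule, days.
#' @param chronic_loss fractional baseline weight-loss threshold.
#' @param study_end censoring day.
#' @return a list of thresholds.
#' @export
endpoint_thresholds <- function(volume_mm3 = 2000, acute_loss = 0.15,
                                acute_window_days = 2, chronic_loss = 0.20,
                                study_end = 150) {
  list(volume_mm3 = volume_mm3, acute_loss = acute_loss,
       acute_window_days = acute_window_days, chronic_loss = chronic_loss,
       study_end = study_end)
}

#' Convert one animal's trajectories into a survival record
#'
#' The earliest rule crossing becomes the event; the cause is one of
#' `volume`, `ulceration`, `weight-loss-acute`, `weight-loss-chronic`,
#' `clinical` (ties broken in that order). The acute rule is evaluated on a
#' daily grid with linear interpolation between weigh-ins; baseline weight is
#' the first recorded weight. Without any crossing by `study_end` the animal
#' is censored there (`cause = "study-end-censor"`, `event = FALSE`).
#'
#' @param volumes data.frame with `day`, `volume` (mm^3).
#' @param weights optional data.frame with `day`, `weight_g`.
#' @param flags optional data.frame with `day`, `cause` for endpoints that
#'   cannot be computed from numbers (`"ulceration"`, `"clinical"`).
#' @param thresholds an [endpoint_thresholds()] list.
#' @return list with `time`, `event`, `cause`.
#' @export
apply_humane_endpoints <- function(volumes, weights = NULL, flags = NULL,
                                   thresholds = endpoint_thresholds()) {
  if (is.null(volumes) || nrow(volumes) == 0L)
    stop("empty measurement series", call. = FALSE)
  volumes <- volumes[order(volumes$day), ]
  cand <- data.frame(day = numeric(0), cause = character(0))
  add <- function(day, cause) {
    if (length(day) && is.finite(day[1L]))
      rbind(cand, data.frame(day = day[1L], cause = cause))
    else cand
  }
  hit <- volumes$day[volumes$volume >= thresholds$volume_mm3]
  cand <- add(hit, "volume")
  if (!is.null(weights) && nrow(weights) >= 1L) {
    w <- weights[order(weights$day), ]
    base <- w$weight_g[1L]
    cand <- add(w$day[w$weight_g <= (1 - thresholds$chronic_loss) * base],
                "weight-loss-chronic")
    if (nrow(w) > 1L) {
      grid <- seq(min(w$day), max(w$day), by = 1)
      wi <- stats::approx(w$day, w$weight_g, xout = grid)$y
      k <- thresholds$acute_window_days
      idx <- which(grid >= min(w$day) + k)
      drop <- 1 - wi[idx] / wi[idx - k]
      cand <- add(grid[idx][drop > thresholds$acute_loss], "weight-loss-acute")
    }
  }
  if (!is.null(flags) && nrow(flags) >= 1L)
    for (i in seq_len(nrow(flags)))
      cand <- add(flags$day[i], flags$cause[i])
  cand <- cand[cand$day <= thresholds$study_end, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(list(time = thresholds$study_end, event = FALSE,
                cause = "study-end-censor"))
  prio <- c("volume", "ulceration", "weight-loss-acute",
            "weight-loss-chronic", "clinical")
  cand <- cand[order(cand$day, match(cand$cause, prio)), ]
  list(time = cand$day[1L], event = TRUE, cause = cand$cause[1L])
}

#' Build survival records for a whole cohort
#'
#' @param tumors data.frame with `animal_id`, `group`, `day`, and radii
#'   `a`, `b`, `c` or `volume`.
#' @param weights optional data.frame with `animal_id`, `day`, `weight_g`.
#' @param flags optional data.frame with `animal_id`, `day`, `cause`.
#' @param thresholds an [endpoint_thresholds()] list.
#' @return data.frame: `animal_id`, `group`, `time`, `event`, `cause`.
#' @export
build_survival <- function(tumors, weights = NULL, flags = NULL,
                           thresholds = endpoint_thresholds()) {
  if (!"volume" %in% names(tumors))
    tumors$volume <- ellipsoid_volume(tumors$a, tumors$b, tumors$c)
  out <- lapply(split(tumors, tumors$animal_id), function(d) {
    id <- d$animal_id[1L]
    w <- if (!is.null(weights)) weights[weights$animal_id == id, ] else NULL
    f <- if (!is.null(flags)) flags[flags$animal_id == id, ] else NULL
    rec <- apply_humane_endpoints(d[c("day", "volume")], w, f, thresholds)
    data.frame(animal_id = id, group = d$group[1L], time = rec$time,
               event = rec$event, cause = rec$cause, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via `survival::survfit`). The median is the first
#' time the survival probability drops to 0.5 or below; when the curve never
#' does, the median is reported as not reached (`NA` with a `"> end"` label),
#' matching the convention of reporting "median survival > study end".
#'
#' @param records data.frame with `time` (> 0) and `event` (logical or 0/1).
#' @return object of class `"km_curve"`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `median`, `median_reached`, `n`, and the underlying
#'   `survfit` object.
#' @export
km_curve <- function(records) {
  if (nrow(records) < 1L) stop("at least one record is required", call. = FALSE)
  if (any(records$time <= 0)) stop("times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.type = "none")
  med_idx <- which(fit$surv <= 0.5)
  med <- if (length(med_idx)) fit$time[med_idx[1L]] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv, median = med,
                 median_reached = length(med_idx) > 0,
                 n = nrow(records), survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (x$median_reached) sprintf("%g", x$median)
         else sprintf("not reached (> %g)", max(x$time))
  cat(sprintf("<km_curve> n = %d, %d events, median survival %s\n",
              x$n, sum(x$n_event), med))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom (via
#' `survival::survdiff`), two-sided p-value. Comparing a group with itself
#' gives statistic 0 and p = 1; with no events in either group the test is
#' undefined and an error is signalled.
#'
#' @param a,b data.frames with `time` and `event` for the two groups.
#' @return list with `statistic` (chi-square), `df`, `p`, `n`, `n_events`.
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  d <- rbind(data.frame(time = a$time, event = as.logical(a$event), g = "A"),
             data.frame(time = b$time, event = as.logical(b$event), g = "B"))
  if (sum(d$event) == 0L)
    stop("log-rank test undefined: no events in either group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  stat <- sd$chisq
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       n = nrow(d), n_events = sum(d$event))
}

#' Pairwise log-rank comparisons against a control group
#'
#' Each treated group against the control, unadjusted by default (Holm
#' adjustment available by flag).
#'
#' @param records survival records with `group`, `time`, `event`.
#' @param control name of the reference group.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per comparison.
#' @export
pairwise_logrank <- function(records, control, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  ctrl <- records[records$group == control, ]
  if (nrow(ctrl) == 0L) stop("control group not found", call. = FALSE)
  others <- setdiff(unique(records$group), control)
  out <- do.call(rbind, lapply(others, function(g) {
    lr <- logrank_test(records[records$group == g, ], ctrl)
    data.frame(group = g, control = control, statistic = lr$statistic,
               p = lr$p, stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}
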