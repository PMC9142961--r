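# Synthetic-data generators: counting traces, biodistribution cohorts,
# therapy cohorts. Every generator takes an integer seed and is deterministic
# for a fixed seed; each emits the ground truth it sampled from alongside the
# simulated measurements so that downstream reductions can be round-tripped.

.kbq_dpm <- 60000 # decays per minute per kBq

.check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  as.integer(seed)
}

# lognormal parameterised by mean and coefficient of variation
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Gamma-counter model for simulation
#'
#' The analysis itself is relative (samples against simultaneously counted
#' standards) so absolute efficiency cancels; simulation still needs one.
#' Defaults are documented choices, not measured values: per-window photopeak
#' efficiencies of a NaI well counter, a small flat background, 5-min bins
#' over a 12-h trace.
#'
#' @param window_efficiencies named counts-per-decay efficiencies in (0, 1],
#'   one per counting window.
#' @param background_rate background in counts/min (scalar, applied per window).
#' @param bin_duration trace bin width, minutes.
#' @param trace_duration total continuous-trace length, minutes.
#' @return object of class `"counter_model"`.
#' @export
counter_model <- function(window_efficiencies = c(Fr221 = 0.35, Bi213 = 0.25,
                                                  Lu177 = 0.30),
                          background_rate = 1, bin_duration = 5,
                          trace_duration = 720) {
  if (any(window_efficiencies <= 0) || any(window_efficiencies > 1))
    stop("window efficiencies must lie in (0, 1]", call. = FALSE)
  if (background_rate < 0) stop("`background_rate` must be >= 0", call. = FALSE)
  if (bin_duration <= 0) stop("`bin_duration` must be > 0", call. = FALSE)
  if (trace_duration < bin_duration)
    stop("`trace_duration` must cover at least one bin", call. = FALSE)
  structure(list(window_efficiencies = window_efficiencies,
                 background_rate = background_rate,
                 bin_duration = bin_duration,
                 trace_duration = trace_duration),
            class = "counter_model")
}

#' Per-organ ground truth for biodistribution simulation
#'
#' `free_ratio` is the ratio R of total Bi-213 at dissection to the
#' Ac-225-supported Bi-213: R > 1 models an organ accumulating relocated
#' daughter (kidney-like excess), R < 1 an organ whose daughter is carried
#' away (blood-like deficit), R = 1 pure equilibrium.
#'
#' @param organ organ label.
#' @param uptake mean parent uptake, %IA/g.
#' @param cv inter-animal coefficient of variation of the uptake (lognormal).
#' @param mass_g mean sample mass, grams.
#' @param mass_cv coefficient of variation of the sample mass.
#' @param free_ratio ratio R of total to supported Bi-213 at dissection.
#' @return one-row data.frame; rbind rows to build a truth table.
#' @export
organ_truth <- function(organ, uptake, cv = 0.2, mass_g = 0.3, mass_cv = 0.1,
                        free_ratio = 1) {
  if (uptake < 0 || cv < 0 || free_ratio < 0 || mass_g <= 0 || mass_cv < 0)
    stop("organ truth parameters out of range", call. = FALSE)
  data.frame(organ = organ, uptake = uptake, cv = cv, mass_g = mass_g,
             mass_cv = mass_cv, free_ratio = free_ratio,
             stringsAsFactors = FALSE)
}

#' Example organ truth table
#'
#' Organ means shaped like a day-3 Ac-225-antibody biodistribution in a
#' subcutaneous xenograft model: high tumor uptake, blood-pool still present,
#' kidney carrying a large excess of relocated Bi-213 and blood a deficit.
#'
#' @return a truth data.frame consumable by [simulate_biodistribution_cohort()].
#' @export
example_organ_truths <- function() {
  rbind(
    organ_truth("tumor",  110.6, cv = 34.6 / 110.6, mass_g = 0.15, free_ratio = 1),
    organ_truth("blood",  13.9,  cv = 2.1 / 13.9,   mass_g = 0.20, free_ratio = 0.2),
    organ_truth("kidney", 10.0,  cv = 0.25,         mass_g = 0.30, free_ratio = 5),
    organ_truth("liver",  8.0,   cv = 0.25,         mass_g = 1.00, free_ratio = 1),
    organ_truth("spleen", 6.0,   cv = 0.30,         mass_g = 0.10, free_ratio = 1),
    organ_truth("muscle", 1.5,   cv = 0.30,         mass_g = 0.25, free_ratio = 1)
  )
}

#' Simulate a continuous Bi-213-window counting trace
#'
#' Emulates placing a dissected sample in the counter immediately after
#' dissection and counting continuously. The sample holds parent activity
#' `A_parent_t0` (kBq) with Fr-221 in equilibrium and total Bi-213 equal to
#' `R` times its supported level. Per-bin counts are Poisson with expectation
#' `eff * dt * A_Bi(t_mid) * 60000 + background * dt`; the free component
#' (R - 1 times the supported level at dissection) decays with the Bi-213
#' half-life while the supported component follows the parent. A delayed
#' Fr-221-window record and a Bi-213-window equilibrium record are emitted at
#' `delayed_at_h` hours.
#'
#' @param A_parent_t0 parent (Ac-225) activity in the sample at dissection, kBq.
#' @param R total-to-supported Bi-213 ratio at dissection (>= 0).
#' @param counter a [counter_model()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param chain a [decay_chain()]; default collapsed Ac-225 chain.
#' @param sample_id sample label.
#' @param delayed_at_h delay of the late records, hours after dissection.
#' @param delayed_duration duration of the late records, minutes.
#' @param noise logical; `FALSE` returns the Poisson expectations themselves
#'   (the noiseless limit used for validation).
#' @return list with `trace` (bin table), `delayed` (two late records),
#'   and `truth` (free/supported activities at dissection).
#' @export
simulate_counting_trace <- function(A_parent_t0, R, counter = counter_model(),
                                    seed = 1L, chain = ac225_chain(),
                                    sample_id = "S1", delayed_at_h = 24,
                                    delayed_duration = 10, noise = TRUE) {
  seed <- .check_seed(seed)
  if (!is.numeric(A_parent_t0) || A_parent_t0 < 0)
    stop("`A_parent_t0` must be >= 0", call. = FALSE)
  if (R < 0) stop("`R` must be >= 0", call. = FALSE)
  set.seed(seed)

  parent <- chain$names[1L]
  eqs <- equilibrium_state(chain, parent)
  a_sup0 <- A_parent_t0 * eqs[["Bi-213"]]
  init <- A_parent_t0 * eqs
  init[["Bi-213"]] <- R * a_sup0

  dt <- counter$bin_duration
  starts <- seq(0, counter$trace_duration - dt, by = dt)
  mids <- starts + dt / 2
  abi <- if (A_parent_t0 > 0)
    bateman_activities(chain, init, c(mids, 0))[, "Bi-213"]
  else rep(0, length(mids) + 1L)
  mu <- counter$window_efficiencies[["Bi213"]] * dt * abi[seq_along(mids)] *
    .kbq_dpm + counter$background_rate * dt
  counts <- if (noise) stats::rpois(length(mu), mu) else mu
  trace <- data.frame(sample_id = sample_id, bin_start = starts,
                      bin_duration = dt, window = "Bi213", counts = counts,
                      stringsAsFactors = FALSE)

  tdel <- delayed_at_h * 60
  late <- bateman_activities(chain, init, tdel)$activities
  mu_fr <- counter$window_efficiencies[["Fr221"]] * delayed_duration *
    late[["Fr-221"]] * .kbq_dpm + counter$background_rate * delayed_duration
  mu_bi <- counter$window_efficiencies[["Bi213"]] * delayed_duration *
    late[["Bi-213"]] * .kbq_dpm + counter$background_rate * delayed_duration
  delayed <- data.frame(
    sample_id = sample_id, start_time = tdel, duration = delayed_duration,
    window = c("Fr221", "Bi213"),
    counts = if (noise) stats::rpois(2L, c(mu_fr, mu_bi)) else c(mu_fr, mu_bi),
    stringsAsFactors = FALSE)

  list(trace = trace, delayed = delayed,
       truth = list(A_parent_t0 = A_parent_t0,
                    A_supported_t0 = unname(a_sup0),
                    A_free_t0 = unname((R - 1) * a_sup0),
                    R = R))
}

#' Simulate a biodistribution cohort with delayed-window counting
#'
#' For each timepoint and organ, `n_per_timepoint` animals draw a lognormal
#' uptake (%IA/g) and sample mass around the organ truth. Samples are counted
#' in the Fr-221 window at `count_delay_h` hours after dissection (once only
#' parent-supported progeny remains); three 1%-of-injected-dose aliquots are
#' counted simultaneously per run. Counts are Poisson; decay to the counting
#' time affects samples and standards identically, as in the real protocol.
#'
#' @param truths organ truth table ([organ_truth()] rows).
#' @param n_per_timepoint animals per timepoint.
#' @param timepoints dissection days post-injection.
#' @param injected_activity injected activity per animal, kBq.
#' @param counter a [counter_model()].
#' @param chain a [decay_chain()].
#' @param seed integer seed.
#' @param count_delay_h delay between dissection and counting, hours.
#' @param count_duration per-sample counting time, minutes.
#' @param n_standards number of standard aliquots per run.
#' @return list of data.frames: `counts` (one record per sample),
#'   `standards` (per run and window) and `truth` (per-animal sampled truth).
#' @export
simulate_biodistribution_cohort <- function(truths, n_per_timepoint = 5,
                                            timepoints = c(1, 3, 7),
                                            injected_activity = 50,
                                            counter = counter_model(),
                                            chain = ac225_chain(), seed = 1L,
                                            count_delay_h = 24,
                                            count_duration = 10,
                                            n_standards = 3L) {
  seed <- .check_seed(seed)
  if (is.null(truths) || nrow(truths) == 0L)
    stop("`truths` must contain at least one organ", call. = FALSE)
  if (n_per_timepoint < 1L) stop("`n_per_timepoint` must be >= 1", call. = FALSE)
  if (!length(timepoints)) stop("`timepoints` must be non-empty", call. = FALSE)
  set.seed(seed)

  parent <- chain$names[1L]
  lam_p <- chain$lambda[1L]
  r_fr <- equilibrium_ratio(chain, parent, "Fr-221")
  eff <- counter$window_efficiencies[["Fr221"]]
  bg <- counter$background_rate

  counts <- list(); standards <- list(); truth <- list()
  for (tp in timepoints) {
    t_count <- tp * 1440 + count_delay_h * 60 # minutes post-injection
    a_inj_decayed <- injected_activity * exp(-lam_p * t_count)
    mu_std <- eff * count_duration * 0.01 * a_inj_decayed * r_fr * .kbq_dpm +
      bg * count_duration
    standards[[length(standards) + 1L]] <- data.frame(
      timepoint_day = tp, window = "Fr221", duration_min = count_duration,
      aliquot = seq_len(n_standards),
      counts = stats::rpois(n_standards, mu_std),
      fraction = 0.01, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(truths))) {
      tr <- truths[k, ]
      u <- .rlnorm_mean_cv(n_per_timepoint, tr$uptake, tr$cv)
      m <- .rlnorm_mean_cv(n_per_timepoint, tr$mass_g, tr$mass_cv)
      a_sample <- a_inj_decayed * u * m / 100 # kBq of parent at count time
      mu <- eff * count_duration * a_sample * r_fr * .kbq_dpm +
        bg * count_duration
      animal <- sprintf("d%g_m%d", tp, seq_len(n_per_timepoint))
      counts[[length(counts) + 1L]] <- data.frame(
        sample_id = paste0(animal, "_", tr$organ), animal_id = animal,
        organ = tr$organ, mass_g = m, window = "Fr221", timepoint_day = tp,
        dissection_time_h = tp * 24,
        start_time_h = tp * 24 + count_delay_h,
        duration_min = count_duration,
        counts = stats::rpois(n_per_timepoint, mu), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        animal_id = animal, organ = tr$organ, timepoint_day = tp,
        uptake_pct_ia_g = u, mass_g = m, free_ratio = tr$free_ratio,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts),
       standards = do.call(rbind, standards),
       truth = do.call(rbind, truth))
}

#' Simulate one organ sample for free/supported Bi-213 decomposition
#'
#' Wraps [simulate_counting_trace()] in the cohort bookkeeping needed by the
#' decomposition round trip: the sample's parent activity follows from its
#' uptake, the equilibrium Bi-213-window record at `t_eq` is accompanied by
#' simultaneously counted 1% standards, and the emitted truth is expressed in
#' %IA/g so that recovered decompositions can be compared directly.
#'
#' @param uptake parent uptake of the sample, %IA/g.
#' @param mass_g sample mass, grams.
#' @param R total-to-supported Bi-213 ratio at dissection.
#' @param injected_activity injected activity, kBq.
#' @param dissection_day dissection time, days post-injection.
#' @param counter a [counter_model()].
#' @param chain a [decay_chain()].
#' @param seed integer seed.
#' @param t_eq_h equilibrium-record delay, hours after dissection.
#' @param noise logical; `FALSE` gives the noiseless limit.
#' @return list: `trace`, `equilibrium` (record + standards), `truth`
#'   (supported/free %IA/g and ratio at dissection).
#' @export
simulate_bismuth_sample <- function(uptake = 10, mass_g = 0.3, R = 1,
                                    injected_activity = 50,
                                    dissection_day = 3,
                                    counter = counter_model(),
                                    chain = ac225_chain(), seed = 1L,
                                    t_eq_h = 24, noise = TRUE) {
  seed <- .check_seed(seed)
  lam_p <- chain$lambda[1L]
  a_parent <- injected_activity * exp(-lam_p * dissection_day * 1440) *
    uptake * mass_g / 100
  sim <- simulate_counting_trace(a_parent, R, counter = counter, seed = seed,
                                 chain = chain, delayed_at_h = t_eq_h,
                                 noise = noise)
  # standards counted simultaneously with the equilibrium record, Bi-213 window
  r_bi <- equilibrium_ratio(chain, chain$names[1L], "Bi-213")
  t_abs <- dissection_day * 1440 + t_eq_h * 60
  dur <- sim$delayed$duration[1L]
  mu_std <- counter$window_efficiencies[["Bi213"]] * dur * 0.01 *
    injected_activity * exp(-lam_p * t_abs) * r_bi * .kbq_dpm +
    counter$background_rate * dur
  std_counts <- if (noise) stats::rpois(3L, mu_std) else rep(mu_std, 3L)
  eq_rec <- sim$delayed[sim$delayed$window == "Bi213", ]
  list(trace = sim$trace,
       equilibrium = list(record = eq_rec,
                          standards = standard_set(std_counts, 0.01,
                                                   window = "Bi213",
                                                   duration = dur)),
       # %IA/g here is measured against equilibrated 1% standards in the same
       # window, so the Ac->Bi equilibrium ratio cancels sample/standard: the
       # supported Bi-213 uptake at equilibrium equals the parent uptake.
       truth = list(A_supported_pct_g = uptake,
                    A_free_pct_g = (R - 1) * uptake,
                    A_t0_pct_g = R * uptake,
                    R = R, mass_g = mass_g))
}

#' Group specification for therapy-cohort simulation
#'
#' Either a growing group (`doubling_time`, days, with lognormal inter-animal
#' spread `td_sdlog`) or a shrink-then-regrow group (`shrink_rate` < 0 per day
#' until `regrow_day`, then regrowth at `regrow_doubling` days).
#'
#' @param group group label.
#' @param n animals in the group.
#' @param v0_median median tumor volume at randomization, mm^3.
#' @param v0_sdlog lognormal log-sd of the initial volume.
#' @param doubling_time median tumor doubling time, days (growing groups).
#' @param td_sdlog lognormal log-sd of the per-animal doubling time.
#' @param shrink_rate negative growth rate 1/day (shrinking groups).
#' @param regrow_day study day at which regrowth starts.
#' @param regrow_doubling doubling time of the regrowth phase, days.
#' @return one-element list usable in [simulate_efficacy_cohort()].
#' @export
efficacy_group <- function(group, n = 10, v0_median = 82.9, v0_sdlog = 0.42,
                           doubling_time = 31.9, td_sdlog = 0.4,
                           shrink_rate = NULL, regrow_day = NULL,
                           regrow_doubling = NULL) {
  spec <- list(group = group, n = n, v0_median = v0_median,
               v0_sdlog = v0_sdlog, doubling_time = doubling_time,
               td_sdlog = td_sdlog, shrink_rate = shrink_rate,
               regrow_day = regrow_day, regrow_doubling = regrow_doubling)
  structure(list(spec), names = group)
}

# true volume trajectory of one animal at days since randomization
.volume_model <- function(v0, rate, shrink_rate, regrow_day, regrow_rate,
                          days, start_day) {
  if (is.null(shrink_rate)) return(v0 * exp(rate * (days - start_day)))
  if (is.null(regrow_day)) regrow_day <- Inf # shrink throughout the study
  t1 <- pmin(days, regrow_day) - start_day
  t2 <- pmax(days - regrow_day, 0)
  v0 * exp(shrink_rate * t1 + regrow_rate * t2)
}

#' Simulate a therapy cohort: caliper series, weights, ground truth
#'
#' Tumor radii are measured twice weekly (alternating 3/4-day intervals) from
#' `start_day` (randomization/treatment) until `study_end` or until the
#' measured volume first reaches `endpoint_volume`, whichever comes first,
#' mirroring animal removal at the humane endpoint. Each radius carries
#' multiplicative lognormal caliper noise. The emitted truth holds each
#' animal's initial volume, growth parameters, true doubling time and the
#' continuous-time day its true volume crosses the endpoint (NA if never).
#'
#' @param groups list of [efficacy_group()] specifications (concatenate with
#'   `c()`).
#' @param seed integer seed.
#' @param start_day first measurement day (days post-inoculation).
#' @param study_end predefined end of study, days post-inoculation.
#' @param caliper_cv multiplicative noise cv per radius.
#' @param endpoint_volume humane-endpoint volume, mm^3.
#' @param weight_mean,weight_sd baseline body-weight distribution, grams.
#' @param weight_cv per-weighing multiplicative noise cv.
#' @return list of data.frames: `tumors` (animal, group, day, a, b, c mm),
#'   `weights` (animal, group, day, weight_g), `truth`.
#' @export
simulate_efficacy_cohort <- function(groups, seed = 1L, start_day = 21,
                                     study_end = 150, caliper_cv = 0.05,
                                     endpoint_volume = 2000,
                                     weight_mean = 20.4, weight_sd = 1.2,
                                     weight_cv = 0.01) {
  seed <- .check_seed(seed)
  if (study_end <= start_day) stop("`study_end` must exceed `start_day`",
                                   call. = FALSE)
  set.seed(seed)
  steps <- rep(c(3, 4), length.out = 2 * ceiling((study_end - start_day) / 3))
  days <- start_day + c(0, cumsum(steps))
  days <- days[days <= study_end]
  sdlog_cal <- sqrt(log1p(caliper_cv^2))

  tumors <- list(); weights <- list(); truth <- list()
  for (g in groups) {
    if (!is.null(g$regrow_day) &&
        (g$regrow_day <= start_day || g$regrow_day >= study_end))
      stop("regrowth change-point must lie inside the study window",
           call. = FALSE)
    for (i in seq_len(g$n)) {
      id <- sprintf("%s_%02d", g$group, i)
      v0 <- stats::rlnorm(1, log(g$v0_median), g$v0_sdlog)
      if (is.null(g$shrink_rate)) {
        td <- if (g$td_sdlog > 0)
          stats::rlnorm(1, log(g$doubling_time), g$td_sdlog)
        else g$doubling_time
        rate <- log(2) / td
        v_true <- .volume_model(v0, rate, NULL, NULL, NULL, days, start_day)
        crossing <- if (v0 >= endpoint_volume) start_day
        else start_day + log(endpoint_volume / v0) / rate
        if (crossing > study_end) crossing <- NA_real_
      } else {
        td <- NA_real_
        rate <- NA_real_
        regrow_rate <- if (is.null(g$regrow_doubling)) 0
        else log(2) / g$regrow_doubling
        v_true <- .volume_model(v0, NULL, g$shrink_rate, g$regrow_day,
                                regrow_rate, days, start_day)
        crossing <- NA_real_
        if (regrow_rate > 0) {
          v_at_regrow <- v0 * exp(g$shrink_rate * (g$regrow_day - start_day))
          tc <- g$regrow_day + log(endpoint_volume / v_at_regrow) / regrow_rate
          if (tc <= study_end) crossing <- tc
        }
      }
      r_true <- (v_true / (4 / 3 * pi))^(1 / 3)
      a <- r_true * stats::rlnorm(length(days), 0, sdlog_cal)
      b <- r_true * stats::rlnorm(length(days), 0, sdlog_cal)
      cc <- r_true * stats::rlnorm(length(days), 0, sdlog_cal)
      vol <- ellipsoid_volume(a, b, cc)
      hit <- which(vol >= endpoint_volume)
      keep <- if (length(hit)) seq_len(hit[1L]) else seq_along(days)
      tumors[[length(tumors) + 1L]] <- data.frame(
        animal_id = id, group = g$group, day = days[keep],
        a = a[keep], b = b[keep], c = cc[keep], stringsAsFactors = FALSE)
      w0 <- stats::rnorm(1, weight_mean, weight_sd)
      wdays <- days[keep]
      weights[[length(weights) + 1L]] <- data.frame(
        animal_id = id, group = g$group, day = wdays,
        weight_g = w0 * stats::rlnorm(length(wdays), 0, sqrt(log1p(weight_cv^2))),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        animal_id = id, group = g$group, v0 = v0, rate = rate,
        true_doubling = td, true_crossing_day = crossing,
        stringsAsFactors = FALSE)
    }
  }
  list(tumors = do.call(rbind, tumors), weights = do.call(rbind, weights),
       truth = do.call(rbind, truth))
}
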