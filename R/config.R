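#' Build an appointment schedule under the double-booking rule
#'
#' Spreads `n_extra` overbooked outpatient slots across the day: every period
#' holds `base_per_period` outpatients, and one extra outpatient is added at
#' `start_period`, `start_period + gap`, `start_period + 2*gap`, and so on.
#' With the default clinic day (37 periods, 2 per period, 6 extras at stride
#' 6 from period 1) the triple-booked periods are 1, 7, 13, 19, 25 and 31.
#'
#' @param n_regular number of regular periods in the day.
#' @param base_per_period outpatients booked in every period.
#' @param n_extra number of overbooked (extra) outpatients.
#' @param start_period 1-based period receiving the first extra slot.
#' @param gap stride, in periods, between consecutive extra slots.
#' @return integer vector of length `n_regular`: outpatients booked per period.
#' @seealso [build_flight_overbooking()]
#' @export
build_double_overbooking <- function(n_regular, base_per_period, n_extra,
                                     start_period = 1L, gap = 6L) {
  stopifnot(n_regular >= 1, base_per_period >= 0, n_extra >= 0)
  sched <- rep.int(as.integer(base_per_period), n_regular)
  if (n_extra > 0) {
    at <- start_period + gap * (seq_len(n_extra) - 1L)
    if (any(at < 1L) || any(at > n_regular)) {
      stop("overbooked slot placement falls outside periods 1..", n_regular,
           " (requested periods ", paste(at, collapse = ", "), ")")
    }
    sched[at] <- sched[at] + 1L
  }
  sched
}

#' Build an appointment schedule under the flight-style rule
#'
#' Stacks all `n_extra` overbooked outpatients into the first period, the way
#' airlines oversell departures: period 1 holds `base_per_period + n_extra`
#' outpatients and every later period holds `base_per_period`.
#'
#' @inheritParams build_double_overbooking
#' @return integer vector of length `n_regular`.
#' @export
build_flight_overbooking <- function(n_regular, base_per_period, n_extra) {
  stopifnot(n_regular >= 1, base_per_period >= 0, n_extra >= 0)
  sched <- rep.int(as.integer(base_per_period), n_regular)
  sched[1L] <- sched[1L] + as.integer(n_extra)
  sched
}

#' Per-period service capacity of a mixed fast/slow scanner fleet
#'
#' Fast scanners finish an exam within one period and contribute one service
#' start every period. The (at most one) slow scanner needs two periods per
#' exam, so it contributes a start only on alternating periods. With
#' `slow_phase = 0` its first exam starts in period 1, giving the capacity
#' pattern `n_fast + n_slow, n_fast, n_fast + n_slow, ...`.
#'
#' @param n_regular number of regular periods.
#' @param n_fast number of fast (one-period) scanners.
#' @param n_slow number of slow (two-period) scanners; 0 or 1.
#' @param slow_phase 0 if the slow scanner starts in period 1, 1 if in period 2.
#' @return integer vector of per-period capacities (service starts).
#' @export
build_capacity_profile <- function(n_regular, n_fast, n_slow, slow_phase = 0L) {
  stopifnot(n_regular >= 1, n_fast >= 0, n_slow %in% c(0L, 1L),
            slow_phase %in% c(0L, 1L))
  cap <- rep.int(as.integer(n_fast), n_regular)
  if (n_slow == 1L) {
    at <- seq.int(1L + slow_phase, n_regular, by = 2L)
    cap[at] <- cap[at] + 1L
  }
  cap
}

#' Assemble and validate a capacity-allocation problem configuration
#'
#' Bundles every model parameter of the one-day allocation problem: horizon
#' sizes, per-period capacities, the outpatient appointment schedule,
#' slot-level show probabilities, Bernoulli arrival probabilities for
#' inpatients and emergency patients, and the unit costs. All invariants are
#' checked here so downstream code can assume a well-formed problem.
#'
#' @param n_regular number of regular periods N (>= 1).
#' @param n_overtime number of overtime periods K (>= 0).
#' @param regular_capacity integer vector, length N: service starts per period.
#' @param overtime_capacity integer vector, length K: capacity per overtime
#'   period (the overtime resources; at most two scanners are released for
#'   overtime because emergencies arriving after hours go to dedicated kit).
#' @param schedule integer vector, length N: outpatients booked per period.
#' @param show_probs show probabilities, one per booked outpatient slot:
#'   either a single scalar (recycled to every slot) or a list of length N
#'   whose i-th element has `schedule[i]` probabilities in (0, 1].
#' @param p_ip,p_ep per-period arrival probability of one inpatient /
#'   one emergency patient (scalar, or length-N vector).
#' @param costs a `cost_parameters` object, see [cost_parameters()].
#' @return an object of class `problem_config`.
#' @export
problem_config <- function(n_regular, n_overtime, regular_capacity,
                           overtime_capacity, schedule, show_probs,
                           p_ip, p_ep, costs) {
  n_regular <- as.integer(n_regular)
  n_overtime <- as.integer(n_overtime)
  if (n_regular < 1L) stop("n_regular must be >= 1")
  if (n_overtime < 0L) stop("n_overtime must be >= 0")
  regular_capacity <- as.integer(regular_capacity)
  overtime_capacity <- as.integer(overtime_capacity)
  schedule <- as.integer(schedule)
  if (length(regular_capacity) != n_regular)
    stop("regular_capacity must have length n_regular = ", n_regular)
  if (length(overtime_capacity) != n_overtime)
    stop("overtime_capacity must have length n_overtime = ", n_overtime)
  if (length(schedule) != n_regular)
    stop("schedule must have length n_regular = ", n_regular)
  if (any(regular_capacity < 1L) || any(overtime_capacity < 1L))
    stop("every period capacity must be >= 1")
  if (any(schedule < 0L)) stop("schedule entries must be >= 0")

  if (is.numeric(show_probs) && length(show_probs) == 1L) {
    show_probs <- lapply(schedule, function(q) rep.int(as.numeric(show_probs), q))
  }
  if (!is.list(show_probs) || length(show_probs) != n_regular)
    stop("show_probs must be a scalar or a list of length n_regular")
  for (i in seq_len(n_regular)) {
    p <- as.numeric(show_probs[[i]])
    if (length(p) != schedule[i])
      stop("show_probs[[", i, "]] has length ", length(p),
           " but schedule[", i, "] = ", schedule[i])
    if (length(p) && (any(p <= 0) || any(p > 1)))
      stop("show_probs[[", i, "]] must lie in (0, 1]")
    show_probs[[i]] <- p
  }

  p_ip <- expand_prob(p_ip, n_regular, "p_ip")
  p_ep <- expand_prob(p_ep, n_regular, "p_ep")
  if (!inherits(costs, "cost_parameters"))
    stop("costs must be a cost_parameters object")

  structure(list(
    n_regular = n_regular, n_overtime = n_overtime,
    regular_capacity = regular_capacity,
    overtime_capacity = overtime_capacity,
    schedule = schedule, show_probs = show_probs,
    p_ip = p_ip, p_ep = p_ep, costs = costs
  ), class = "problem_config")
}

# recycle a scalar arrival probability to one value per period
expand_prob <- function(p, n, name) {
  p <- as.numeric(p)
  if (length(p) == 1L) p <- rep.int(p, n)
  if (length(p) != n) stop(name, " must be a scalar or length-", n, " vector")
  if (any(p < 0) || any(p > 1)) stop(name, " must lie in [0, 1]")
  p
}

#' @export
print.problem_config <- function(x, ...) {
  cat("Capacity-allocation problem configuration\n")
  cat("  regular periods:  ", x$n_regular,
      " (capacity ", paste(range(x$regular_capacity), collapse = "-"), ")\n",
      sep = "")
  cat("  overtime periods: ", x$n_overtime,
      if (x$n_overtime > 0)
        paste0(" (capacity ", paste(unique(x$overtime_capacity), collapse = ","), ")"),
      "\n", sep = "")
  cat("  scheduled outpatients: ", sum(x$schedule), "\n", sep = "")
  cat("  arrival probabilities: p_ip = ", x$p_ip[1], ", p_ep = ", x$p_ep[1],
      "\n", sep = "")
  invisible(x)
}

#' Arrival-probability presets
#'
#' Named levels for the inpatient / emergency arrival probabilities:
#' baseline (0.60, 0.15), low (0.40, 0.10), high (0.80, 0.20).
#'
#' @param level one of "baseline", "low", "high".
#' @return list with elements `p_ip` and `p_ep`.
#' @export
arrival_preset <- function(level = c("baseline", "low", "high")) {
  level <- match.arg(level)
  switch(level,
         baseline = list(p_ip = 0.60, p_ep = 0.15),
         low      = list(p_ip = 0.40, p_ep = 0.10),
         high     = list(p_ip = 0.80, p_ep = 0.20))
}

#' The default clinic-day configuration
#'
#' Convenience constructor for the study unit: a 37-period day with 4 overtime
#' periods, two fast scanners plus one slow scanner (capacity alternating
#' 3, 2, 3, ... from period 1), 2 outpatients booked per period plus 6
#' overbooked extras, and two overtime resources. Show probabilities default
#' to a constant but are normally filled by [generate_show_probabilities()].
#'
#' @param overbooking "double", "flight" or "none".
#' @param n_extra number of overbooked outpatients (default 6).
#' @param overtime_resources overtime capacity per overtime period (1 or 2).
#' @param cost_level,arrival_level preset levels, see [cost_preset()] and
#'   [arrival_preset()].
#' @param show_probs scalar or per-slot list, as in [problem_config()].
#' @return a `problem_config`.
#' @export
baseline_config <- function(overbooking = c("double", "flight", "none"),
                            n_extra = 6L, overtime_resources = 2L,
                            cost_level = "baseline",
                            arrival_level = "baseline",
                            show_probs = 0.8) {
  overbooking <- match.arg(overbooking)
  n <- 37L; k <- 4L
  sched <- switch(overbooking,
                  double = build_double_overbooking(n, 2L, n_extra, 1L, 6L),
                  flight = build_flight_overbooking(n, 2L, n_extra),
                  none   = build_double_overbooking(n, 2L, 0L))
  arr <- arrival_preset(arrival_level)
  problem_config(
    n_regular = n, n_overtime = k,
    regular_capacity = build_capacity_profile(n, 2L, 1L, 0L),
    overtime_capacity = rep.int(as.integer(overtime_resources), k),
    schedule = sched, show_probs = show_probs,
    p_ip = arr$p_ip, p_ep = arr$p_ep,
    costs = cost_preset(cost_level)
  )
}
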