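#' Unit-cost parameters
#'
#' Per-patient unit costs of the one-day allocation problem, all in the same
#' (unit-less) currency; the shipped presets are in US$.
#'
#' @param wc_ip,wc_op waiting cost per inpatient / outpatient per regular
#'   period not served.
#' @param oc_ip,oc_op overtime cost per inpatient / outpatient served in an
#'   overtime period.
#' @param pc_ip,pc_op terminal penalty per inpatient / outpatient left
#'   unserved at the end of the day.
#' @return object of class `cost_parameters`.
#' @export
cost_parameters <- function(wc_ip, wc_op, oc_ip, oc_op, pc_ip, pc_op) {
  vals <- c(wc_ip = wc_ip, wc_op = wc_op, oc_ip = oc_ip,
            oc_op = oc_op, pc_ip = pc_ip, pc_op = pc_op)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all unit costs must be finite and >= 0")
  structure(as.list(vals), class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat(sprintf("Unit costs: waiting IP %.2f / OP %.2f; overtime IP %.2f / OP %.2f; penalty IP %.2f / OP %.2f\n",
              x$wc_ip, x$wc_op, x$oc_ip, x$oc_op, x$pc_ip, x$pc_op))
  invisible(x)
}

#' Derive unit costs from regional income figures
#'
#' The waiting cost of an outpatient is one hour of average household income
#' (income loss while held in the waiting room, one regular period being
#' treated as that hour's charge unit); the inpatient waiting cost is half of
#' it (an indirect bed-blocking cost). The penalty for an outpatient turned
#' away is one full workday (8 h) of income, doubled for inpatients who may
#' stay an extra night. Overtime costs one quarter of the radiologist's
#' hourly wage per patient (a 15-minute slice), identical for both types.
#'
#' @param monthly_income average monthly household income.
#' @param monthly_hours monthly hours of work used to convert it to an hourly
#'   figure (220 in the shipped presets).
#' @param radiologist_hourly radiologist hourly wage.
#' @param round_cents round each derived cost to 2 decimals (the default);
#'   set `FALSE` to keep full precision for sensitivity work.
#' @return a `cost_parameters` object.
#' @examples
#' derive_baseline_costs(343.87, 220, 11.04)
#' @export
derive_baseline_costs <- function(monthly_income, monthly_hours,
                                  radiologist_hourly, round_cents = TRUE) {
  if (monthly_income <= 0 || monthly_hours <= 0 || radiologist_hourly <= 0)
    stop("all inputs must be positive")
  r <- if (round_cents) function(x) round(x, 2) else identity
  wc_op <- r(monthly_income / monthly_hours)
  wc_ip <- r(0.5 * wc_op)
  pc_op <- r(8 * wc_op)
  pc_ip <- r(2 * pc_op)
  oc <- r(radiologist_hourly / 4)
  cost_parameters(wc_ip = wc_ip, wc_op = wc_op, oc_ip = oc, oc_op = oc,
                  pc_ip = pc_ip, pc_op = pc_op)
}

#' Cost-level presets
#'
#' Three named cost columns used throughout the numerical experiments:
#' baseline, low (half of baseline) and high (1.5x baseline).
#'
#' @param level one of "baseline", "low", "high".
#' @return a `cost_parameters` object.
#' @export
cost_preset <- function(level = c("baseline", "low", "high")) {
  level <- match.arg(level)
  base <- derive_baseline_costs(343.87, 220, 11.04)
  f <- switch(level, baseline = 1, low = 0.5, high = 1.5)
  cost_parameters(wc_ip = round(f * base$wc_ip, 2),
                  wc_op = round(f * base$wc_op, 2),
                  oc_ip = round(f * base$oc_ip, 2),
                  oc_op = round(f * base$oc_op, 2),
                  pc_ip = round(f * base$pc_ip, 2),
                  pc_op = round(f * base$pc_op, 2))
}

#' Waiting cost of a regular-period decision
#'
#' Charges each inpatient and outpatient left waiting after the action is
#' taken; emergency patients never wait (they are always selected first) and
#' therefore never contribute.
#'
#' @param state regular state, integer vector `c(w_ip, w_op, w_ep)`.
#' @param action action triple `c(a_ip, a_op, a_ep)`.
#' @param costs a `cost_parameters` object.
#' @return the period's waiting cost.
#' @export
waiting_cost <- function(state, action, costs) {
  if (any(action > state) || any(action < 0))
    stop("action is infeasible for state")
  costs$wc_ip * (state[1] - action[1]) + costs$wc_op * (state[2] - action[2])
}

#' Overtime cost of serving patients in an overtime period
#'
#' @param action action pair `c(b_ip, b_op)` served in the overtime period.
#' @param costs a `cost_parameters` object.
#' @return the period's overtime cost.
#' @export
overtime_cost <- function(action, costs) {
  if (any(action < 0)) stop("action counts must be >= 0")
  costs$oc_ip * action[1] + costs$oc_op * action[2]
}

#' Terminal penalty for patients left unserved
#'
#' @param terminal terminal state `c(w_ip, w_op)` after all regular and
#'   overtime periods.
#' @param costs a `cost_parameters` object.
#' @return the penalty cost.
#' @export
penalty_cost <- function(terminal, costs) {
  if (any(terminal < 0)) stop("terminal counts must be >= 0")
  costs$pc_ip * terminal[1] + costs$pc_op * terminal[2]
}
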