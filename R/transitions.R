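# Exact one-step transition kernels between regular-period states. The three
# patient streams are independent: inpatient and emergency arrivals are
# per-period Bernoulli events, while the count of scheduled outpatients who
# show for the NEXT period follows a Poisson-binomial law with slot-specific
# show probabilities.

#' Bernoulli arrival kernel for inpatients (and emergency patients)
#'
#' After serving `a` of the `w` waiting patients, the successor count is
#' `w - a` with probability `1 - p_arrival` (no arrival) and `w - a + 1` with
#' probability `p_arrival`. The same kernel applies to emergency patients.
#'
#' @param w waiting count at the start of the period.
#' @param a number selected for service (`0 <= a <= w`).
#' @param p_arrival probability that one new patient arrives this period.
#' @return named numeric vector: names are successor counts, values probabilities.
#' @export
ip_transition <- function(w, a, p_arrival) {
  if (a > w || a < 0) stop("a must satisfy 0 <= a <= w")
  if (p_arrival < 0 || p_arrival > 1) stop("p_arrival must lie in [0, 1]")
  base <- w - a
  if (p_arrival == 0) return(stats::setNames(1, base))
  if (p_arrival == 1) return(stats::setNames(1, base + 1))
  stats::setNames(c(1 - p_arrival, p_arrival), c(base, base + 1))
}

#' Poisson-binomial show-count distribution
#'
#' Probability mass function of the number of shows among `Q` independently
#' scheduled outpatients with slot-specific show probabilities, computed by
#' iterative convolution: starting from a point mass at zero, each slot
#' convolves the running pmf with its own (no-show, show) Bernoulli mass.
#'
#' @param slot_probs show probabilities, one per scheduled slot (possibly empty).
#' @return numeric vector of length `length(slot_probs) + 1`; element `u + 1`
#'   is the probability that exactly `u` patients show.
#' @export
op_show_pmf <- function(slot_probs) {
  slot_probs <- as.numeric(slot_probs)
  if (length(slot_probs) && (any(slot_probs < 0) || any(slot_probs > 1)))
    stop("slot probabilities must lie in [0, 1]")
  pmf <- 1
  for (p in slot_probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

#' Joint one-step transition distribution between regular states
#'
#' Product of the three independent component kernels. The outpatient
#' component uses the show probabilities of the slots booked for the *next*
#' period (shows for period i+1 resolve during period i).
#'
#' @param state regular state `c(w_ip, w_op, w_ep)`.
#' @param action feasible action triple `c(a_ip, a_op, a_ep)`.
#' @param period current regular period i, `1 <= i <= N - 1` (the step out of
#'   period N into overtime is deterministic and handled by the solver).
#' @param config a `problem_config`.
#' @return data frame with columns `w_ip`, `w_op`, `w_ep`, `prob`; probabilities
#'   sum to 1.
#' @export
joint_transition <- function(state, action, period, config) {
  i <- as.integer(period)
  if (i < 1L || i > config$n_regular - 1L)
    stop("period must lie in 1..N-1")
  if (any(action > state) || any(action < 0) || action[3] != state[3])
    stop("action is infeasible for state")
  k_ip <- ip_transition(state[1], action[1], config$p_ip[i])
  k_ep <- ip_transition(state[3], action[3], config$p_ep[i])
  pmf <- op_show_pmf(config$show_probs[[i + 1L]])
  op_base <- state[2] - action[2]
  out <- expand.grid(ii = seq_along(k_ip), uu = seq_along(pmf),
                     ee = seq_along(k_ep), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    w_ip = as.integer(names(k_ip))[out$ii],
    w_op = op_base + out$uu - 1L,
    w_ep = as.integer(names(k_ep))[out$ee],
    prob = unname(k_ip[out$ii]) * pmf[out$uu] * unname(k_ep[out$ee])
  )
}

#' Distribution of the state at the start of the first period
#'
#' The system opens each day empty; arrivals during the opening interval
#' produce the period-1 state: one inpatient with probability `p_ip`, one
#' emergency with probability `p_ep`, and a Poisson-binomial number of shows
#' among the outpatients booked for period 1.
#'
#' @param config a `problem_config`.
#' @return data frame with columns `w_ip`, `w_op`, `w_ep`, `prob`.
#' @export
initial_state_distribution <- function(config) {
  k_ip <- ip_transition(0, 0, config$p_ip[1])
  k_ep <- ip_transition(0, 0, config$p_ep[1])
  pmf <- op_show_pmf(config$show_probs[[1]])
  out <- expand.grid(ii = seq_along(k_ip), uu = seq_along(pmf),
                     ee = seq_along(k_ep), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    w_ip = as.integer(names(k_ip))[out$ii],
    w_op = out$uu - 1L,
    w_ep = as.integer(names(k_ep))[out$ee],
    prob = unname(k_ip[out$ii]) * pmf[out$uu] * unname(k_ep[out$ee])
  )
}
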