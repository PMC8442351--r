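# Benchmark allocation policies. All of them honour the hard rules of the
# system - waiting emergencies are always selected first in regular periods,
# and exactly min(capacity, waiting) patients are served - and differ only in
# how the remaining slots are split between inpatients and outpatients:
#   P1  random draw from the pooled waiting inpatients and outpatients
#   P2  outpatients first (closest to the unit's current practice)
#   P3  inpatients first
#   P4  inpatients first in the first half of the day, outpatients first in
#       the second half and in overtime
#   P5  the mirror image of P4 (outpatients first early, inpatients late and
#       in overtime)

#' Construct a benchmark heuristic policy
#'
#' @param id one of "P1".."P5".
#' @param n_regular number of regular periods (used by the mixed policies to
#'   place the half-day switch; with 37 periods the first half is periods
#'   1-19, the second 20-37).
#' @return an object of class `alloc_policy`.
#' @seealso [optimal_policy()] to wrap a solved model in the same interface.
#' @export
heuristic_policy <- function(id = c("P1", "P2", "P3", "P4", "P5"),
                             n_regular = 37L) {
  id <- match.arg(id)
  structure(list(id = id, split = as.integer(ceiling(n_regular / 2)),
                 n_regular = as.integer(n_regular)),
            class = "alloc_policy")
}

#' Wrap a solved model as a policy
#'
#' @param solution an `mdp_solution` from [solve_mdp()].
#' @return an `alloc_policy` that looks actions up in the optimal tables.
#' @export
optimal_policy <- function(solution) {
  structure(list(id = "optimal", solution = solution,
                 n_regular = solution$config$n_regular),
            class = "alloc_policy")
}

#' @export
print.alloc_policy <- function(x, ...) {
  cat("Allocation policy:", x$id, "\n")
  invisible(x)
}

# split cap slots between ip and op, one type taking priority
priority_fill <- function(w_ip, w_op, cap, ip_first) {
  if (ip_first) {
    a_ip <- min(w_ip, cap); a_op <- min(w_op, cap - a_ip)
  } else {
    a_op <- min(w_op, cap); a_ip <- min(w_ip, cap - a_op)
  }
  c(a_ip, a_op)
}

# uniform draw without replacement from the pooled waiting lists
random_fill <- function(w_ip, w_op, cap) {
  total <- w_ip + w_op
  take <- min(cap, total)
  if (take == 0L) return(c(0L, 0L))
  picked <- sample.int(total, take)  # patients 1..w_ip are inpatients
  a_ip <- sum(picked <= w_ip)
  c(a_ip, take - a_ip)
}

#' Action chosen by a policy in a given period and state
#'
#' Regular-period states are length-3 vectors (the waiting emergency, if any,
#' is seated first); overtime states are length-2. P1 consumes random numbers
#' from the R session's generator, so seed it for reproducibility.
#'
#' @param policy an `alloc_policy`.
#' @param period 1-based stage index (`1..N` regular, `N+1..N+K` overtime).
#' @param state waiting-count vector (length 3 regular, 2 overtime).
#' @param capacity service starts available in the period.
#' @return feasible action vector of the same length as `state`.
#' @export
heuristic_action <- function(policy, period, state, capacity) {
  if (policy$id == "optimal")
    return(optimal_action(policy$solution, period, state))
  regular <- length(state) == 3L
  if (regular) {
    w_ep <- state[3]
    if (w_ep > capacity) stop("cannot honour emergency priority")
    cap <- min(capacity, sum(state)) - w_ep
    fill <- switch(policy$id,
      P1 = random_fill(state[1], state[2], cap),
      P2 = priority_fill(state[1], state[2], cap, ip_first = FALSE),
      P3 = priority_fill(state[1], state[2], cap, ip_first = TRUE),
      P4 = priority_fill(state[1], state[2], cap, ip_first = period <= policy$split),
      P5 = priority_fill(state[1], state[2], cap, ip_first = period > policy$split))
    c(a_ip = fill[1], a_op = fill[2], a_ep = w_ep)
  } else {
    cap <- min(capacity, sum(state))
    fill <- switch(policy$id,
      P1 = random_fill(state[1], state[2], cap),
      P2 = priority_fill(state[1], state[2], cap, ip_first = FALSE),
      P3 = priority_fill(state[1], state[2], cap, ip_first = TRUE),
      P4 = priority_fill(state[1], state[2], cap, ip_first = FALSE),
      P5 = priority_fill(state[1], state[2], cap, ip_first = TRUE))
    c(b_ip = fill[1], b_op = fill[2])
  }
}
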