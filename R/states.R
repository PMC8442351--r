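# State and action enumeration.
#
# A regular-period state is the waiting-count triple (w_ip, w_op, w_ep); an
# overtime state is the pair (w_ip, w_op). Two enumeration modes exist:
# "unrestricted" applies only the per-type box bounds (at period i at most i
# inpatient arrivals can have accumulated, at most the cumulative schedule of
# outpatients, at most one waiting emergency), while "restricted" adds the
# joint capacity bound: every elapsed period has served at least C_l - 1
# inpatients/outpatients (the -1 covers the worst case of one emergency
# consuming a slot each period), so the backlog w_ip + w_op can never exceed
# cumulative arrivals minus guaranteed service. Restricted enumeration is the
# one the solver uses; it typically removes ~40% of the box states.

# joint backlog bound for regular period i (Inf when inactive)
regular_joint_bound <- function(i, config) {
  if (i == 1L) return(Inf)
  cum_ag <- sum(config$schedule[1:i])
  consumed <- sum(config$regular_capacity[1:(i - 1L)] - 1L)
  if (cum_ag + i < consumed) return(-1L)  # degenerate: capacity outruns arrivals
  cum_ag + i - consumed
}

# joint backlog bound for overtime period k (counts consumed overtime capacity)
overtime_joint_bound <- function(k, config) {
  n <- config$n_regular
  b <- sum(config$schedule) + n - sum(config$regular_capacity - 1L)
  if (k > 1L) b <- b - sum(config$overtime_capacity[1:(k - 1L)])
  b
}

#' Enumerate feasible states of a regular period
#'
#' @param period regular period index, 1..N.
#' @param config a `problem_config`.
#' @param restricted apply the capacity-aware joint backlog bound (default);
#'   `FALSE` enumerates the per-type box bounds only.
#' @return integer matrix with columns `w_ip`, `w_op`, `w_ep`, one row per state.
#' @export
regular_states <- function(period, config, restricted = TRUE) {
  i <- as.integer(period)
  if (i < 1L || i > config$n_regular)
    stop("period must lie in 1..", config$n_regular)
  if (i == 1L) {
    ip_max <- 1L
    op_max <- config$schedule[1L]
    joint <- Inf
  } else {
    ip_max <- i
    op_max <- sum(config$schedule[1:i])
    joint <- if (restricted) regular_joint_bound(i, config) else Inf
    if (is.finite(joint) && joint < 0) {  # fallback branch: fresh-arrival box
      ip_max <- 1L
      op_max <- config$schedule[i]
      joint <- Inf
    }
  }
  g <- expand.grid(w_ip = 0:ip_max, w_op = 0:op_max, w_ep = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$w_ip + g$w_op <= joint, , drop = FALSE]
  m <- as.matrix(g)
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Enumerate feasible states of an overtime period
#'
#' @param k overtime period index, 1..K.
#' @inheritParams regular_states
#' @return integer matrix with columns `w_ip`, `w_op`.
#' @export
overtime_states <- function(k, config, restricted = TRUE) {
  k <- as.integer(k)
  if (k < 1L || k > config$n_overtime)
    stop("k must lie in 1..", config$n_overtime)
  n <- config$n_regular
  op_max <- sum(config$schedule)
  joint <- if (restricted) overtime_joint_bound(k, config) else Inf
  if (is.finite(joint) && joint < 0) {
    m <- matrix(0L, nrow = 1L, ncol = 2L)  # cleared system: only the empty state
  } else {
    g <- expand.grid(w_ip = 0:n, w_op = 0:op_max, KEEP.OUT.ATTRS = FALSE)
    g <- g[g$w_ip + g$w_op <= joint, , drop = FALSE]
    m <- as.matrix(g)
    storage.mode(m) <- "integer"
  }
  colnames(m) <- c("w_ip", "w_op")
  rownames(m) <- NULL
  m
}

#' Per-period state counts
#'
#' Tabulates, for every regular and overtime period, the number of feasible
#' states under restricted and unrestricted enumeration.
#'
#' @param config a `problem_config`.
#' @return data frame with columns `period` (1-based; overtime periods are
#'   labelled N+1..N+K), `type`, `restricted`, `unrestricted`.
#' @export
state_count_table <- function(config) {
  n <- config$n_regular; k <- config$n_overtime
  reg_r <- vapply(seq_len(n), function(i) nrow(regular_states(i, config, TRUE)), 0L)
  reg_u <- vapply(seq_len(n), function(i) nrow(regular_states(i, config, FALSE)), 0L)
  ot_r <- if (k > 0) vapply(seq_len(k), function(j) nrow(overtime_states(j, config, TRUE)), 0L) else integer()
  ot_u <- if (k > 0) vapply(seq_len(k), function(j) nrow(overtime_states(j, config, FALSE)), 0L) else integer()
  data.frame(
    period = c(seq_len(n), n + seq_len(k)),
    type = rep(c("regular", "overtime"), c(n, k)),
    restricted = c(reg_r, ot_r),
    unrestricted = c(reg_u, ot_u)
  )
}

#' Total state count across all periods
#'
#' @inheritParams regular_states
#' @return total number of states over the N regular and K overtime periods.
#' @export
count_states <- function(config, restricted = TRUE) {
  tab <- state_count_table(config)
  if (restricted) sum(tab$restricted) else sum(tab$unrestricted)
}

#' Feasible actions for a regular-period state
#'
#' Any waiting emergency patient must be selected (`a_ep = w_ep`), and the
#' action must serve exactly `min(capacity, total waiting)` patients - there
#' is no voluntary idling. The remaining capacity is split between waiting
#' inpatients and outpatients in every feasible way. Rows are ordered by
#' descending `a_ip` so ties in the solver break deterministically.
#'
#' @param state integer vector `c(w_ip, w_op, w_ep)`.
#' @param capacity service starts available in the period.
#' @return integer matrix with columns `a_ip`, `a_op`, `a_ep`.
#' @export
feasible_regular_actions <- function(state, capacity) {
  stopifnot(capacity >= 1, all(state >= 0), state[3] <= 1)
  w_ip <- state[1]; w_op <- state[2]; w_ep <- state[3]
  if (w_ep > capacity)
    stop("cannot honour emergency priority: w_ep = ", w_ep,
         " exceeds capacity ", capacity)
  r <- min(capacity, w_ip + w_op + w_ep) - w_ep  # slots left for IP/OP
  a_ip <- seq.int(min(w_ip, r), max(0L, r - w_op))
  m <- cbind(a_ip = a_ip, a_op = r - a_ip, a_ep = rep.int(w_ep, length(a_ip)))
  storage.mode(m) <- "integer"
  m
}

#' Feasible actions for an overtime-period state
#'
#' Serves exactly `min(capacity, total waiting)` patients, split between
#' inpatients and outpatients in every feasible way; rows ordered by
#' descending `b_ip`.
#'
#' @param state integer vector `c(w_ip, w_op)`.
#' @param capacity overtime capacity of the period.
#' @return integer matrix with columns `b_ip`, `b_op`.
#' @export
feasible_overtime_actions <- function(state, capacity) {
  stopifnot(capacity >= 1, all(state >= 0))
  t <- min(capacity, state[1] + state[2])
  b_ip <- seq.int(min(state[1], t), max(0L, t - state[2]))
  m <- cbind(b_ip = b_ip, b_op = t - b_ip)
  storage.mode(m) <- "integer"
  m
}
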