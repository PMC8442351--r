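# Backward-induction solver. Value and policy tables are stored as dense
# arrays indexed by waiting counts plus one (R is 1-based): a regular period
# holds a (ip_max+1) x (op_max+1) x 2 array, an overtime period a
# (N+1) x (total_schedule+1) matrix. Cells outside the restricted state set
# hold NA; if a transition ever lands on an NA cell the sweep stops with an
# error, which doubles as a runtime check that the restricted sets are closed
# under the dynamics.

# box bounds of the (restricted) state array for regular period i
regular_box <- function(i, config) {
  if (i == 1L) list(ip = 1L, op = config$schedule[1L])
  else list(ip = i, op = sum(config$schedule[1:i]))
}

#' Terminal penalty values
#'
#' Value of every terminal state `(w_ip, w_op)` reachable after all regular
#' and overtime periods: the linear penalty for patients left unserved.
#'
#' @param config a `problem_config`.
#' @return numeric matrix; element `[w_ip + 1, w_op + 1]` is the penalty of
#'   ending the day with that many unserved inpatients / outpatients.
#' @export
terminal_values <- function(config) {
  ip_max <- config$n_regular
  op_max <- sum(config$schedule)
  outer(0:ip_max, 0:op_max,
        function(i, o) config$costs$pc_ip * i + config$costs$pc_op * o)
}

#' Backward sweep over the overtime periods
#'
#' Solves periods K down to 1. Overtime transitions are deterministic (no
#' new arrivals after hours): the successor of `(w_ip, w_op)` under action
#' `(b_ip, b_op)` is simply `(w_ip - b_ip, w_op - b_op)`. Ties in the argmin
#' break toward the action serving more inpatients.
#'
#' @param config a `problem_config`.
#' @param next_values value matrix of the stage after the last overtime
#'   period, normally [terminal_values()].
#' @return list with per-period lists `values`, `action_ip`, `action_op`
#'   (each a list of K matrices indexed `[w_ip + 1, w_op + 1]`).
#' @export
backward_overtime <- function(config, next_values) {
  kk <- config$n_overtime
  n <- config$n_regular
  op_max <- sum(config$schedule)
  costs <- config$costs
  values <- act_ip <- act_op <- vector("list", kk)
  v_next <- next_values
  for (k in rev(seq_len(kk))) {
    st <- overtime_states(k, config, restricted = TRUE)
    v <- a1 <- a2 <- matrix(NA_real_, n + 1L, op_max + 1L)
    cap <- config$overtime_capacity[k]
    for (r in seq_len(nrow(st))) {
      w <- st[r, ]
      acts <- feasible_overtime_actions(w, cap)
      best <- Inf; bi <- bo <- NA_integer_
      for (j in seq_len(nrow(acts))) {
        b <- acts[j, ]
        nv <- v_next[w[1] - b[1] + 1L, w[2] - b[2] + 1L]
        if (is.na(nv))
          stop("overtime successor (", w[1] - b[1], ",", w[2] - b[2],
               ") missing from stage ", k + 1L, " values")
        val <- costs$oc_ip * b[1] + costs$oc_op * b[2] + nv
        if (val < best) { best <- val; bi <- b[1]; bo <- b[2] }
      }
      v[w[1] + 1L, w[2] + 1L] <- best
      a1[w[1] + 1L, w[2] + 1L] <- bi
      a2[w[1] + 1L, w[2] + 1L] <- bo
    }
    values[[k]] <- v; act_ip[[k]] <- a1; act_op[[k]] <- a2
    v_next <- v
  }
  list(values = values, action_ip = act_ip, action_op = act_op)
}

#' Backward sweep over the regular periods
#'
#' Solves periods N down to 1. For i < N the continuation is the expectation
#' of the next stage's value under the joint arrival kernel; because the
#' emergency component of the action always clears the waiting emergency, the
#' expected continuation depends only on the post-action remainders
#' `(w_ip - a_ip, w_op - a_op)`, so it is precomputed once per period as a
#' matrix and shared by all states and actions. The step out of period N into
#' overtime is deterministic and drops the emergency component (after-hours
#' emergencies are handled by dedicated equipment).
#'
#' @param config a `problem_config`.
#' @param next_values value matrix of the stage after period N: overtime
#'   period 1 when K >= 1, otherwise [terminal_values()].
#' @return list with per-period lists `values` (3-d arrays indexed
#'   `[w_ip + 1, w_op + 1, w_ep + 1]`), `action_ip`, `action_op`.
#' @export
backward_regular <- function(config, next_values) {
  n <- config$n_regular
  costs <- config$costs
  values <- act_ip <- act_op <- vector("list", n)
  for (i in rev(seq_len(n))) {
    box <- regular_box(i, config)
    if (i == n) {
      ev <- next_values  # deterministic crossover into overtime
    } else {
      v_next <- values[[i + 1L]]
      # average out the emergency arrival, then convolve the inpatient
      # Bernoulli and the outpatient show pmf by shifting the value matrix
      v2 <- array((1 - config$p_ep[i]) * v_next[, , 1L] +
                    config$p_ep[i] * v_next[, , 2L],
                  dim = dim(v_next)[1:2])
      pmf <- op_show_pmf(config$show_probs[[i + 1L]])
      p_ip <- config$p_ip[i]
      ev <- matrix(0, box$ip + 1L, box$op + 1L)
      for (dip in 0:1) {
        wip <- if (dip == 0L) 1 - p_ip else p_ip
        if (wip == 0) next
        for (u in seq_along(pmf)) {
          if (pmf[u] == 0) next
          ev <- ev + (wip * pmf[u]) *
            v2[seq_len(box$ip + 1L) + dip, seq_len(box$op + 1L) + (u - 1L),
               drop = FALSE]
        }
      }
    }
    st <- regular_states(i, config, restricted = TRUE)
    v <- a1 <- a2 <- array(NA_real_, dim = c(box$ip + 1L, box$op + 1L, 2L))
    cap <- config$regular_capacity[i]
    for (r in seq_len(nrow(st))) {
      w <- st[r, ]
      acts <- feasible_regular_actions(w, cap)
      best <- Inf; bi <- bo <- NA_integer_
      for (j in seq_len(nrow(acts))) {
        a <- acts[j, ]
        cont <- ev[w[1] - a[1] + 1L, w[2] - a[2] + 1L]
        if (is.na(cont))
          stop("regular successor of state (", paste(w, collapse = ","),
               ") under action (", paste(a, collapse = ","),
               ") in period ", i, " lies outside the restricted state set")
        val <- costs$wc_ip * (w[1] - a[1]) + costs$wc_op * (w[2] - a[2]) + cont
        if (val < best) { best <- val; bi <- a[1]; bo <- a[2] }
      }
      v[w[1] + 1L, w[2] + 1L, w[3] + 1L] <- best
      a1[w[1] + 1L, w[2] + 1L, w[3] + 1L] <- bi
      a2[w[1] + 1L, w[2] + 1L, w[3] + 1L] <- bo
    }
    values[[i]] <- v; act_ip[[i]] <- a1; act_op[[i]] <- a2
  }
  list(values = values, action_ip = act_ip, action_op = act_op)
}

#' Solve the one-day allocation problem by backward induction
#'
#' Runs the terminal, overtime, and regular sweeps and averages the period-1
#' values over the opening-arrival distribution to obtain the expected total
#' cost of a day operated under the optimal policy.
#'
#' @param config a `problem_config`.
#' @return an object of class `mdp_solution`: the per-period value tables and
#'   policy tables, the terminal value matrix, the expected day cost, and
#'   state counts. Use [policy_table()] to flatten the policy for export and
#'   [optimal_policy()] to plug it into the simulator.
#' @export
solve_mdp <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  term <- terminal_values(config)
  ot <- if (config$n_overtime > 0) backward_overtime(config, term) else NULL
  reg <- backward_regular(config, if (is.null(ot)) term else ot$values[[1L]])
  init <- initial_state_distribution(config)
  v1 <- reg$values[[1L]]
  expected <- sum(init$prob *
                    v1[cbind(init$w_ip + 1L, init$w_op + 1L, init$w_ep + 1L)])
  structure(list(
    config = config,
    terminal = term,
    regular = reg,
    overtime = ot,
    expected_day_cost = expected,
    n_states = count_states(config, restricted = TRUE),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "mdp_solution")
}

#' @export
print.mdp_solution <- function(x, ...) {
  cat("Optimal capacity-allocation policy (backward induction)\n")
  cat("  periods: ", x$config$n_regular, " regular + ",
      x$config$n_overtime, " overtime\n", sep = "")
  cat("  states solved: ", x$n_states, "\n", sep = "")
  cat(sprintf("  expected day cost: %.2f\n", x$expected_day_cost))
  cat(sprintf("  solve time: %.2f s\n", x$elapsed))
  invisible(x)
}

#' Look up the optimal action for a state
#'
#' @param solution an `mdp_solution`.
#' @param period 1-based stage index: `1..N` are regular periods,
#'   `N+1..N+K` overtime periods.
#' @param state waiting-count vector: `c(w_ip, w_op, w_ep)` for a regular
#'   period, `c(w_ip, w_op)` for an overtime period.
#' @return the optimal action (integer vector, same length as `state`).
#' @export
optimal_action <- function(solution, period, state) {
  n <- solution$config$n_regular
  if (period <= n) {
    i <- period
    a1 <- solution$regular$action_ip[[i]][state[1] + 1L, state[2] + 1L, state[3] + 1L]
    a2 <- solution$regular$action_op[[i]][state[1] + 1L, state[2] + 1L, state[3] + 1L]
    if (is.na(a1)) stop("state outside the restricted set of period ", period)
    c(a_ip = a1, a_op = a2, a_ep = state[3])
  } else {
    k <- period - n
    b1 <- solution$overtime$action_ip[[k]][state[1] + 1L, state[2] + 1L]
    b2 <- solution$overtime$action_op[[k]][state[1] + 1L, state[2] + 1L]
    if (is.na(b1)) stop("state outside the restricted set of overtime period ", k)
    c(b_ip = b1, b_op = b2)
  }
}

#' Flatten the optimal policy into a decision-support table
#'
#' One row per (period, state) with the optimal action - the form a scheduler
#' would keep next to the console: look up the current period and waiting
#' counts, read off how many of each patient type to call in.
#'
#' @param solution an `mdp_solution`.
#' @return data frame with columns `period`, `w_ip`, `w_op`, `w_ep`, `a_ip`,
#'   `a_op`, `a_ep`; for overtime rows `w_ep` and `a_ep` are `NA`.
#' @export
policy_table <- function(solution) {
  cfg <- solution$config
  n <- cfg$n_regular
  rows <- vector("list", n + cfg$n_overtime)
  for (i in seq_len(n)) {
    st <- regular_states(i, cfg, restricted = TRUE)
    a1 <- solution$regular$action_ip[[i]][cbind(st[, 1] + 1L, st[, 2] + 1L, st[, 3] + 1L)]
    a2 <- solution$regular$action_op[[i]][cbind(st[, 1] + 1L, st[, 2] + 1L, st[, 3] + 1L)]
    rows[[i]] <- data.frame(period = i, w_ip = st[, 1], w_op = st[, 2],
                            w_ep = st[, 3], a_ip = a1, a_op = a2, a_ep = st[, 3])
  }
  for (k in seq_len(cfg$n_overtime)) {
    st <- overtime_states(k, cfg, restricted = TRUE)
    b1 <- solution$overtime$action_ip[[k]][cbind(st[, 1] + 1L, st[, 2] + 1L)]
    b2 <- solution$overtime$action_op[[k]][cbind(st[, 1] + 1L, st[, 2] + 1L)]
    rows[[n + k]] <- data.frame(period = n + k, w_ip = st[, 1], w_op = st[, 2],
                                w_ep = NA_integer_, a_ip = b1, a_op = b2,
                                a_ep = NA_integer_)
  }
  do.call(rbind, rows)
}

#' Flatten the value tables
#'
#' @param solution an `mdp_solution`.
#' @return data frame with columns `period`, `w_ip`, `w_op`, `w_ep`, `value`
#'   (`w_ep` is `NA` for overtime rows).
#' @export
value_table <- function(solution) {
  cfg <- solution$config
  n <- cfg$n_regular
  rows <- vector("list", n + cfg$n_overtime)
  for (i in seq_len(n)) {
    st <- regular_states(i, cfg, restricted = TRUE)
    v <- solution$regular$values[[i]][cbind(st[, 1] + 1L, st[, 2] + 1L, st[, 3] + 1L)]
    rows[[i]] <- data.frame(period = i, w_ip = st[, 1], w_op = st[, 2],
                            w_ep = st[, 3], value = v)
  }
  for (k in seq_len(cfg$n_overtime)) {
    st <- overtime_states(k, cfg, restricted = TRUE)
    v <- solution$overtime$values[[k]][cbind(st[, 1] + 1L, st[, 2] + 1L)]
    rows[[n + k]] <- data.frame(period = n + k, w_ip = st[, 1], w_op = st[, 2],
                                w_ep = NA_integer_, value = v)
  }
  do.call(rbind, rows)
}
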