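# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: brute-force subset enumeration for the show-count
# distribution, and exhaustive policy enumeration with exact outcome-tree
# expectation for the dynamic program.

# missing-lookup fallback (named-vector lookups return NA for absent names)
`%||%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Poisson-binomial pmf by explicit enumeration of all 2^Q show/no-show subsets
pb_pmf_bruteforce <- function(slot_probs) {
  q <- length(slot_probs)
  pmf <- numeric(q + 1)
  if (q == 0) return(1)
  for (mask in 0:(2^q - 1)) {
    bits <- as.integer(intToBits(mask)[1:q])
    pr <- prod(ifelse(bits == 1, slot_probs, 1 - slot_probs))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + pr
  }
  pmf
}

# small problem configurations used across tests
tiny_config <- function(p_show = 0.7, p_ip = 0.5, p_ep = 0.2,
                        costs = cost_preset("baseline")) {
  problem_config(n_regular = 3, n_overtime = 1,
                 regular_capacity = c(1, 1, 1), overtime_capacity = 2,
                 schedule = c(1, 1, 0),
                 show_probs = list(p_show, p_show, numeric()),
                 p_ip = p_ip, p_ep = p_ep, costs = costs)
}

# N = 2 instance small enough for exhaustive deterministic-policy enumeration
micro_config <- function(p_show = 0.6, p_ip = 0.5, p_ep = 0.3) {
  problem_config(n_regular = 2, n_overtime = 1,
                 regular_capacity = c(1, 1), overtime_capacity = 1,
                 schedule = c(1, 1),
                 show_probs = list(p_show, p_show),
                 p_ip = p_ip, p_ep = p_ep, costs = cost_preset("baseline"))
}

# a mid-sized synthetic clinic day used for the stochastic acceptance checks:
# same structure as the full problem (mixed fleet, overbooking, overtime) at
# a third of the horizon
small_day_config <- function(overbooking = "double", overtime_resources = 2,
                             cost_level = "baseline", arrival_level = "baseline",
                             show_probs = NULL, n_extra = 2L) {
  n <- 12L
  sched <- switch(overbooking,
                  double = build_double_overbooking(n, 2L, n_extra, 1L, 6L),
                  flight = build_flight_overbooking(n, 2L, n_extra),
                  none = rep.int(2L, n))
  if (is.null(show_probs)) {
    set.seed(20240915)
    show_probs <- generate_show_probabilities(noshow_spec(), sched)
  }
  arr <- arrival_preset(arrival_level)
  problem_config(n_regular = n, n_overtime = 2L,
                 regular_capacity = build_capacity_profile(n, 2L, 1L, 0L),
                 overtime_capacity = rep.int(as.integer(overtime_resources), 2L),
                 schedule = sched, show_probs = show_probs,
                 p_ip = arr$p_ip, p_ep = arr$p_ep,
                 costs = cost_preset(cost_level))
}

# --- exhaustive-policy oracle ------------------------------------------------
# Enumerates every deterministic Markov policy of a small instance and
# computes its exact expected day cost by enumerating the full outcome tree.
# Returns the minimum expected cost (averaged over the opening arrivals).

oracle_key <- function(state) paste(state, collapse = ",")

# list all decision points: per period, per state, the feasible action matrix
oracle_decision_points <- function(config) {
  pts <- list()
  for (i in seq_len(config$n_regular)) {
    st <- regular_states(i, config, restricted = TRUE)
    for (r in seq_len(nrow(st))) {
      acts <- feasible_regular_actions(st[r, ], config$regular_capacity[i])
      pts[[length(pts) + 1]] <- list(period = i, key = oracle_key(st[r, ]),
                                     actions = acts)
    }
  }
  for (k in seq_len(config$n_overtime)) {
    st <- overtime_states(k, config, restricted = TRUE)
    for (r in seq_len(nrow(st))) {
      acts <- feasible_overtime_actions(st[r, ], config$overtime_capacity[k])
      pts[[length(pts) + 1]] <- list(period = config$n_regular + k,
                                     key = oracle_key(st[r, ]), actions = acts)
    }
  }
  pts
}

# exact expected cost of a fixed policy from a given period-1 state,
# by recursive enumeration of every arrival outcome
oracle_cost_from <- function(config, pmap, i, state) {
  n <- config$n_regular
  co <- config$costs
  if (i > n) {  # overtime chain is deterministic
    s <- state
    total <- 0
    for (k in seq_len(config$n_overtime)) {
      b <- pmap[[paste0(n + k, "|", oracle_key(s))]]
      total <- total + co$oc_ip * b[1] + co$oc_op * b[2]
      s <- s - b
    }
    return(total + co$pc_ip * s[1] + co$pc_op * s[2])
  }
  a <- pmap[[paste0(i, "|", oracle_key(state))]]
  cost <- co$wc_ip * (state[1] - a[1]) + co$wc_op * (state[2] - a[2])
  rem <- state - a
  if (i == n) return(cost + oracle_cost_from(config, pmap, i + 1, rem[1:2]))
  q <- config$schedule[i + 1]
  probs <- config$show_probs[[i + 1]]
  ev <- 0
  for (dip in 0:1) for (dep in 0:1) {
    p1 <- (if (dip == 1) config$p_ip[i] else 1 - config$p_ip[i]) *
      (if (dep == 1) config$p_ep[i] else 1 - config$p_ep[i])
    if (p1 == 0) next
    for (mask in 0:(2^q - 1)) {
      bits <- if (q > 0) as.integer(intToBits(mask)[1:q]) else integer()
      p2 <- prod(ifelse(bits == 1, probs, 1 - probs))
      nxt <- c(rem[1] + dip, rem[2] + sum(bits), dep)
      ev <- ev + p1 * p2 * oracle_cost_from(config, pmap, i + 1, nxt)
    }
  }
  cost + ev
}

# expected day cost of a fixed policy, averaged over opening arrivals
oracle_policy_cost <- function(config, pmap) {
  q <- config$schedule[1]
  probs <- config$show_probs[[1]]
  ev <- 0
  for (dip in 0:1) for (dep in 0:1) {
    p1 <- (if (dip == 1) config$p_ip[1] else 1 - config$p_ip[1]) *
      (if (dep == 1) config$p_ep[1] else 1 - config$p_ep[1])
    for (mask in 0:(2^q - 1)) {
      bits <- if (q > 0) as.integer(intToBits(mask)[1:q]) else integer()
      p2 <- prod(ifelse(bits == 1, probs, 1 - probs))
      ev <- ev + p1 * p2 *
        oracle_cost_from(config, pmap, 1, c(dip, sum(bits), dep))
    }
  }
  ev
}

# minimum expected day cost over ALL deterministic Markov policies
oracle_exhaustive_min <- function(config) {
  pts <- oracle_decision_points(config)
  n_actions <- vapply(pts, function(p) nrow(p$actions), 0L)
  n_pol <- prod(n_actions)
  stopifnot(n_pol <= 5000)  # guard: instance must stay enumerable
  best <- Inf
  idx <- rep(1L, length(pts))
  repeat {
    pmap <- stats::setNames(
      lapply(seq_along(pts), function(j) pts[[j]]$actions[idx[j], ]),
      vapply(pts, function(p) paste0(p$period, "|", p$key), ""))
    best <- min(best, oracle_policy_cost(config, pmap))
    j <- 1L
    while (j <= length(pts)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= n_actions[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(pts)) break
  }
  best
}
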