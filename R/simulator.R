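# Monte-Carlo day simulator. A "day stream" holds every random outcome of
# one business day - the Bernoulli inpatient/emergency arrivals entering each
# regular period and the per-slot show outcomes of the booked outpatients -
# so the same stream can be replayed under different policies (common random
# numbers) for low-variance policy comparison.

#' Draw the random arrival stream of one business day
#'
#' @param config a `problem_config`.
#' @return list with `ip`, `ep` (logical, length N: an arrival entered period
#'   i) and `shows` (list of length N: per-slot show outcomes of the
#'   outpatients booked for period i).
#' @export
draw_day_stream <- function(config) {
  n <- config$n_regular
  list(
    ip = stats::runif(n) < config$p_ip,
    ep = stats::runif(n) < config$p_ep,
    shows = lapply(config$show_probs,
                   function(p) if (length(p)) stats::runif(length(p)) < p else logical())
  )
}

#' Simulate one business day under a policy
#'
#' Plays the day forward from the empty pre-day state: period-1 arrivals form
#' the opening state; in each regular period the policy picks a feasible
#' action, waiting costs accrue for patients not selected, and new arrivals
#' enter; leftovers cross deterministically into overtime where serving costs
#' overtime rates; whoever remains at the end incurs the terminal penalty.
#'
#' @param policy an `alloc_policy`.
#' @param config a `problem_config`.
#' @param stream a day stream from [draw_day_stream()]; drawn from the
#'   session RNG when `NULL`.
#' @return one-row data frame: cost decomposition (`waiting_cost`,
#'   `overtime_cost`, `penalty_cost`, `total_cost`), unserved counts, served
#'   counts by period type and patient type, and arrival counts.
#' @export
simulate_day <- function(policy, config, stream = NULL) {
  if (is.null(stream)) stream <- draw_day_stream(config)
  n <- config$n_regular
  costs <- config$costs
  w <- c(stream$ip[1], sum(stream$shows[[1]]), stream$ep[1])
  storage.mode(w) <- "integer"
  wait_c <- ot_c <- 0
  served_reg <- served_ot <- 0L
  served <- c(ip = 0L, op = 0L, ep = 0L)
  for (i in seq_len(n)) {
    cap <- config$regular_capacity[i]
    a <- heuristic_action(policy, i, w, cap)
    if (any(a > w) || any(a < 0) || a[3] != w[3] ||
        sum(a) != min(cap, sum(w)))
      stop("policy ", policy$id, " returned infeasible action (",
           paste(a, collapse = ","), ") for state (",
           paste(w, collapse = ","), ") in period ", i)
    wait_c <- wait_c + costs$wc_ip * (w[1] - a[1]) + costs$wc_op * (w[2] - a[2])
    served_reg <- served_reg + sum(a)
    served <- served + a
    w <- w - a
    if (i < n) {
      w <- w + c(stream$ip[i + 1L], sum(stream$shows[[i + 1L]]), stream$ep[i + 1L])
    }
  }
  s <- w[1:2]  # emergencies never cross into overtime (always just served)
  for (k in seq_len(config$n_overtime)) {
    cap <- config$overtime_capacity[k]
    b <- heuristic_action(policy, n + k, s, cap)
    if (any(b > s) || any(b < 0) || sum(b) != min(cap, sum(s)))
      stop("policy ", policy$id, " returned infeasible overtime action")
    ot_c <- ot_c + costs$oc_ip * b[1] + costs$oc_op * b[2]
    served_ot <- served_ot + sum(b)
    served[1:2] <- served[1:2] + b
    s <- s - b
  }
  pen <- costs$pc_ip * s[1] + costs$pc_op * s[2]
  data.frame(
    waiting_cost = wait_c, overtime_cost = ot_c, penalty_cost = pen,
    total_cost = wait_c + ot_c + pen,
    unserved_ip = s[1], unserved_op = s[2],
    served_regular = served_reg, served_overtime = served_ot,
    served_ip = served[["ip"]], served_op = served[["op"]],
    served_ep = served[["ep"]],
    arrived_ip = sum(stream$ip), arrived_op = sum(vapply(stream$shows, sum, 0L)),
    arrived_ep = sum(stream$ep)
  )
}

#' Simulate many independent business days
#'
#' @param policy an `alloc_policy`.
#' @param config a `problem_config`.
#' @param n_days number of day replicates.
#' @param seed optional integer seed for the session RNG.
#' @param streams optional pre-drawn list of `n_days` day streams (for common
#'   random numbers across policies); drawn internally when `NULL`.
#' @return an object of class `sim_result`: element `days` is the per-day
#'   data frame, `summary` holds the mean, SD and 75th percentile of total
#'   cost plus mean/SD unserved counts.
#' @export
simulate_many <- function(policy, config, n_days, seed = NULL, streams = NULL) {
  stopifnot(n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(streams))
    streams <- replicate(n_days, draw_day_stream(config), simplify = FALSE)
  days <- do.call(rbind, lapply(streams[seq_len(n_days)],
                                function(s) simulate_day(policy, config, s)))
  rownames(days) <- NULL
  structure(list(
    policy = policy$id,
    days = days,
    summary = list(
      mean_cost = mean(days$total_cost),
      sd_cost = stats::sd(days$total_cost),
      q75_cost = unname(stats::quantile(days$total_cost, 0.75)),
      mean_unserved_ip = mean(days$unserved_ip),
      sd_unserved_ip = stats::sd(days$unserved_ip),
      mean_unserved_op = mean(days$unserved_op),
      sd_unserved_op = stats::sd(days$unserved_op)
    )
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Policy %s over %d simulated days\n", x$policy, nrow(x$days)))
  cat(sprintf("  total cost: %.2f (%.2f), 75th pct %.2f\n",
              s$mean_cost, s$sd_cost, s$q75_cost))
  cat(sprintf("  unserved: IP %.2f +/- %.2f, OP %.2f +/- %.2f\n",
              s$mean_unserved_ip, s$sd_unserved_ip,
              s$mean_unserved_op, s$sd_unserved_op))
  invisible(x)
}

#' Average occupancy of the offered capacity
#'
#' Fraction of offered service slots (total regular capacity plus the full
#' configured overtime capacity, per day) actually used over the simulated
#' sample. Unused overtime slots count in the denominator.
#'
#' @param day_results per-day data frame (the `days` element of a
#'   `sim_result`).
#' @param config the `problem_config` the days were simulated under.
#' @return occupancy fraction in \[0, 1\].
#' @export
occupancy_rate <- function(day_results, config) {
  stopifnot(nrow(day_results) >= 1)
  offered <- sum(config$regular_capacity) + sum(config$overtime_capacity)
  sum(day_results$served_regular + day_results$served_overtime) /
    (nrow(day_results) * offered)
}

#' Compare policies on a common set of simulated days
#'
#' Simulates every policy over `n_days` business days and compares each
#' alternative with the reference policy ("optimal" when present, otherwise
#' the first) by a Welch two-sample t-test on total cost at the 5% level.
#' With `common_random = TRUE` (the default) all policies face the same
#' arrival streams, which strips arrival noise out of the comparison.
#'
#' @param config a `problem_config`.
#' @param policies character vector of policy names among "optimal",
#'   "P1".."P5".
#' @param n_days day replicates per policy.
#' @param seed integer seed.
#' @param common_random reuse the same arrival streams for every policy.
#' @param solution optional pre-computed `mdp_solution` (solved internally
#'   when "optimal" is requested without one).
#' @return an object of class `policy_comparison` with elements `summary`
#'   (one row per policy: mean/SD/75th-percentile cost, unserved counts,
#'   Welch t and p vs the reference) and `results` (named list of
#'   `sim_result` objects).
#' @export
compare_policies <- function(config, policies = c("optimal", "P1", "P2", "P3", "P4", "P5"),
                             n_days = 10000L, seed = 1L, common_random = TRUE,
                             solution = NULL) {
  stopifnot(length(policies) >= 1)
  if ("optimal" %in% policies && is.null(solution)) solution <- solve_mdp(config)
  objs <- lapply(policies, function(p) {
    if (p == "optimal") optimal_policy(solution)
    else heuristic_policy(p, n_regular = config$n_regular)
  })
  names(objs) <- policies
  streams <- NULL
  if (common_random) {
    set.seed(seed)
    streams <- replicate(n_days, draw_day_stream(config), simplify = FALSE)
  }
  results <- lapply(seq_along(objs), function(j) {
    # offset the seed per policy so P1's own selection draws differ from the
    # arrival draws while staying reproducible
    simulate_many(objs[[j]], config, n_days, seed = seed + j,
                  streams = streams)
  })
  names(results) <- policies
  ref <- if ("optimal" %in% policies) "optimal" else policies[1]
  ref_costs <- results[[ref]]$days$total_cost
  summ <- do.call(rbind, lapply(policies, function(p) {
    s <- results[[p]]$summary
    if (p == ref) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(results[[p]]$days$total_cost, ref_costs,
                          var.equal = FALSE)
    }
    data.frame(policy = p, mean_cost = s$mean_cost, sd_cost = s$sd_cost,
               q75_cost = s$q75_cost,
               mean_unserved_ip = s$mean_unserved_ip,
               sd_unserved_ip = s$sd_unserved_ip,
               mean_unserved_op = s$mean_unserved_op,
               sd_unserved_op = s$sd_unserved_op,
               t_vs_ref = unname(tt$statistic), p_vs_ref = tt$p.value,
               significant_5pct = p != ref && tt$p.value < 0.05)
  }))
  structure(list(summary = summ, results = results, reference = ref,
                 n_days = n_days, seed = seed, common_random = common_random),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison over %d simulated days (reference: %s)\n",
              x$n_days, x$reference))
  s <- x$summary
  cat("  total cost, mean (SD):\n")
  for (r in seq_len(nrow(s))) {
    cat(sprintf("    %-8s %9.2f (%.2f)%s\n", s$policy[r], s$mean_cost[r],
                s$sd_cost[r], if (s$significant_5pct[r]) " *" else ""))
  }
  cat("  unserved, mean +/- SD:\n")
  for (r in seq_len(nrow(s))) {
    cat(sprintf("    %-8s IP %.2f +/- %.2f   OP %.2f +/- %.2f\n",
                s$policy[r], s$mean_unserved_ip[r], s$sd_unserved_ip[r],
                s$mean_unserved_op[r], s$sd_unserved_op[r]))
  }
  cat("  * differs from the reference at the 5% level (Welch t-test)\n")
  invisible(x)
}
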