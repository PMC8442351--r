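# Configuration file I/O and the scenario-grid runner. The config file is
# flat YAML whose keys mirror the problem_config fields; a written config
# re-reads to an identical object.

#' Write a problem configuration to a YAML file
#'
#' All fields are written fully resolved (capacity profile, schedule and
#' per-slot show probabilities as explicit sequences) so the file stands on
#' its own and round-trips exactly.
#'
#' @param config a `problem_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- list(
    n_regular = config$n_regular,
    n_overtime = config$n_overtime,
    regular_capacity = as.integer(config$regular_capacity),
    overtime_capacity = as.integer(config$overtime_capacity),
    schedule = as.integer(config$schedule),
    show_probs = lapply(config$show_probs, as.numeric),
    p_ip = as.numeric(config$p_ip),
    p_ep = as.numeric(config$p_ep),
    costs = lapply(unclass(config$costs), as.numeric)
  )
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Load and validate a problem configuration from a YAML file
#'
#' Accepts either fully resolved fields (as written by [write_config()]) or
#' the shorthand blocks `overbooking: {rule, base, extras, start, gap}` and
#' `fleet: {fast, slow, slow_phase}` in place of `schedule` and
#' `regular_capacity`, plus `overtime: {periods, resources}` in place of
#' `overtime_capacity`. Every invariant of [problem_config()] is enforced;
#' violations name the offending field.
#'
#' @param path path to the YAML file.
#' @return a validated `problem_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(x[[key]])) stop("config is missing required key: ", key)
    x[[key]]
  }
  n <- as.integer(need("n_regular"))
  if (!is.null(x[["overtime"]])) {
    k <- as.integer(x[["overtime"]][["periods"]])
    overtime_capacity <- rep.int(as.integer(x[["overtime"]][["resources"]]), k)
  } else {
    k <- as.integer(need("n_overtime"))
    overtime_capacity <- as.integer(need("overtime_capacity"))
  }
  schedule <- if (!is.null(x[["overbooking"]])) {
    ob <- x[["overbooking"]]
    switch(as.character(ob$rule),
           double = build_double_overbooking(n, ob$base, ob$extras,
                                             if (is.null(ob$start)) 1L else ob$start,
                                             if (is.null(ob$gap)) 6L else ob$gap),
           flight = build_flight_overbooking(n, ob$base, ob$extras),
           none = rep.int(as.integer(ob$base), n),
           stop("overbooking$rule must be double, flight or none"))
  } else as.integer(need("schedule"))
  capacity <- if (!is.null(x[["fleet"]])) {
    fl <- x[["fleet"]]
    build_capacity_profile(n, fl$fast, fl$slow,
                           if (is.null(fl$slow_phase)) 0L else fl$slow_phase)
  } else as.integer(need("regular_capacity"))
  co <- need("costs")
  costs <- cost_parameters(wc_ip = co$wc_ip, wc_op = co$wc_op,
                           oc_ip = co$oc_ip, oc_op = co$oc_op,
                           pc_ip = co$pc_ip, pc_op = co$pc_op)
  show_probs <- x[["show_probs"]]
  if (is.null(show_probs)) stop("config is missing required key: show_probs")
  if (is.list(show_probs)) show_probs <- lapply(show_probs, as.numeric)
  problem_config(n_regular = n, n_overtime = k,
                 regular_capacity = capacity,
                 overtime_capacity = overtime_capacity,
                 schedule = schedule, show_probs = show_probs,
                 p_ip = as.numeric(need("p_ip")), p_ep = as.numeric(need("p_ep")),
                 costs = costs)
}

#' Build a scenario grid
#'
#' Full cross of the experiment factors; the default levels reproduce the
#' 216-cell plan (2 overbooking rules x 2 overtime-resource levels x 3 cost
#' levels x 3 arrival levels x 6 policies).
#'
#' @param overbooking,overtime_resources,cost_level,arrival_level,policies
#'   vectors of factor levels.
#' @return data frame with one row per scenario-policy combination.
#' @export
scenario_grid <- function(overbooking = c("double", "flight"),
                          overtime_resources = c(1L, 2L),
                          cost_level = c("baseline", "low", "high"),
                          arrival_level = c("baseline", "low", "high"),
                          policies = c("optimal", "P1", "P2", "P3", "P4", "P5")) {
  expand.grid(overbooking = overbooking,
              overtime_resources = overtime_resources,
              cost_level = cost_level, arrival_level = arrival_level,
              policy = policies,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Run a scenario grid
#'
#' Builds one configuration per scenario (a scenario is a unique combination
#' of overbooking rule, overtime resources, cost level and arrival level),
#' solves it once if the optimal policy is requested, simulates every policy
#' of the scenario on common random days, and returns one summary row per
#' grid row.
#'
#' @param grid a data frame from [scenario_grid()].
#' @param n_days simulated days per policy per scenario.
#' @param seed integer seed (each scenario derives its own sub-seed).
#' @param config_builder function(overbooking, overtime_resources,
#'   cost_level, arrival_level) returning a `problem_config`; defaults to the
#'   full clinic day via [baseline_config()].
#' @return data frame: the grid columns plus mean/SD cost, 75th percentile,
#'   mean/SD unserved counts, and the Welch-test flag against the scenario's
#'   reference policy.
#' @export
run_grid <- function(grid, n_days = 10000L, seed = 1L, config_builder = NULL) {
  if (is.null(config_builder)) {
    config_builder <- function(overbooking, overtime_resources, cost_level,
                               arrival_level) {
      baseline_config(overbooking = overbooking,
                      overtime_resources = overtime_resources,
                      cost_level = cost_level, arrival_level = arrival_level)
    }
  }
  key <- interaction(grid$overbooking, grid$overtime_resources,
                     grid$cost_level, grid$arrival_level, drop = TRUE)
  out <- vector("list", nlevels(key))
  for (sc in seq_len(nlevels(key))) {
    rows <- which(key == levels(key)[sc])
    g1 <- grid[rows[1], ]
    cfg <- config_builder(g1$overbooking, g1$overtime_resources,
                          g1$cost_level, g1$arrival_level)
    cmp <- compare_policies(cfg, policies = grid$policy[rows],
                            n_days = n_days, seed = seed + sc)
    out[[sc]] <- cbind(grid[rows, , drop = FALSE],
                       cmp$summary[match(grid$policy[rows], cmp$summary$policy),
                                   -1, drop = FALSE])
  }
  res <- do.call(rbind, out)
  res <- res[order(as.integer(rownames(res))), ]
  rownames(res) <- NULL
  res
}
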