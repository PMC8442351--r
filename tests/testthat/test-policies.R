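test_that("priority policies fill remaining slots in the stated order", {
  p2 <- heuristic_policy("P2", 37)
  p3 <- heuristic_policy("P3", 37)
  expect_equal(unname(heuristic_action(p2, 1, c(1, 3, 1), 3)), c(0, 2, 1))
  expect_equal(unname(heuristic_action(p3, 1, c(1, 3, 1), 3)), c(1, 1, 1))
  # P1 with only the emergency waiting is forced regardless of randomness
  p1 <- heuristic_policy("P1", 37)
  for (rep in 1:5)
    expect_equal(unname(heuristic_action(p1, 1, c(0, 0, 1), 2)), c(0, 0, 1))
  # P1 always returns a feasible, non-idling action
  set.seed(9)
  for (rep in 1:50) {
    w <- c(sample(0:3, 1), sample(0:3, 1), sample(0:1, 1))
    a <- heuristic_action(p1, 1, w, 2)
    expect_true(all(a <= w) && sum(a) == min(2, sum(w)))
  }
})

test_that("mixed policies switch priority at mid-day and in overtime", {
  p4 <- heuristic_policy("P4", 37)
  p5 <- heuristic_policy("P5", 37)
  st <- c(1, 3, 0)
  # first half (periods 1-19): P4 serves inpatients first
  expect_equal(unname(heuristic_action(p4, 19, st, 3))[1:2], c(1, 2))
  expect_equal(unname(heuristic_action(p4, 20, st, 2))[1:2], c(0, 2))
  expect_equal(unname(heuristic_action(p5, 19, st, 3))[1:2], c(0, 3))
  expect_equal(unname(heuristic_action(p5, 20, st, 2))[1:2], c(1, 1))
  # overtime: P4 favours outpatients, P5 inpatients
  expect_equal(unname(heuristic_action(p4, 38, c(2, 2), 2)), c(0, 2))
  expect_equal(unname(heuristic_action(p5, 38, c(2, 2), 2)), c(2, 0))
})

test_that("a deterministic day replays the hand-computed trajectory", {
  # all probabilities 1, two periods of capacity 1 and one overtime slot
  cfg <- problem_config(2, 1, c(1, 1), 1, c(1, 1), list(1, 1), 1, 1,
                        cost_preset("baseline"))
  stream <- list(ip = c(TRUE, TRUE), ep = c(TRUE, TRUE),
                 shows = list(TRUE, TRUE))
  d <- simulate_day(heuristic_policy("P3", 2), cfg, stream)
  # period 1: state (1,1,1), serve EP; wait 0.78 + 1.56
  # period 2: state (2,2,1), serve EP; wait 1.56 + 3.12
  # overtime: (2,2), P3 serves the IP (2.76); penalty on (1,2)
  expect_equal(d$waiting_cost, 2.34 + 4.68)
  expect_equal(d$overtime_cost, 2.76)
  expect_equal(d$penalty_cost, 24.96 + 2 * 12.48)
  expect_equal(d$total_cost, d$waiting_cost + d$overtime_cost + d$penalty_cost)
  expect_equal(d$unserved_ip, 1)
  expect_equal(d$unserved_op, 2)
  # empty day costs nothing
  cfg0 <- problem_config(2, 1, c(2, 2), 1, c(0, 0), list(numeric(), numeric()),
                         0, 0, cost_preset())
  d0 <- simulate_day(heuristic_policy("P2", 2), cfg0)
  expect_equal(d0$total_cost, 0)
  expect_equal(d0$unserved_ip + d0$unserved_op, 0)
})

test_that("seeded simulation is reproducible and conserves patients", {
  cfg <- small_day_config()
  sol <- solve_mdp(cfg)
  r1 <- simulate_many(optimal_policy(sol), cfg, 50, seed = 123)
  r2 <- simulate_many(optimal_policy(sol), cfg, 50, seed = 123)
  expect_identical(r1$days, r2$days)
  # per-day accounting: arrivals = served + unserved, per patient type;
  # emergencies are always served in full
  for (p in c("optimal", "P1", "P4")) {
    pol <- if (p == "optimal") optimal_policy(sol)
           else heuristic_policy(p, cfg$n_regular)
    days <- simulate_many(pol, cfg, 200, seed = 7)$days
    expect_equal(days$arrived_ip, days$served_ip + days$unserved_ip)
    expect_equal(days$arrived_op, days$served_op + days$unserved_op)
    expect_equal(days$arrived_ep, days$served_ep)
    expect_equal(days$total_cost,
                 days$waiting_cost + days$overtime_cost + days$penalty_cost)
    expect_equal(days$served_regular + days$served_overtime,
                 days$served_ip + days$served_op + days$served_ep)
  }
})

test_that("occupancy is the served fraction of offered slots", {
  cfg <- problem_config(2, 1, c(1, 1), 1, c(1, 1), list(1, 1), 1, 1,
                        cost_preset())
  # deterministic saturated day: all 3 offered slots used
  d <- simulate_day(heuristic_policy("P3", 2), cfg,
                    list(ip = c(TRUE, TRUE), ep = c(TRUE, TRUE),
                         shows = list(TRUE, TRUE)))
  expect_equal(occupancy_rate(d, cfg), 1)
  # empty day: zero occupancy
  d0 <- simulate_day(heuristic_policy("P3", 2), cfg,
                     list(ip = c(FALSE, FALSE), ep = c(FALSE, FALSE),
                          shows = list(FALSE, FALSE)))
  expect_equal(occupancy_rate(d0, cfg), 0)
  # two-day sample: manual ratio
  both <- rbind(d, d0)
  expect_equal(occupancy_rate(both, cfg),
               sum(both$served_regular + both$served_overtime) / (2 * 3))
})

test_that("policy comparison computes Welch statistics against the reference", {
  cfg <- small_day_config()
  sol <- solve_mdp(cfg)
  cmp <- compare_policies(cfg, c("optimal", "P2", "P3"), n_days = 300,
                          seed = 42, solution = sol)
  expect_equal(cmp$summary$policy, c("optimal", "P2", "P3"))
  expect_equal(cmp$summary$t_vs_ref[1], 0)
  # cross-check one Welch statistic against the textbook formula
  x <- cmp$results$P2$days$total_cost
  y <- cmp$results$optimal$days$total_cost
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(cmp$summary$t_vs_ref[cmp$summary$policy == "P2"], tstat,
               tolerance = 1e-12)
  # a policy compared with itself on common streams is identical
  cmp2 <- compare_policies(cfg, c("P2", "P2"), n_days = 100, seed = 1)
  expect_equal(cmp2$results[[1]]$days$total_cost,
               cmp2$results[[2]]$days$total_cost)
})

test_that("the scenario grid runner returns one row per grid cell", {
  grid <- scenario_grid(overbooking = c("double", "flight"),
                        overtime_resources = 2,
                        cost_level = "baseline", arrival_level = "baseline",
                        policies = c("P2", "P3"))
  expect_equal(nrow(grid), 4)
  # the full factorial plan has 2 x 2 x 3 x 3 x 6 = 216 cells
  expect_equal(nrow(scenario_grid()), 216)
  res <- run_grid(grid, n_days = 60, seed = 5,
                  config_builder = function(ob, otr, cl, al)
                    small_day_config(ob, otr, cl, al))
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$mean_cost)))
  expect_true(all(res$mean_cost > 0))
})
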