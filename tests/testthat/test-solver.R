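test_that("terminal values are the linear penalty over ending states", {
  cfg <- small_day_config()
  tv <- terminal_values(cfg)
  expect_equal(tv[1, 1], 0)
  expect_equal(tv[2, 1], 24.96)
  expect_equal(tv[4, 5], 3 * 24.96 + 4 * 12.48)
})

test_that("overtime sweep minimizes overtime-plus-continuation cost", {
  cfg <- problem_config(1, 1, 1, 2, 2, list(c(0.5, 0.5)), 0, 0, cost_preset())
  ot <- backward_overtime(cfg, terminal_values(cfg))
  # state (1,1), capacity 2: serving both costs 5.52 and clears the penalty
  expect_equal(ot$values[[1]][2, 2], 5.52)
  expect_equal(ot$action_ip[[1]][2, 2], 1)
  expect_equal(ot$action_op[[1]][2, 2], 1)
  # capacity 1 with a dominant inpatient penalty: serve the inpatient
  cfg2 <- problem_config(1, 1, 1, 1, 2, list(c(0.5, 0.5)), 0, 0,
                         cost_parameters(0, 0, 1, 1, 100, 1))
  ot2 <- backward_overtime(cfg2, terminal_values(cfg2))
  expect_equal(ot2$action_ip[[1]][2, 2], 1)
  expect_equal(ot2$values[[1]][2, 2], 1 + 1)  # overtime for IP + penalty for OP
  # zero costs: value identically zero, tie broken toward more inpatients
  cfg3 <- problem_config(1, 1, 1, 1, 2, list(c(0.5, 0.5)), 0, 0,
                         cost_parameters(0, 0, 0, 0, 0, 0))
  ot3 <- backward_overtime(cfg3, terminal_values(cfg3))
  expect_true(all(ot3$values[[1]] == 0, na.rm = TRUE))
  expect_equal(ot3$action_ip[[1]][2, 2], 1)
})

test_that("a one-period model serves the inpatient to dodge the penalty", {
  cfg <- problem_config(1, 0, 1, integer(), 0, list(numeric()), 0, 0,
                        cost_parameters(0, 0, 0, 0, 10, 1))
  sol <- solve_mdp(cfg)
  expect_equal(sol$regular$values[[1]][2, 1, 1], 0)  # state (1,0,0): serve, no cost
  expect_equal(sol$regular$action_ip[[1]][2, 1, 1], 1)
})

test_that("solver value equals the exhaustive-policy minimum on a micro instance", {
  cfg <- micro_config()
  sol <- solve_mdp(cfg)
  expect_equal(sol$expected_day_cost, oracle_exhaustive_min(cfg),
               tolerance = 1e-9)
})

test_that("fully deterministic instance equals the outcome-tree expectation", {
  # every probability 1: a single trajectory, cost computable by hand
  cfg <- problem_config(2, 1, c(1, 1), 1, c(1, 1), list(1, 1), 1, 1,
                        cost_preset("baseline"))
  sol <- solve_mdp(cfg)
  # period 1 state (1,1,1): EP forced, IP and OP wait (wc .78+1.56); period 2
  # receives another (1,1,1): 2 IP + 2 OP + 1 EP waiting, serve EP, leaves 2+2
  # waiting (wc 2*.78+2*1.56); overtime serves 1, penalty on the remaining 3.
  # DP picks the split minimizing overtime+penalty: serve IP in overtime
  # (2.76), penalty on 1 IP + 2 OP = 24.96 + 24.96; total:
  expected <- (0.78 + 1.56) + (2 * 0.78 + 2 * 1.56) + 2.76 + 24.96 + 2 * 12.48
  expect_equal(sol$expected_day_cost, expected, tolerance = 1e-9)
})

test_that("degenerate empty day costs nothing", {
  cfg <- problem_config(2, 1, c(2, 2), 1, c(0, 0), list(numeric(), numeric()),
                        0, 0, cost_preset())
  sol <- solve_mdp(cfg)
  expect_equal(sol$expected_day_cost, 0)
})

test_that("values are monotone in the waiting counts and in lost capacity", {
  cfg <- small_day_config()
  sol <- solve_mdp(cfg)
  for (i in c(1, 4, 9, cfg$n_regular)) {
    v <- sol$regular$values[[i]]
    d <- dim(v)
    for (layer in 1:2) {
      m <- v[, , layer]
      if (d[1] > 1)
        expect_true(all(diff(m) >= -1e-9, na.rm = TRUE),
                    label = sprintf("V nondecreasing in w_ip, period %d", i))
      if (d[2] > 1)
        expect_true(all(t(diff(t(m))) >= -1e-9, na.rm = TRUE),
                    label = sprintf("V nondecreasing in w_op, period %d", i))
    }
    expect_true(all(v[, , 2] - v[, , 1] >= -1e-9, na.rm = TRUE))
    solved <- v[!is.na(v)]
    expect_true(all(is.finite(solved) & solved >= -1e-12))
  }
  # removing capacity never helps: same day with one fast scanner fewer
  cfg_small <- cfg
  cfg_small$regular_capacity <- pmax(cfg$regular_capacity - 1L, 1L)
  sol_small <- solve_mdp(cfg_small)
  expect_true(sol_small$expected_day_cost >= sol$expected_day_cost - 1e-9)
})

test_that("policy and value tables flatten every solved state", {
  cfg <- tiny_config()
  sol <- solve_mdp(cfg)
  pt <- policy_table(sol)
  vt <- value_table(sol)
  expect_equal(nrow(pt), count_states(cfg, TRUE))
  expect_equal(nrow(vt), count_states(cfg, TRUE))
  expect_true(all(pt$a_ip <= pt$w_ip & pt$a_op <= pt$w_op))
  reg <- pt[pt$period <= cfg$n_regular, ]
  expect_true(all(reg$a_ep == reg$w_ep))
  # round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pt, path, row.names = FALSE)
  expect_equal(utils::read.csv(path), pt)
  # lookups agree with the stored tables
  expect_equal(unname(optimal_action(sol, 1, c(1, 1, 1))[1:2]),
               c(sol$regular$action_ip[[1]][2, 2, 2],
                 sol$regular$action_op[[1]][2, 2, 2]))
})
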