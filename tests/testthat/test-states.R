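test_that("period-1 states are the opening-arrival box", {
  cfg <- baseline_config()  # Ag_1 = 3 under double booking
  st <- regular_states(1, cfg)
  expect_equal(nrow(st), 2 * 4 * 2)
  expect_true(any(apply(st, 1, function(r) all(r == 0))))  # empty state present
  expect_true(all(st[, "w_ip"] <= 1 & st[, "w_op"] <= 3 & st[, "w_ep"] <= 1))
})

test_that("restricted enumeration applies the joint backlog bound", {
  cfg <- baseline_config()
  st2 <- regular_states(2, cfg, restricted = TRUE)
  # period 2: cumulative schedule 5, one elapsed period of capacity 3
  expect_true(all(st2[, "w_ip"] + st2[, "w_op"] <= 5))
  expect_equal(nrow(st2), 30)
  # restricted sets are subsets of unrestricted sets, period by period
  for (i in c(1, 2, 5, 17, 37)) {
    r <- regular_states(i, cfg, TRUE)
    u <- regular_states(i, cfg, FALSE)
    expect_true(all(apply(r, 1, paste, collapse = ",") %in%
                      apply(u, 1, paste, collapse = ",")))
  }
})

test_that("overtime state sets match the capacity-consumption bounds", {
  cfg <- baseline_config()
  s1 <- overtime_states(1, cfg, restricted = TRUE)
  expect_true(all(s1[, 1] + s1[, 2] <= 61))
  expect_equal(nrow(s1), 1653)
  expect_equal(nrow(overtime_states(1, cfg, restricted = FALSE)), 38 * 81)
  # consumed overtime capacity tightens the bound by 2 per elapsed period
  expect_equal(max(rowSums(overtime_states(2, cfg))), 59)
  # when capacity outruns all possible arrivals only the empty state remains
  cfg2 <- problem_config(2, 1, c(5, 5), 1, c(0, 0), list(numeric(), numeric()),
                         0.5, 0.1, cost_preset())
  expect_equal(overtime_states(1, cfg2), matrix(0L, 1, 2,
               dimnames = list(NULL, c("w_ip", "w_op"))))
})

test_that("total state counts reproduce the published baseline figures", {
  cfg <- baseline_config()
  expect_equal(count_states(cfg, restricted = FALSE), 93534)
  expect_equal(count_states(cfg, restricted = TRUE), 52680)
  tab <- state_count_table(cfg)
  expect_equal(nrow(tab), 41)
  expect_true(all(tab$restricted <= tab$unrestricted))
})

test_that("feasible regular actions honour emergency priority and capacity", {
  a <- feasible_regular_actions(c(1, 3, 1), 3)
  expect_equal(nrow(a), 2)
  expect_setequal(apply(a, 1, paste, collapse = ","), c("0,2,1", "1,1,1"))
  expect_equal(feasible_regular_actions(c(0, 0, 0), 3),
               matrix(0L, 1, 3, dimnames = list(NULL, c("a_ip", "a_op", "a_ep"))))
  a2 <- feasible_regular_actions(c(2, 2, 0), 2)
  expect_equal(a2[, "a_ip"], c(2L, 1L, 0L))  # deterministic descending order
  expect_no_error(feasible_regular_actions(c(0, 0, 1), 1))
  expect_error(feasible_regular_actions(c(0, 0, 2), 1))
})

test_that("feasible overtime actions split min(capacity, waiting)", {
  expect_equal(feasible_overtime_actions(c(3, 1), 2)[, "b_ip"], c(2L, 1L))
  expect_equal(feasible_overtime_actions(c(0, 5), 2),
               matrix(c(0L, 2L), 1, dimnames = list(NULL, c("b_ip", "b_op"))))
  expect_equal(feasible_overtime_actions(c(1, 1), 2),
               matrix(c(1L, 1L), 1, dimnames = list(NULL, c("b_ip", "b_op"))))
})

test_that("action count matches its closed form and no slot idles", {
  set.seed(5)
  for (rep in 1:200) {
    w <- c(sample(0:4, 1), sample(0:4, 1), sample(0:1, 1))
    cap <- sample(1:4, 1)
    if (w[3] > cap) next
    acts <- feasible_regular_actions(w, cap)
    r <- min(cap, sum(w)) - w[3]
    expect_equal(nrow(acts), min(w[1], r) - max(0, r - w[2]) + 1)
    expect_true(all(rowSums(acts) == min(cap, sum(w))))
  }
})

test_that("restricted sets are closed under the dynamics", {
  cfg <- small_day_config()
  for (i in seq_len(cfg$n_regular - 1)) {
    st <- regular_states(i, cfg, TRUE)
    nxt <- regular_states(i + 1, cfg, TRUE)
    nxt_keys <- apply(nxt, 1, paste, collapse = ",")
    for (r in seq_len(nrow(st))) {
      acts <- feasible_regular_actions(st[r, ], cfg$regular_capacity[i])
      for (j in seq_len(nrow(acts))) {
        tr <- joint_transition(st[r, ], acts[j, ], i, cfg)
        tr <- tr[tr$prob > 0, ]
        expect_true(all(paste(tr$w_ip, tr$w_op, tr$w_ep, sep = ",") %in%
                          nxt_keys),
                    label = sprintf("closure at period %d", i))
      }
    }
  }
  # crossing into overtime: every post-action remainder of period N is a
  # feasible overtime-period-1 state
  n <- cfg$n_regular
  stN <- regular_states(n, cfg, TRUE)
  ot_keys <- apply(overtime_states(1, cfg, TRUE), 1, paste, collapse = ",")
  for (r in seq_len(nrow(stN))) {
    acts <- feasible_regular_actions(stN[r, ], cfg$regular_capacity[n])
    for (j in seq_len(nrow(acts))) {
      rem <- stN[r, 1:2] - acts[j, 1:2]
      expect_true(paste(rem, collapse = ",") %in% ot_keys)
    }
  }
})
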