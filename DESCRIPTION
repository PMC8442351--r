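Package: radalloc
Title: Dynamic Capacity Allocation for Radiology Services with No-Shows and Overbooking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a one-day capacity-allocation problem for a diagnostic
    imaging unit that serves inpatients, outpatients, and emergency patients
    on a small fleet of scanners with unequal service times. The problem is a
    finite-horizon Markov decision process: outpatients are pre-booked (with
    slot-specific show probabilities driving a Poisson-binomial arrival
    count), inpatients and emergency patients arrive as per-period Bernoulli
    events, and leftover demand spills into costed overtime periods with a
    terminal penalty for patients left unserved. The package enumerates
    feasible states and actions (with capacity-aware pruning of the state
    space), computes exact transition kernels, solves for the optimal policy
    by backward induction, and benchmarks it against priority heuristics in a
    seeded Monte-Carlo day simulator. Appointment overbooking rules
    (spread-out double booking and front-loaded flight-style booking) and a
    synthetic generator of per-slot show probabilities are included so the
    full pipeline runs without access to patient records.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
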