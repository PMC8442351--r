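# The default clinic day: 37 regular 15-minute periods (08:00-17:00) plus 4
# overtime periods; two fast CT scanners and one slow (30-minute) scanner;
# 74 booked outpatients plus 6 double-overbooked extras; two overtime
# resources. Costs and arrival probabilities are the baseline presets (US$).
# The scalar show_probs is a placeholder: replace it with per-slot values
# from gen-noshow / generate_show_probabilities() for heterogeneous no-shows.
n_regular: 37
overtime: {periods: 4, resources: 2}
overbooking: {rule: double, base: 2, extras: 6, start: 1, gap: 6}
fleet: {fast: 2, slow: 1, slow_phase: 0}
show_probs: 0.8
p_ip: 0.60
p_ep: 0.15
costs:
  wc_ip: 0.78
  wc_op: 1.56
  oc_ip: 2.76
  oc_op: 2.76
  pc_ip: 24.96
  pc_op: 12.48
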