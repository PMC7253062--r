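# Named scenario presets for the colony simulator.
#
# Every preset fully populates a scenario: a genotype block (arguments to
# genotype(); a `schedule: {F1, span}` entry is expanded via make_schedule(),
# and consumption_schedule: precipitous selects the built-in feeding
# shut-off), optional grid settings (arguments to make_gaussian_patch()),
# and sweep settings. Unstated fields fall back to the package defaults:
# M2 grid {0.99, 0.95, 0.90, 0.85, 0.80}, dispersal 1-9 cells/day,
# 100 replicates, 300x300 grid with ~1e6 food units, one L1 founder.

# Demonstration run: fast-aging-free genotype at maximal dispersal.
demo_boom:
  description: single colony, no reproductive decline, 50 progeny/day, M2 0.99, dispersal 9
  genotype: {F1: 50, F2: 0, M2: 0.99, s_fed: 0.9}
  M2_grid: [0.99]
  dispersal_grid: [9]
  replicates: 1

# No age-related reproductive decline, progeny production rate varied.
no_decline_2:
  description: 2 progeny per adult day, no reproductive decline
  genotype: {F1: 2, F2: 0}
no_decline_5:
  description: 5 progeny per adult day, no reproductive decline
  genotype: {F1: 5, F2: 0}
no_decline_8:
  description: 8 progeny per adult day, no reproductive decline
  genotype: {F1: 8, F2: 0}
no_decline_20:
  description: 20 progeny per adult day, no reproductive decline
  genotype: {F1: 20, F2: 0}
no_decline_30:
  description: 30 progeny per adult day, no reproductive decline
  genotype: {F1: 30, F2: 0}
no_decline_50:
  description: 50 progeny per adult day, no reproductive decline
  genotype: {F1: 50, F2: 0}

# Curtailed reproductive schedules (total brood tapering off over a span).
span10_30progeny:
  description: 30 progeny on day 1 tapering to zero at day 10
  genotype: {schedule: {F1: 30, span: 10}}
day1_only_4:
  description: 4 progeny on adult day 1 only
  genotype: {schedule: {F1: 4, span: 1}}

# Reproduction on adult day 1 only, brood size varied.
day1_only_2:
  description: 2 progeny on day 1 only
  genotype: {schedule: {F1: 2, span: 1}}
day1_only_5:
  description: 5 progeny on day 1 only
  genotype: {schedule: {F1: 5, span: 1}}
day1_only_20:
  description: 20 progeny on day 1 only
  genotype: {schedule: {F1: 20, span: 1}}
day1_only_50:
  description: 50 progeny on day 1 only
  genotype: {schedule: {F1: 50, span: 1}}

# Adult food consumption rate varied (4 progeny on day 1 only).
greed_low:
  description: adult consumption 50 units/day, 4 progeny on day 1 only
  genotype: {schedule: {F1: 4, span: 1}, c_adult: 50}
greed_mid:
  description: adult consumption 250 units/day, 4 progeny on day 1 only
  genotype: {schedule: {F1: 4, span: 1}, c_adult: 250}
greed_high:
  description: adult consumption 1000 units/day, 4 progeny on day 1 only
  genotype: {schedule: {F1: 4, span: 1}, c_adult: 1000}

# Age decline in adult feeding: abrupt shut-off after adult day 2.
feeding_decline_precipitous:
  description: feeding at 100% on days 1-2 and 0 from day 3, 4 progeny on day 1 only
  genotype: {schedule: {F1: 4, span: 1}, consumption_schedule: precipitous}

# Robustness variations around the day-1-only 4-progeny control.
founders_3:
  description: three founding L1 larvae
  genotype: {schedule: {F1: 4, span: 1}}
  founders: 3
founders_5:
  description: five founding L1 larvae
  genotype: {schedule: {F1: 4, span: 1}}
  founders: 5
founders_7:
  description: seven founding L1 larvae
  genotype: {schedule: {F1: 4, span: 1}}
  founders: 7
grid_200:
  description: 200 x 200 grid, same patch
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {width: 200, height: 200}
grid_500:
  description: 500 x 500 grid, same patch
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {width: 500, height: 500}
patch_x5:
  description: fivefold larger food patch (~5e6 units)
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {total_food: 5.0e+6}
patch_half:
  description: halved food patch (~5e5 units)
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {total_food: 5.0e+5}
patch_flatter:
  description: flatter patch morphology (sigma x 2)
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {sigma: 10}
patch_steeper:
  description: steeper patch morphology (sigma x 0.5)
  genotype: {schedule: {F1: 4, span: 1}}
  grid: {sigma: 2.5}
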