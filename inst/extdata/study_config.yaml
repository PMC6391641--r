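# Example study configuration. Omitted fields keep the package defaults;
# the schedule block may be dropped entirely to use the shipped 24-week ramp.
n_weeks: 24
cohort_sizes: [34, 31, 31]
study_timezone: America/New_York
criteria:
  kcal_threshold_female: 1000
  kcal_threshold_male: 1200
  min_logging_days: 5
  require_weekend_day: true
  min_weighins_per_week: 2
  same_day_gaming_fraction: 0.10
schedule:
  weekly_cents: [500, 500, 500, 500, 800, 800, 800, 800,
                 1000, 1000, 1000, 1000, 1200, 1200, 1200, 1200,
                 1700, 1700, 1700, 1700, 2000, 2000, 2400, 2800]
  weekly_floor_by_cohort: {"1": 0, "2": 0, "3": 200}
  total_cap: 30000
  weekly_cap: 2800
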