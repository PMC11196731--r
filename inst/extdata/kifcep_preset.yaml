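# Program configuration at the scale of the Kangaroo Island feral cat
# eradication case study. Unit costs are plausible placeholders, NOT
# calibrated program figures; edit every value for your own program.
# Equivalent to camtrapdecide::kifcep_preset().
n_cameras: 200
program_years: 3
service_rounds_per_year:
  manual_manual: 365   # daily SD retrieval: timely detection is paramount
  manual_ai: 365
  connected_ai: 1      # one annual maintenance visit; solar + 4G otherwise
staff_days_per_round: 4
round_km: 500          # sites 30-75 km from the operations base
staff_day_cost: 400
vehicle_cost_per_km: 0.85
images_per_year: 600000
manual_rate_images_per_day: 1500
ai_fee_per_image: 0.01
upload_staff_days_per_round: 0.25
connectivity_cost_per_camera_year: 180
hardware_unit_costs:
  camera_basic: 500
  camera_4g: 800
  solar_panel: 150
  antenna: 130
  sd_card: 25
  battery_set: 15
antenna_fraction: 0.25
battery_sets_per_round: 0.03
emission_g_per_km: 220  # manufacturer figure for a diesel 4WD utility
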