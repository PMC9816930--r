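# Example run configuration: eight published Danish vitamin-D fortification
# scenarios (a common cap in ug per 10 MJ and an allow-list of food groups).
# Point `inputs` at a survey written by `fortiplan simulate` (or real data in
# the same CSV dialects) before running `fortiplan run-all --config ...`.
seed: 1
output_dir: fortiplan_out
inputs:
  persons: synthetic_survey/persons.csv
  records: synthetic_survey/records.csv
  food_table: synthetic_survey/food_table.csv
  food_groups: synthetic_survey/food_groups.csv
strata: default
targets:
  default:
    ri: 10          # recommended intake, ug/day, every stratum
  age_based_ul: true  # UL 50 ug/day for strata within ages 4-10, else 100
scenarios:
  - name: s1_all_cap12
    cap_ug_per_10mj: 12
    allowed_groups: all_fortifiable
  - name: s2_all_cap25
    cap_ug_per_10mj: 25
    allowed_groups: all_fortifiable
  - name: s3_five_cap20
    cap_ug_per_10mj: 20
    allowed_groups: [milk, cheese, cereals, fats, juice]
  - name: s4_four_cap20
    cap_ug_per_10mj: 20
    allowed_groups: [milk, cheese, cereals, fats]
  - name: s5_five_cap25
    cap_ug_per_10mj: 25
    allowed_groups: [milk, cheese, cereals, fats, juice]
  - name: s6_four_cap25
    cap_ug_per_10mj: 25
    allowed_groups: [milk, cheese, cereals, fats]
  - name: s7_five_cap30
    cap_ug_per_10mj: 30
    allowed_groups: [milk, cheese, cereals, fats, juice]
  - name: s8_four_cap30
    cap_ug_per_10mj: 30
    allowed_groups: [milk, cheese, cereals, fats]
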