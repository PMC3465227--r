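model:
  cohort_size: 1000
  start_age: 40
  horizon: 45
  cycle_length: 1
  discount_rate: 0.029999999999999999
  wtpt: 45000
  initial_occupancy:
    HD: 0
    PD: 0
    Tx: 1
    LRHD: 0
    LRPD: 0
    D: 0
transitions:
  hd_pd: 0.014999999999999999
  hd_tx: 0.059999999999999998
  pd_hd: 0.050000000000000003
  pd_tx: 0.080000000000000002
  tx_exit_to_hd: 0.035000000000000003
  tx_exit_to_pd: 0.0035000000000000001
  lr_tunnel: yes
mortality:
  q0: 0.029999999999999999
  growth: 0.070000000000000007
  lr_first_year_survival: 0.72999999999999998
costs:
  first_year:
    HD: 2545
    PD: 1819
    Tx: 36772
    LRHD: 6627
    LRPD: 3748
    D: 0
  prevalence:
    HD: 31912
    PD: 24996
    Tx: 6030
    LRHD: 31912
    LRPD: 24996
    D: 0
  components:
    HD:
      hospitalization_days: 890
      rHuEPO: 636
      iv_iron: 254
      access_or_surgery: 700
      other: 65
    PD:
      hospitalization_days: 364
      rHuEPO: 546
      iv_iron: 182
      access_or_surgery: 640
      other: 87
uplifts:
  hospitalization: 0.96999999999999997
  rhuepo: 0.68999999999999995
  iv_iron: 0.46999999999999997
  nonscheduled_surcharge:
    HD: 2660.48
    PD: 1113.6399999999999
utilities:
  HD: 0.68999999999999995
  PD: 0.68999999999999995
  Tx: 0.81000000000000005
  LRHD: 0.53000000000000003
  LRPD: 0.53000000000000003
  D: 0
psa:
  replicates: 1000
  relative_sd: 0.10000000000000001
  wtpt_grid:
  - 0
  - 1000
  - 2000
  - 3000
  - 4000
  - 5000
  - 6000
  - 7000
  - 8000
  - 9000
  - 10000
  - 11000
  - 12000
  - 13000
  - 14000
  - 15000
  - 16000
  - 17000
  - 18000
  - 19000
  - 20000
  - 21000
  - 22000
  - 23000
  - 24000
  - 25000
  - 26000
  - 27000
  - 28000
  - 29000
  - 30000
  - 31000
  - 32000
  - 33000
  - 34000
  - 35000
  - 36000
  - 37000
  - 38000
  - 39000
  - 40000
  - 41000
  - 42000
  - 43000
  - 44000
  - 45000
  - 46000
  - 47000
  - 48000
  - 49000
  - 50000
  - 51000
  - 52000
  - 53000
  - 54000
  - 55000
  - 56000
  - 57000
  - 58000
  - 59000
  - 60000
  - 61000
  - 62000
  - 63000
  - 64000
  - 65000
  - 66000
  - 67000
  - 68000
  - 69000
  - 70000
  - 71000
  - 72000
  - 73000
  - 74000
  - 75000
  - 76000
  - 77000
  - 78000
  - 79000
  - 80000
  - 81000
  - 82000
  - 83000
  - 84000
  - 85000
  - 86000
  - 87000
  - 88000
  - 89000
  - 90000
  seed: 1234
productivity:
  loss_per_death_year: 29345
  working_age_limit: 67
  enabled: no
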