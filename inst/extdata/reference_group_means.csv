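day_subset,group,feature,mean
all7,AI,sed_bouts_1_3,81.8
all7,AI,sed_bouts_4_5,40.74
all7,AI,sed_bouts_6_30,218.45
all7,AI,sed_bouts_31_60,77.48
all7,AI,sed_bouts_gt60,123.18
all7,AI,sed_total,541.65
all7,AI,wake_total,297.51
all7,HC,sed_bouts_1_3,94.27
all7,HC,sed_bouts_4_5,44.45
all7,HC,sed_bouts_6_30,187.23
all7,HC,sed_bouts_31_60,56.05
all7,HC,sed_bouts_gt60,78.94
all7,HC,sed_total,460.94
all7,HC,wake_total,378.39
weekday,AI,sed_bouts_1_3,83.32
weekday,AI,sed_bouts_4_5,41.25
weekday,AI,sed_bouts_6_30,228.24
weekday,AI,sed_bouts_31_60,72.49
weekday,AI,sed_bouts_gt60,120.41
weekday,AI,sed_total,545.72
weekday,AI,wake_total,293.427
weekday,HC,sed_bouts_1_3,95.04
weekday,HC,sed_bouts_4_5,45.15
weekday,HC,sed_bouts_6_30,188.46
weekday,HC,sed_bouts_31_60,48.90
weekday,HC,sed_bouts_gt60,81.53
weekday,HC,sed_total,458.96
weekday,HC,wake_total,380.43
weekend,AI,sed_bouts_1_3,78
weekend,AI,sed_bouts_4_5,39.47
weekend,AI,sed_bouts_6_30,193.97
weekend,AI,sed_bouts_31_60,89.93
weekend,AI,sed_bouts_gt60,130.10
weekend,AI,sed_total,531.47
weekend,AI,wake_total,307.70
weekend,HC,sed_bouts_1_3,92.34
weekend,HC,sed_bouts_4_5,42.98
weekend,HC,sed_bouts_6_30,184.16
weekend,HC,sed_bouts_31_60,73.91
weekend,HC,sed_bouts_gt60,72.48
weekend,HC,sed_total,465.86
weekend,HC,wake_total,373.30
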