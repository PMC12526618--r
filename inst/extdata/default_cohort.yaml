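n_participants: 30
conditions:
- sham
- m1_tdcs
- dlpfc_tdcs
phases:
- p0_30
- p30_60
- p60_100
fs: 1000.0
phase_distances:
  p0_30: 30.0
  p30_60: 30.0
  p60_100: 40.0
velocity_mode: table
noise_sd_velocity: 0.15
participant_sd: 0.2
band_amplitude: 1.0
broadband_sd: 0.3
participant_amp_sd: 0.2
seed: 1
velocity_params:
- condition: sham
  phase: p0_30
  mean: 9.26
  sd: 0.44
- condition: sham
  phase: p30_60
  mean: 11.12
  sd: 0.6
- condition: sham
  phase: p60_100
  mean: 10.08
  sd: 0.32
- condition: m1_tdcs
  phase: p0_30
  mean: 9.35
  sd: 0.4
- condition: m1_tdcs
  phase: p30_60
  mean: 11.59
  sd: 0.67
- condition: m1_tdcs
  phase: p60_100
  mean: 9.88
  sd: 0.34
- condition: dlpfc_tdcs
  phase: p0_30
  mean: 8.97
  sd: 0.49
- condition: dlpfc_tdcs
  phase: p30_60
  mean: 11.32
  sd: 0.59
- condition: dlpfc_tdcs
  phase: p60_100
  mean: 9.85
  sd: 0.4
coherence_targets:
- condition: sham
  phase: p0_30
  pair: RA-BF
  band: alpha
  target: 0.2
- condition: sham
  phase: p0_30
  pair: RA-BF
  band: beta
  target: 0.41
- condition: sham
  phase: p0_30
  pair: RA-BF
  band: gamma
  target: 0.88
- condition: sham
  phase: p0_30
  pair: TA-GL
  band: alpha
  target: 0.12
- condition: sham
  phase: p0_30
  pair: TA-GL
  band: beta
  target: 0.25
- condition: sham
  phase: p0_30
  pair: TA-GL
  band: gamma
  target: 0.68
- condition: sham
  phase: p30_60
  pair: RA-BF
  band: alpha
  target: 0.24
- condition: sham
  phase: p30_60
  pair: RA-BF
  band: beta
  target: 0.44
- condition: sham
  phase: p30_60
  pair: RA-BF
  band: gamma
  target: 0.55
- condition: sham
  phase: p30_60
  pair: TA-GL
  band: alpha
  target: 0.09
- condition: sham
  phase: p30_60
  pair: TA-GL
  band: beta
  target: 0.08
- condition: sham
  phase: p30_60
  pair: TA-GL
  band: gamma
  target: 0.34
- condition: sham
  phase: p60_100
  pair: RA-BF
  band: alpha
  target: 0.23
- condition: sham
  phase: p60_100
  pair: RA-BF
  band: beta
  target: 0.53
- condition: sham
  phase: p60_100
  pair: RA-BF
  band: gamma
  target: 0.15
- condition: sham
  phase: p60_100
  pair: TA-GL
  band: alpha
  target: 0.22
- condition: sham
  phase: p60_100
  pair: TA-GL
  band: beta
  target: 0.51
- condition: sham
  phase: p60_100
  pair: TA-GL
  band: gamma
  target: 0.95
- condition: m1_tdcs
  phase: p0_30
  pair: RA-BF
  band: alpha
  target: 0.25
- condition: m1_tdcs
  phase: p0_30
  pair: RA-BF
  band: beta
  target: 0.48
- condition: m1_tdcs
  phase: p0_30
  pair: RA-BF
  band: gamma
  target: 0.95
- condition: m1_tdcs
  phase: p0_30
  pair: TA-GL
  band: alpha
  target: 0.15
- condition: m1_tdcs
  phase: p0_30
  pair: TA-GL
  band: beta
  target: 0.3
- condition: m1_tdcs
  phase: p0_30
  pair: TA-GL
  band: gamma
  target: 0.75
- condition: m1_tdcs
  phase: p30_60
  pair: RA-BF
  band: alpha
  target: 0.32
- condition: m1_tdcs
  phase: p30_60
  pair: RA-BF
  band: beta
  target: 0.55
- condition: m1_tdcs
  phase: p30_60
  pair: RA-BF
  band: gamma
  target: 0.7
- condition: m1_tdcs
  phase: p30_60
  pair: TA-GL
  band: alpha
  target: 0.12
- condition: m1_tdcs
  phase: p30_60
  pair: TA-GL
  band: beta
  target: 0.11
- condition: m1_tdcs
  phase: p30_60
  pair: TA-GL
  band: gamma
  target: 0.45
- condition: m1_tdcs
  phase: p60_100
  pair: RA-BF
  band: alpha
  target: 0.2
- condition: m1_tdcs
  phase: p60_100
  pair: RA-BF
  band: beta
  target: 0.6
- condition: m1_tdcs
  phase: p60_100
  pair: RA-BF
  band: gamma
  target: 0.12
- condition: m1_tdcs
  phase: p60_100
  pair: TA-GL
  band: alpha
  target: 0.25
- condition: m1_tdcs
  phase: p60_100
  pair: TA-GL
  band: beta
  target: 0.58
- condition: m1_tdcs
  phase: p60_100
  pair: TA-GL
  band: gamma
  target: 0.95
- condition: dlpfc_tdcs
  phase: p0_30
  pair: RA-BF
  band: alpha
  target: 0.18
- condition: dlpfc_tdcs
  phase: p0_30
  pair: RA-BF
  band: beta
  target: 0.39
- condition: dlpfc_tdcs
  phase: p0_30
  pair: RA-BF
  band: gamma
  target: 0.82
- condition: dlpfc_tdcs
  phase: p0_30
  pair: TA-GL
  band: alpha
  target: 0.1
- condition: dlpfc_tdcs
  phase: p0_30
  pair: TA-GL
  band: beta
  target: 0.22
- condition: dlpfc_tdcs
  phase: p0_30
  pair: TA-GL
  band: gamma
  target: 0.65
- condition: dlpfc_tdcs
  phase: p30_60
  pair: RA-BF
  band: alpha
  target: 0.2
- condition: dlpfc_tdcs
  phase: p30_60
  pair: RA-BF
  band: beta
  target: 0.4
- condition: dlpfc_tdcs
  phase: p30_60
  pair: RA-BF
  band: gamma
  target: 0.5
- condition: dlpfc_tdcs
  phase: p30_60
  pair: TA-GL
  band: alpha
  target: 0.08
- condition: dlpfc_tdcs
  phase: p30_60
  pair: TA-GL
  band: beta
  target: 0.07
- condition: dlpfc_tdcs
  phase: p30_60
  pair: TA-GL
  band: gamma
  target: 0.3
- condition: dlpfc_tdcs
  phase: p60_100
  pair: RA-BF
  band: alpha
  target: 0.25
- condition: dlpfc_tdcs
  phase: p60_100
  pair: RA-BF
  band: beta
  target: 0.5
- condition: dlpfc_tdcs
  phase: p60_100
  pair: RA-BF
  band: gamma
  target: 0.16
- condition: dlpfc_tdcs
  phase: p60_100
  pair: TA-GL
  band: alpha
  target: 0.2
- condition: dlpfc_tdcs
  phase: p60_100
  pair: TA-GL
  band: beta
  target: 0.48
- condition: dlpfc_tdcs
  phase: p60_100
  pair: TA-GL
  band: gamma
  target: 0.9
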