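# Cumulative marginal counts transcribed from the baseline threshold
# tables of a large prospective LDCT lung-cancer-screening cohort
# (11 355 participants screened; 5 929 with >=1 solid nodule, of whom 228
# proved malignant within follow-up). Counts are cumulative strictly
# below each threshold among nodule participants, per sizing scale.
# The participant-level fixture reconstructed from these counts is
# synthetic: only these marginal cells are faithful.
total_participants: 5929
total_cancers: 228
no_nodule_participants: 4809
no_nodule_cancers: 37
unsegmentable_count: 144
unsegmentable_diameter_range: [6.0, 8.0]
bins:
  - {scale: diameter, threshold: 5.0, participants_below: 1421, cancers_below: 15}
  - {scale: diameter, threshold: 6.0, participants_below: 2378, cancers_below: 21}
  - {scale: diameter, threshold: 8.0, participants_below: 4074, cancers_below: 51}
  - {scale: volume, threshold: 80.0, participants_below: 3756, cancers_below: 30}
  - {scale: volume, threshold: 100.0, participants_below: 4183, cancers_below: 34}
  - {scale: volume, threshold: 300.0, participants_below: 5418, cancers_below: 76}
# Of participants at/above each rule-in size threshold, how many are
# Brock-gate (>=10%) positive, by outcome.
brock_gates:
  - {scale: diameter, threshold: 8.0, gated_cancers: 149, gated_benign: 330}
  - {scale: volume, threshold: 300.0, gated_cancers: 139, gated_benign: 198}
# Participants with >=1 perifissural-typical nodule; cancers include
# registry-identified cases whose perifissural nodule is assumed malignant.
perifissural_participants: 3823
perifissural_cancers: 8
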