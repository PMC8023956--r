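# Default pass/fail criteria. `wire` applies at competency levels 0 and 1
# (K-wire placement); `dhs` applies at level 2 (full procedure).
# Comparators: le/ge/lt/gt/eq test against `threshold`; `in` tests membership
# of `allowed`. Failure is strictly beyond each bound (boundary values pass).
wire:
  - id: tad
    metric: tip_apex_distance
    comparator: le
    threshold: 20.0
  - id: placement_zone
    metric: placement_zone
    comparator: in
    allowed: [center-center, center-inferior]
  - id: cortical_breach
    metric: cortical_breach
    comparator: eq
    threshold: false
  - id: kwire_attempts
    metric: kwire_attempts
    comparator: le
    threshold: 3
dhs:
  - id: tad
    metric: tip_apex_distance
    comparator: le
    threshold: 20.0
  - id: placement_zone
    metric: placement_zone
    comparator: in
    allowed: [center-center, center-inferior]
  - id: cortical_breach
    metric: cortical_breach
    comparator: eq
    threshold: false
  - id: kwire_attempts
    metric: kwire_attempts
    comparator: le
    threshold: 3
  - id: reamer_breach
    metric: reamer_breach
    comparator: eq
    threshold: false
  - id: plate_angle
    metric: plate_angle_appropriate
    comparator: eq
    threshold: true
  - id: shaft_screw_bicortical
    metric: shaft_screw_bicortical
    comparator: eq
    threshold: true
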