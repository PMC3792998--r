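# Per-class t-distribution parameters for Argos location error, in decimal
# degrees of longitude/latitude. One entry per location class (3 best .. B
# worst). These are editable configuration: the defaults follow the
# magnitude ordering of published class-specific Argos error estimates
# (sub-km for class 3 up to ~10 km for class B), with heavier tails
# (smaller nu) for the low-quality classes.
classes:
  "3": {nu: 10.0, tau_lon: 0.0040, tau_lat: 0.0030}
  "2": {nu: 8.0,  tau_lon: 0.0080, tau_lat: 0.0060}
  "1": {nu: 5.0,  tau_lon: 0.0120, tau_lat: 0.0090}
  "0": {nu: 3.0,  tau_lon: 0.0350, tau_lat: 0.0250}
  "A": {nu: 2.5,  tau_lon: 0.0550, tau_lat: 0.0400}
  "B": {nu: 2.0,  tau_lon: 0.0900, tau_lat: 0.0650}
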