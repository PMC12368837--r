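# Example interface configuration: only the entries that differ from the
# package defaults need to be given.
source:
  P1: 800          # Pa, first-stage background pressure
aerosol:
  median_diameter: 1.0e-6
declustering:
  T50_ref: 750
guide:
  U_star: 3
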