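# Template configuration for ivdmicro. Every key is optional; omitted keys
# fall back to package defaults. Lengths in mm, concentrations in mM
# (oxygen in %), diffusivities in mm^2/h, rates in nmol/(10^6 cells)/h.
geometry:
  halfwidth_ap: 10        # placeholder caprine L3-4 half-extents
  halfwidth_lat: 12.5
  height: 4
  cep_thickness: 0.6
  np_fraction: 0.5
  grid_spacing: 0.2
metabolism:
  total_density: {NP: 6133, AF: 19732}   # cells/mm^3
  viability: {degenerated: 0.40, healthy: 0.80}
  rates:                                  # measured per-cell rates
    degenerated: {ocr: 5.5, lpr: 30}
    healthy: {ocr: 3.8, lpr: 16}
  ph_lactate: {intercept: 7.49636, slope: 0.09972}
transport:
  diffusivity:
    degenerated:
      oxygen:  {NP: 3.08, AF_radial: 3.08, AF_axial: 2.2, CEP: 1.74}
      glucose: {NP: 0.45, AF_radial: 0.37, AF_axial: 0.45, CEP: 0.06}
      lactate: {NP: 0.61, AF_radial: 0.61, AF_axial: 0.5, CEP: 0.1}
    healthy:
      oxygen:  {NP: 3.08, AF_radial: 3.08, AF_axial: 2.2, CEP: 3.53}
      glucose: {NP: 0.45, AF_radial: 0.37, AF_axial: 0.45, CEP: 0.12}
      lactate: {NP: 0.61, AF_radial: 0.61, AF_axial: 0.5, CEP: 0.21}
boundaries:
  degenerated:
    oxygen:  {AF_OUTER: 15, CEP_FACE: 12}
    glucose: {AF_OUTER: 1.4, CEP_FACE: 0.8}
    lactate: {AF_OUTER: 6.3, CEP_FACE: 10.5}
  healthy:
    oxygen:  {AF_OUTER: 15, CEP_FACE: 12}
    glucose: {AF_OUTER: 4.0, CEP_FACE: 2.3}
    lactate: {AF_OUTER: 2.5, CEP_FACE: 1.0}
gag:
  degradation_rate: 0.086    # /year
  initial_content: 0         # ug/mm^3
  days_per_year: 365
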