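# Donor-archetype defaults for the synthetic cohort generator.
#
# Values are calibrated once to the cohort-level facts the analysis is
# designed around; each non-obvious number carries a short note. Users may
# override any field via `donor_archetype(..., override = list())`.
#
# Units: areas um^2; densities: islets per mm^2 parenchyma; CD45 rates:
# expected cells per 1000 um^2 of compartment; curve rate k: per um^2 of
# islet area in f(A) = plateau + span * exp(-k * A).

common:
  # lognormal islet areas, truncated below at the 1000 um^2 islet
  # definition; (meanlog, sdlog) solved so that, conditional on >= 1000,
  # 50% of islets fall below 3000 um^2 and 82% inside 10^3-10^4 um^2
  size_log_mean: 6.009057
  size_log_sd: 2.054064
  shape_noise: 0.08          # radial Fourier amplitude; circularity ~0.9
  islet_vertices: 64
  nuclei_density: 8.0        # background nuclei per 1000 um^2 (8e3 / mm^2)
  min_islet_area: 1000
  # endocrine cell-type territory curves (fraction of islet area vs area A);
  # beta/gamma content falls and alpha content rises with islet size
  composition_curves:
    beta:  {plateau: 0.35, span:  0.25, k: 1.0e-4}
    alpha: {plateau: 0.45, span: -0.25, k: 1.0e-4}
    delta: {plateau: 0.08, span:  0.04, k: 2.0e-4}
    gamma: {plateau: 0.03, span:  0.07, k: 2.0e-4}
  composition_noise_sd: 0.04
  deficient_max_fraction: 0.008   # "< 1%" phenotypes are planted below 0.8%
  chga_fraction: {mean: 0.95, sd: 0.02}
  chga_fraction_low: {mean: 0.05, sd: 0.01}  # CHGA-faint PPY-dominant islets
  stain_ratios:              # secondary stains nested inside territories
    proins_hi: 0.60          # hi-threshold area / total ProINS area
    ins: 0.90
    iapp: 0.75
    progcg: 0.85
  gamma_dominant_fraction: 0.80   # PPY territory share in PPY-dominant islets
  # CD45 point-process rates (cells per 1000 um^2), by islet burden class:
  # baseline applies to low-burden islets, high_burden to the
  # immune-engaged insulin-containing class, residual to alpha-only islets that
  # retain 1 + Poisson cells (2-3 cells per islet on average)
  cd45_rates:
    baseline:    {intra: 0.001, peri: 0.003}
    high_burden: {intra: 0.250, peri: 0.500}
    residual:    {intra: 0.060, peri: 0.130}
  insulitis_min_cells: 15
  insulitis_extra_mean: 10   # insulitic plants get 15 + Poisson(10) cells

groups:
  # idi_fraction: printed hallmark fractions (T1DS PT ~64% / PH 84%,
  # T1DL > 99%); Ctrl/AAb values are low/intermediate by design.
  # gcg_deficient_small_fraction: branch probability for islets < 3000 um^2
  # (0.3x above); marginals land near the printed ~34% (Ctrl PT) and
  # ~56% (Ctrl PH) GCG-deficient fractions.
  # high_burden_fraction_ici: probability that an insulin-containing islet
  # (any label) carries a high CD45 burden; solved against the point-process
  # rates so the fraction of islets with >= 1 associated CD45 cell lands at
  # ~25% (Ctrl), ~50% (AAb/T1DS, printed band 45-55%) and recedes in T1DL.
  Ctrl:
    islet_density: 2.0
    idi_fraction: {PT: 0.010, PH: 0.020}
    gcg_deficient_small_fraction: {PT: 0.52, PH: 0.86}
    ppy_uncinate_fraction: {PT: 0.02, PH: 0.18}
    high_burden_fraction_ici: 0.26
    p_gamma_given_idi: {PT: 0.30, PH: 0.40}
    p_residual_given_alpha_idi: 0.0
    insulitic_islet_fraction: {PT: 0.000, PH: 0.000}
  AAb:
    islet_density: 1.7      # ~1.6-fold loss of the smallest islets
    idi_fraction: {PT: 0.080, PH: 0.100}
    gcg_deficient_small_fraction: {PT: 0.38, PH: 0.60}
    ppy_uncinate_fraction: {PT: 0.02, PH: 0.18}
    high_burden_fraction_ici: 0.49
    p_gamma_given_idi: {PT: 0.15, PH: 0.30}
    p_residual_given_alpha_idi: 0.45
    insulitic_islet_fraction: {PT: 0.008, PH: 0.006}
  T1DS:
    islet_density: 1.5
    idi_fraction: {PT: 0.640, PH: 0.840}
    gcg_deficient_small_fraction: {PT: 0.23, PH: 0.40}
    ppy_uncinate_fraction: {PT: 0.02, PH: 0.18}
    high_burden_fraction_ici: 0.48
    p_gamma_given_idi: {PT: 0.06, PH: 0.17}
    p_residual_given_alpha_idi: 0.50
    insulitic_islet_fraction: {PT: 0.032, PH: 0.013}
  T1DL:
    islet_density: 1.2
    idi_fraction: {PT: 0.995, PH: 0.995}
    gcg_deficient_small_fraction: {PT: 0.15, PH: 0.30}
    ppy_uncinate_fraction: {PT: 0.02, PH: 0.18}
    high_burden_fraction_ici: 0.00
    p_gamma_given_idi: {PT: 0.06, PH: 0.25}
    p_residual_given_alpha_idi: 0.30
    insulitic_islet_fraction: {PT: 0.005, PH: 0.004}
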