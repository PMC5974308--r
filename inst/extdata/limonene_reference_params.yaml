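# Reference kinetic constants for the 10-state Michaelis-Menten model of the
# limonene-producing mevalonate pathway. This is a synthetic, documented
# reference set (not a transcription of literature values), calibrated once
# so that intermediate metabolites show rise/peak/decline dynamics over a
# 72 h fermentation under the reference enzyme-expression profiles.
# Units: concentrations in arbitrary mM-like units, time in hours.
kinetic_constants:
  v_accoa: 0.30        # constant acetyl-CoA supply flux (host metabolism proxy)
  kcat_atob: 0.9
  km_atob: 0.8
  kcat_hmgs: 0.8
  km_hmgs: 0.5
  kcat_hmgr: 0.6
  km_hmgr: 0.6
  kcat_mk: 0.7
  km_mk: 0.7
  kcat_pmk: 0.7
  km_pmk: 0.7
  kcat_pmd: 0.8
  km_pmd: 0.5
  kcat_idi_f: 1.5
  km_idi_f: 0.4
  kcat_idi_r: 0.5
  km_idi_r: 0.6
  kcat_gpps: 0.9
  km_gpps_ipp: 0.3
  km_gpps_dmapp: 0.3
  kcat_ls: 0.5
  km_ls: 0.5
initial_metabolites:
  acetyl_coa: 0.5
  acetoacetyl_coa: 0.0
  hmg_coa: 0.0
  mevalonate: 0.0
  mevalonate_p: 0.0
  mevalonate_pp: 0.0
  ipp: 0.0
  dmapp: 0.0
  gpp: 0.0
  limonene: 0.0
# Reference leaky-Hill expression profiles: upstream enzymes induce early,
# the downstream condensation/synthase steps ramp later, which produces the
# transient accumulation of IPP/DMAPP and GPP.
reference_hill:
  AtoB: {k_f: 1.0, k_m: 4.0, k_l: 0.05}
  HMGS: {k_f: 1.0, k_m: 4.0, k_l: 0.05}
  HMGR: {k_f: 1.0, k_m: 4.0, k_l: 0.05}
  MK:   {k_f: 1.0, k_m: 6.0, k_l: 0.05}
  PMK:  {k_f: 1.0, k_m: 6.0, k_l: 0.05}
  PMD:  {k_f: 1.0, k_m: 6.0, k_l: 0.05}
  Idi:  {k_f: 1.0, k_m: 8.0, k_l: 0.05}
  GPPS: {k_f: 1.0, k_m: 20.0, k_l: 0.05}
  LS:   {k_f: 1.0, k_m: 24.0, k_l: 0.05}
# Log-uniform sampling ranges for virtual-strain Hill coefficients
# (about two orders of magnitude around the reference expression levels).
hill_sampling_ranges:
  k_f: {lower: 0.1, upper: 10.0}
  k_m: {lower: 2.0, upper: 32.0}
  k_l: {lower: 0.005, upper: 0.5}
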