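# Five-group study presets: untreated control, enzyme-weakened ectatic model
# (KC), and KC treated with tissue-derived particles from cornea (COR),
# cartilage (CART) or lymph node (LN). Only the ordinal relationships are
# meaningful (KC least dense / largest fibrils / weakest / least stable;
# LN densest with the smallest fibrils; COR restored toward control);
# absolute values are plausible round numbers for corneal stroma.
control:
  fibril: {target_density: 60, diameter_mean_nm: 28, diameter_sd_nm: 3.5}
  tensile: {toe_amplitude: 0.092, toe_rate: 8}
  dsc: {td_C: 66.80}
  qpcr: {Tnfa: 0, Aldh: 0, Kera: 0, Bgn: 0}
KC:
  fibril: {target_density: 35, diameter_mean_nm: 34, diameter_sd_nm: 5}
  tensile: {toe_amplitude: 0.037, toe_rate: 8}
  dsc: {td_C: 62.57}
  qpcr: {Tnfa: 2.5, Aldh: -2, Kera: -2.5, Bgn: -1.5}
COR:
  fibril: {target_density: 65, diameter_mean_nm: 25, diameter_sd_nm: 6}
  tensile: {toe_amplitude: 0.088, toe_rate: 8}
  dsc: {td_C: 66.96}
  qpcr: {Tnfa: -1, Aldh: -0.3, Kera: -0.2, Bgn: -0.2}
CART:
  fibril: {target_density: 60, diameter_mean_nm: 28, diameter_sd_nm: 4}
  tensile: {toe_amplitude: 0.066, toe_rate: 8}
  dsc: {td_C: 66.08}
  qpcr: {Tnfa: -0.8, Aldh: -0.4, Kera: -0.4, Bgn: -0.3}
LN:
  fibril: {target_density: 78, diameter_mean_nm: 22, diameter_sd_nm: 3}
  tensile: {toe_amplitude: 0.062, toe_rate: 8}
  dsc: {td_C: 66.80}
  qpcr: {Tnfa: -1.2, Aldh: -0.3, Kera: -0.3, Bgn: -0.2}
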