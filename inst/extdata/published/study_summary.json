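{
  "n_scats_collected": 117,
  "n_bobcat_scats": 45,
  "n_coyote_scats": 46,
  "n_scats_genotyped_5plus_loci": 23,
  "n_scats_retained_6plus_loci": 21,
  "n_individuals": 9,
  "amplification_rate_range": [0.31, 0.49],
  "genotyping_rate_range": [0.37, 0.42],
  "mean_Ho": 0.742, "se_Ho": 0.074,
  "mean_uHe": 0.631, "se_uHe": 0.053,
  "AR": 3.67, "A_range": [2, 5],
  "mean_FIS": -0.255, "se_FIS": 0.065,
  "mean_r_ml": 0.155, "sd_r_ml": 0.248,
  "mean_r_triadic": 0.077, "sd_r_triadic": 0.161,
  "inbred_individual_F": 0.4343, "inbred_individual_F_ci": [0.282, 0.726],
  "N_hat": 14.41, "se_N": 3.052, "N_ci": [1.9, 24.2],
  "sigma_m": 772.9, "se_sigma_m": 130.7,
  "D_het_weighted": 0.11,
  "Nb_het": 5.0, "Nb_het_ci_lower": 2.7,
  "Nb_coancestry": 8.4, "Nb_coancestry_ci": [3.8, 14.7],
  "n_detector_sections": 749, "section_length_m": 200
}
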