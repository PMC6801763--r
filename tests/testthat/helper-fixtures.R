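# Build a small titration series in code from per-point peak tables.
make_series <- function(ratios, protein_conc, peaks_list, label = "test",
                        mode = "constant-protein") {
  points <- lapply(seq_along(ratios), function(i) {
    list(index = i, ratio = ratios[i], protein_conc = protein_conc,
         ligand_conc = ratios[i] * protein_conc, peaks = peaks_list[[i]])
  })
  titration_series(points, label = label, mode = mode)
}

make_peaks <- function(residue_id, delta_h, delta_n, height = NA_real_,
                       residue_name = NA_character_) {
  data.frame(residue_id = as.integer(residue_id),
             residue_name = residue_name, delta_h = delta_h,
             delta_n = delta_n, height = height, stringsAsFactors = FALSE)
}

# An analytic noiseless series: each residue follows the single-site closed
# form exactly, moving along the 1H axis only (so CSP == |dH shift|).
analytic_single_series <- function(kd, ddmax, a, ratios,
                                   residue_ids = 1:5) {
  occ <- single_site_oracle(ratios, single_site_params(kd, 1, a))
  peaks_list <- lapply(seq_along(ratios), function(i) {
    make_peaks(residue_ids,
               delta_h = 8 + 0.05 * seq_along(residue_ids) +
                 ddmax * occ[i],
               delta_n = 115 + seq_along(residue_ids))
  })
  make_series(ratios, a, peaks_list)
}

ten_ratio_schedule <- c(0, 0.1, 0.2, 0.5, 1, 1.9, 3.6, 5.2, 6.8, 8.4)
seven_ratio_schedule <- c(0, 0.1, 0.2, 0.5, 1, 2, 4)
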