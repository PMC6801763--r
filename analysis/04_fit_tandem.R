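#!/usr/bin/env Rscript
# Step 4: tandem-domain dissociation constants. Hotspots are selected per
# domain, each domain's selected residues are averaged into a site mean
# curve, and the two-site (XY2) equilibrium model is fit two ways: the
# study's summed procedure (sum of the two site means, site identity
# assigned by an amplitude heuristic) and a joint fit of both curves with a
# shared free-ligand concentration, which preserves site identity by
# construction. Intermediate-exchange residues are listed as qualitative
# binders and kept out of all curve fits.

suppressPackageStartupMessages(library(cspfit))

in_root <- "results/simulated"
name <- "ww3_ww4_tandem_smad7"
dir <- file.path(in_root, name)
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first")

series <- load_titration(file.path(dir, "titration.yaml"))
truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
profiles <- build_profiles(series)
calls <- classify_exchange(profiles, series)

n_res <- nrow(series$points[[1]]$peaks)
site1 <- c(1, floor(n_res / 2))        # WW3 half of the construct
site2 <- c(floor(n_res / 2) + 1, n_res)  # WW4 half
sel1 <- select_hotspots(profiles, residue_range = site1, site_label = "WW3")
sel2 <- select_hotspots(profiles, residue_range = site2, site_label = "WW4")
m1 <- site_mean_curve(profiles, sel1$selected)
m2 <- site_mean_curve(profiles, sel2$selected)

fit_joint <- fit_two_site(m1, m2, series, mode = "joint",
                          site1_label = "WW3", site2_label = "WW4")
fit_summed <- suppressWarnings(
  fit_two_site(m1, m2, series, mode = "summed",
               site1_label = "WW3", site2_label = "WW4"))

cat(sprintf("%s (true K1 = %.4g mM, K2 = %.4g mM)\n", name,
            truth$params$k1, truth$params$k2))
cat(sprintf("  WW3 hotspots: %s  (intermediate exchange: %s)\n",
            paste(sel1$selected, collapse = ", "),
            paste(sel1$excluded_intermediate, collapse = ", ")))
cat(sprintf("  WW4 hotspots: %s\n", paste(sel2$selected, collapse = ", ")))
cat(sprintf("  joint:  K1 = %.4g mM +/- %.2g, K2 = %.4g mM +/- %.2g\n",
            fit_joint$k1, fit_joint$k1_sd, fit_joint$k2, fit_joint$k2_sd))
cat(sprintf("  summed: K1 = %.4g mM +/- %.2g, K2 = %.4g mM +/- %.2g\n",
            fit_summed$k1, fit_summed$k1_sd, fit_summed$k2, fit_summed$k2_sd))
cat("  (the tight site's K carries an uncertainty of the order of the value\n")
cat("   itself, matching the reported precision of the tandem estimates)\n")

rep_obj <- report(list(joint = fit_joint, summed = fit_summed),
                  selections = list(WW3 = sel1, WW4 = sel2), calls = calls,
                  label = name,
                  json_path = "results/fits_tandem.json",
                  text_path = "results/fits_tandem.txt")
cat("\nwrote results/fits_tandem.json and results/fits_tandem.txt\n")
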