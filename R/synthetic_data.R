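#' Specify a synthetic HSQC titration
#'
#' Defines the world a simulated titration is drawn from: construct size,
#' schedule, true binding model, per-residue saturation-shift amplitudes,
#' position noise and optional intermediate-exchange residues. Defaults
#' reflect a small WW-domain construct followed by 1H-15N HSQC: ~30 assigned
#' amides per domain, binding-site residues a third of the construct,
#' saturation shift changes of 0.05-0.25 ppm (weighted), and 0.003 ppm
#' position noise.
#'
#' @param n_residues Number of assigned residues; for `model = "two-site"`
#'   the first half belongs to site 1, the second half to site 2.
#' @param protein_conc Total protein concentration, mM.
#' @param ratios Ligand:protein molar ratios, starting at 0, strictly
#'   increasing.
#' @param model `"single"` or `"two-site"`.
#' @param true_params A [single_site_params()] or [two_site_params()] object
#'   matching `model` (its `a`/`p` must equal `protein_conc`).
#' @param binder_fraction Fraction of residues with nonzero saturation shift.
#' @param ddmax_range Range (min, max) the per-binder weighted saturation
#'   shift amplitudes are drawn from, ppm.
#' @param noise_sd Gaussian position noise sd, ppm; applied independently to
#'   the 1H shift and to the 15N shift scaled by `alpha` (so 15N noise sd in
#'   ppm is `noise_sd / alpha`).
#' @param intermediate_residues Residue ids whose peaks vanish at points
#'   where their occupancy lies in (0.2, 0.8), emulating coalescence
#'   broadening.
#' @param alpha 15N weight used to convert weighted amplitudes into 15N ppm.
#' @param label Series label.
#' @param seed Integer seed; the entire draw is reproducible from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_residues = 30L, protein_conc, ratios, model,
                            true_params, binder_fraction = 0.3,
                            ddmax_range = c(0.05, 0.25), noise_sd = 0.003,
                            intermediate_residues = integer(0),
                            alpha = 0.1014, label = "synthetic", seed) {
  model <- match.arg(model, c("single", "two-site"))
  stopifnot(n_residues >= 3, protein_conc > 0,
            length(ratios) >= 2, ratios[1] == 0, all(diff(ratios) > 0),
            binder_fraction >= 0, binder_fraction <= 1,
            length(ddmax_range) == 2, ddmax_range[1] > 0,
            ddmax_range[2] >= ddmax_range[1],
            noise_sd >= 0, alpha > 0, is.numeric(seed), length(seed) == 1L)
  if (model == "single") {
    stopifnot(inherits(true_params, "single_site_params"))
    stopifnot(isTRUE(all.equal(true_params$a, protein_conc)))
  } else {
    stopifnot(inherits(true_params, "two_site_params"))
    stopifnot(isTRUE(all.equal(true_params$p, protein_conc)))
  }
  structure(list(n_residues = as.integer(n_residues),
                 protein_conc = protein_conc, ratios = as.numeric(ratios),
                 model = model, true_params = true_params,
                 binder_fraction = binder_fraction,
                 ddmax_range = as.numeric(ddmax_range), noise_sd = noise_sd,
                 intermediate_residues = as.integer(intermediate_residues),
                 alpha = alpha, label = label, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Per-residue occupancy at every titration point, from the independent
# numeric oracles (not the closed forms the fitting code uses).
simulate_occupancy <- function(spec) {
  n <- spec$n_residues
  ratios <- spec$ratios
  if (spec$model == "single") {
    unit <- single_site_params(spec$true_params$kd, 1, spec$true_params$a)
    occ_curve <- single_site_oracle(ratios, unit)
    occ <- matrix(occ_curve, nrow = n, ncol = length(ratios), byrow = TRUE)
    site <- rep(1L, n)
  } else {
    l_tot <- ratios * spec$protein_conc
    L <- two_site_free_ligand_bisect(l_tot, spec$true_params)
    occ1 <- L / (spec$true_params$k1 + L)
    occ2 <- L / (spec$true_params$k2 + L)
    site <- rep(c(1L, 2L), c(floor(n / 2), n - floor(n / 2)))
    occ <- matrix(NA_real_, n, length(ratios))
    occ[site == 1L, ] <- matrix(occ1, sum(site == 1L), length(ratios),
                                byrow = TRUE)
    occ[site == 2L, ] <- matrix(occ2, sum(site == 2L), length(ratios),
                                byrow = TRUE)
  }
  list(occ = occ, site = site)
}

#' Simulate a fast-exchange HSQC titration
#'
#' Draws free-state amide positions uniformly in the HSQC window
#' (1H 6.5-10.5 ppm, 15N 102-132 ppm), gives each binder a bound-state offset
#' of weighted magnitude drawn from `ddmax_range` in a random direction, and
#' places each peak at the population-weighted average of free and bound
#' positions — occupancy computed with the numeric equilibrium oracle of the
#' chosen model, never the closed form under test. Gaussian noise perturbs
#' every peak position; residues listed in `intermediate_residues` are
#' removed from peak lists at points where their occupancy lies in
#' (0.2, 0.8), the coalescence window where broadening is maximal. Noise is
#' applied to the ligand-bearing points only: the free reference defines the
#' coordinate origin of the shift-distance measurement.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `series` (a [titration_series()]) and `truth`
#'   (per-residue site, weighted amplitude and bound-state offsets, the
#'   occupancy matrix, the true parameters and the seed).
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_titration_impl(spec))
}

simulate_titration_impl <- function(spec) {
  n <- spec$n_residues
  npt <- length(spec$ratios)
  ids <- seq_len(n)
  # no PRO: prolines carry no backbone amide and never appear in an HSQC
  names3 <- sample(setdiff(unname(AA_1TO3), "PRO"), n, replace = TRUE)
  dh_free <- runif(n, 6.5, 10.5)
  dn_free <- runif(n, 102, 132)
  height0 <- runif(n, 5e5, 2e6)

  n_bind <- round(spec$binder_fraction * n)
  occ_info <- simulate_occupancy(spec)
  site <- occ_info$site
  if (spec$model == "two-site") {
    # spread binders over both halves so each site has hotspot residues
    b1 <- sample(ids[site == 1L], min(ceiling(n_bind / 2), sum(site == 1L)))
    b2 <- sample(ids[site == 2L], min(floor(n_bind / 2), sum(site == 2L)))
    binders <- sort(c(b1, b2))
  } else {
    binders <- sort(sample(ids, n_bind))
  }
  ddmax <- numeric(n)
  ddmax[binders] <- runif(length(binders), spec$ddmax_range[1],
                          spec$ddmax_range[2])
  phi <- runif(n, 0, 2 * pi)
  dh_inf <- ddmax * cos(phi)
  dn_inf <- ddmax * sin(phi) / spec$alpha

  occ <- occ_info$occ
  points <- vector("list", npt)
  for (j in seq_len(npt)) {
    # the free reference defines the coordinate origin: noise enters the
    # CSP through the ligand-bearing points measured against it
    noise_h <- if (j == 1L) 0 else rnorm(n, 0, spec$noise_sd)
    noise_n <- if (j == 1L) 0 else rnorm(n, 0, spec$noise_sd / spec$alpha)
    dh <- dh_free + dh_inf * occ[, j] + noise_h
    dn <- dn_free + dn_inf * occ[, j] + noise_n
    keep <- rep(TRUE, n)
    if (j > 1 && length(spec$intermediate_residues) > 0) {
      broad <- spec$intermediate_residues
      keep[broad] <- !(occ[broad, j] > 0.2 & occ[broad, j] < 0.8)
    }
    peaks <- data.frame(residue_id = ids, residue_name = names3,
                        delta_h = dh, delta_n = dn, height = height0,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
    points[[j]] <- new_titration_point(
      j, spec$ratios[j], spec$protein_conc,
      spec$ratios[j] * spec$protein_conc, peaks)
  }
  series <- titration_series(points, label = spec$label,
                             mode = "constant-protein")
  truth <- list(
    model = spec$model, params = spec$true_params, alpha = spec$alpha,
    seed = spec$seed,
    residues = data.frame(residue_id = ids, site = site,
                          binder = ids %in% binders, ddmax = ddmax,
                          dh_inf = dh_inf, dn_inf = dn_inf),
    occupancy = occ,
    site_ranges = if (spec$model == "two-site") {
      list(site1 = range(ids[site == 1L]), site2 = range(ids[site == 2L]))
    } else NULL
  )
  list(series = series, truth = truth)
}

#' Simulation specs mirroring the study's titrations
#'
#' Four named, seeded [simulation_spec()]s matching the experimental designs:
#' the synthetic-peptide WW4/Smad7 and WW4/pSmad7 titrations (protein 0.78 mM,
#' seven ratio points 1:0 to 1:4, true K_d 1.19 and 0.5 mM), the recombinant
#' single-domain WW4/Smad7 titration (protein 0.08 mM, ten ratio points 1:0
#' to 1:8.4, true K_d 0.237 mM), and the tandem WW3-WW4 titration (0.08 mM,
#' same ten-point schedule, two-site with K1 = 0.02057 mM and K2 = 0.2493 mM,
#' including three site-1 residues in intermediate exchange). The K values
#' are the study's own estimates, reused as the true parameters of the
#' simulated world.
#'
#' @return A named list of `simulation_spec` objects.
#' @export
paper_fixtures <- function() {
  seven <- c(0, 0.1, 0.2, 0.5, 1, 2, 4)
  ten <- c(0, 0.1, 0.2, 0.5, 1, 1.9, 3.6, 5.2, 6.8, 8.4)
  list(
    ww4_smad7_synthetic = simulation_spec(
      n_residues = 30L, protein_conc = 0.78, ratios = seven, model = "single",
      true_params = single_site_params(kd = 1.19, ddmax = 0.15, a = 0.78),
      label = "ww4_smad7_synthetic", seed = 41L),
    ww4_psmad7_synthetic = simulation_spec(
      n_residues = 30L, protein_conc = 0.78, ratios = seven, model = "single",
      true_params = single_site_params(kd = 0.5, ddmax = 0.15, a = 0.78),
      label = "ww4_psmad7_synthetic", seed = 42L),
    ww4_smad7_recombinant = simulation_spec(
      n_residues = 30L, protein_conc = 0.08, ratios = ten, model = "single",
      true_params = single_site_params(kd = 0.237, ddmax = 0.15, a = 0.08),
      label = "ww4_smad7_recombinant", seed = 43L),
    ww3_ww4_tandem_smad7 = simulation_spec(
      n_residues = 60L, protein_conc = 0.08, ratios = ten, model = "two-site",
      true_params = two_site_params(k1 = 0.02057, k2 = 0.2493,
                                    d1 = 0.15, d2 = 0.15, p = 0.08),
      intermediate_residues = c(25L, 26L, 27L),
      label = "ww3_ww4_tandem_smad7", seed = 44L)
  )
}

#' Write a simulated titration to disk as peak lists plus a config
#'
#' Emits one peak-list CSV per titration point, a YAML titration config that
#' [load_titration()] accepts, and a ground-truth JSON.
#'
#' @param sim Result of [simulate_titration()].
#' @param dir Output directory (created if needed).
#' @param dialect Peak-list dialect to write.
#' @return The config path, invisibly.
#' @export
write_titration <- function(sim, dir, dialect = "csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- sim$series
  ext <- if (dialect == "sparky") "list" else dialect
  files <- sprintf("point_%02d.%s", seq_along(series$points), ext)
  for (i in seq_along(series$points)) {
    write_peak_table(series$points[[i]]$peaks, file.path(dir, files[i]),
                     dialect = dialect)
  }
  config <- list(
    label = series$label,
    protein_conc_mM = series$points[[1]]$protein_conc,
    ratios = vapply(series$points, `[[`, numeric(1), "ratio"),
    mode = series$mode,
    dialect = dialect,
    peak_files = files
  )
  config_path <- file.path(dir, "titration.yaml")
  yaml::write_yaml(config, config_path)
  truth <- sim$truth
  truth$params <- unclass(truth$params)
  truth$occupancy <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config_path)
}
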