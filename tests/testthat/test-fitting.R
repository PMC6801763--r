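test_that("hotspot rule reproduces the mean + 1 SD arithmetic", {
  dd <- c(0.01, 0.02, 0.03, 0.10)
  prof <- data.frame(residue_id = rep(1:4, each = 2),
                     point_index = rep(1:2, 4),
                     ratio = rep(c(0, 4), 4), ligand_conc = rep(c(0, 2), 4),
                     delta_delta = as.vector(rbind(0, dd)),
                     flag = "observed", stringsAsFactors = FALSE)
  sel <- select_hotspots(prof)
  expect_equal(sel$mean, 0.04)
  expect_equal(sel$sd, 0.040825, tolerance = 1e-5)
  expect_equal(sel$threshold, 0.080825, tolerance = 1e-5)
  expect_identical(sel$selected, 4L)
  expect_identical(sel$point_used, 2L)
  # invariant: threshold is exactly mean + sd
  expect_identical(sel$threshold, sel$mean + sel$sd)
  # order invariance
  sel_rev <- select_hotspots(prof[nrow(prof):1, ])
  expect_identical(sel_rev$selected, sel$selected)
  expect_identical(sel_rev$threshold, sel$threshold)
  # degenerate tie: sd 0, everything selected
  prof_eq <- prof; prof_eq$delta_delta <- rep(c(0, 0.05), 4)
  expect_identical(select_hotspots(prof_eq)$selected, 1:4)
  # too few usable residues
  expect_error(select_hotspots(prof[prof$residue_id <= 2, ]), ">= 3")
})

test_that("hotspot selection excludes intermediate-exchange residues from the statistics", {
  prof <- data.frame(residue_id = rep(1:5, each = 2),
                     point_index = rep(1:2, 5),
                     ratio = rep(c(0, 4), 5), ligand_conc = rep(c(0, 2), 5),
                     delta_delta = as.vector(rbind(0, c(0.01, 0.02, 0.03, 0.10, NA))),
                     flag = c(rep("observed", 8), "observed", "missing"),
                     stringsAsFactors = FALSE)
  sel <- select_hotspots(prof)
  expect_identical(sel$excluded_intermediate, 5L)
  expect_equal(sel$mean, 0.04)   # statistics over residues 1-4 only
  expect_identical(sel$selected, 4L)
})

test_that("single-residue fits recover noiseless truth and refuse bad input", {
  spec <- simulation_spec(n_residues = 15L, protein_conc = 0.08,
                          ratios = ten_ratio_schedule, model = "single",
                          true_params = single_site_params(0.237, 0.12, 0.08),
                          binder_fraction = 0.5, noise_sd = 0, seed = 21L)
  sim <- simulate_titration(spec)
  prof <- build_profiles(sim$series)
  binders <- sim$truth$residues[sim$truth$residues$binder, ]
  for (k in seq_len(min(3, nrow(binders)))) {
    res <- binders$residue_id[k]
    fit <- fit_single_residue(prof, res, sim$series)
    expect_true(fit$converged)
    expect_lt(abs(fit$kd - 0.237) / 0.237, 1e-6)
    expect_lt(abs(fit$ddmax - binders$ddmax[k]) / binders$ddmax[k], 1e-6)
  }
  # flat profile carries no binding signal
  non <- sim$truth$residues$residue_id[!sim$truth$residues$binder][1]
  expect_error(fit_single_residue(prof, non, sim$series), "no binding signal")
  # fewer than 4 points is insufficient
  short <- prof[prof$point_index <= 3, ]
  bres <- binders$residue_id[1]
  expect_error(fit_single_residue(short, bres, sim$series), ">= 4")
})

test_that("intermediate-exchange residues are refused by the fitter", {
  spec <- simulation_spec(n_residues = 10L, protein_conc = 0.08,
                          ratios = ten_ratio_schedule, model = "single",
                          true_params = single_site_params(0.237, 0.12, 0.08),
                          binder_fraction = 1, noise_sd = 0,
                          intermediate_residues = 4L, seed = 22L)
  sim <- simulate_titration(spec)
  prof <- build_profiles(sim$series)
  expect_error(fit_single_residue(prof, 4L, sim$series),
               "intermediate exchange")
})

test_that("site averaging: both modes agree on a shared-Kd site and expose disagreement otherwise", {
  spec <- simulation_spec(n_residues = 12L, protein_conc = 0.08,
                          ratios = ten_ratio_schedule, model = "single",
                          true_params = single_site_params(0.139, 0.15, 0.08),
                          binder_fraction = 0.5, noise_sd = 0, seed = 23L)
  sim <- simulate_titration(spec)
  prof <- build_profiles(sim$series)
  sel <- select_hotspots(prof)
  f_curve <- fit_site_average(sel, prof, sim$series, mode = "curve-average")
  f_kd <- fit_site_average(sel, prof, sim$series, mode = "kd-average")
  expect_lt(abs(f_curve$kd - 0.139) / 0.139, 1e-5)
  expect_lt(abs(f_curve$kd - f_kd$kd) / f_kd$kd, 1e-6)

  # selection of one residue degenerates to the single-residue fit
  sel1 <- sel; sel1$selected <- sel$selected[1]
  f1 <- fit_site_average(sel1, prof, sim$series)
  fr <- fit_single_residue(prof, sel$selected[1], sim$series)
  expect_equal(f1$kd, fr$kd, tolerance = 1e-9)

  # residues with 10x different true Kd: curve- and kd-averaging disagree
  ratios <- ten_ratio_schedule
  a <- 0.08
  y_tight <- single_site_shift(ratios, single_site_params(0.02, 0.15, a))
  y_loose <- single_site_shift(ratios, single_site_params(0.2, 0.15, a))
  mixed <- data.frame(
    residue_id = rep(1:2, each = length(ratios)),
    point_index = rep(seq_along(ratios), 2),
    ratio = rep(ratios, 2), ligand_conc = rep(ratios * a, 2),
    delta_delta = c(y_tight, y_loose), flag = "observed",
    stringsAsFactors = FALSE)
  series <- analytic_single_series(0.1, 0.1, a, ratios, residue_ids = 1:2)
  sel_mixed <- structure(list(site_label = "mixed", selected = 1:2,
                              threshold = 0, mean = 0, sd = 0,
                              point_used = length(ratios),
                              excluded_intermediate = integer(0)),
                         class = "hotspot_selection")
  f_cm <- fit_site_average(sel_mixed, mixed, series, mode = "curve-average")
  f_km <- fit_site_average(sel_mixed, mixed, series, mode = "kd-average")
  expect_equal(f_km$kd, mean(c(0.02, 0.2)), tolerance = 1e-5)
  expect_gt(abs(f_cm$kd - f_km$kd) / f_km$kd, 0.05)
  expect_gt(f_km$kd_sd, 0.05)  # the SD exposes the heterogeneity
})

test_that("two-site fits recover a noiseless tandem and keep site identity in joint mode", {
  spec <- paper_fixtures()$ww3_ww4_tandem_smad7
  spec$noise_sd <- 0
  sim <- simulate_titration(spec)
  prof <- build_profiles(sim$series)
  sel1 <- select_hotspots(prof, residue_range = sim$truth$site_ranges$site1,
                          site_label = "site1")
  sel2 <- select_hotspots(prof, residue_range = sim$truth$site_ranges$site2,
                          site_label = "site2")
  m1 <- site_mean_curve(prof, sel1$selected)
  m2 <- site_mean_curve(prof, sel2$selected)
  fit <- fit_two_site(m1, m2, sim$series, mode = "joint")
  expect_true(fit$converged)
  expect_lt(abs(fit$k1 - 0.02057) / 0.02057, 1e-4)
  expect_lt(abs(fit$k2 - 0.2493) / 0.2493, 1e-4)
  # summed mode warns that site identity rests on an amplitude heuristic
  expect_warning(fit_s <- fit_two_site(m1, m2, sim$series, mode = "summed"),
                 "heuristic")
  expect_true(fit_s$converged)
  expect_lt(fit_s$residual_rms, 1e-6)
})

test_that("identical-sites summed fit matches the doubled single-site fit", {
  K <- 0.15; dlt <- 0.12; p <- 0.08
  ratios <- ten_ratio_schedule
  l_tot <- ratios * p
  tp <- two_site_params(K, K, dlt, dlt, p)
  s <- two_site_site_shifts(l_tot, tp)
  curve <- data.frame(point_index = seq_along(ratios), ratio = ratios,
                      ligand_conc = l_tot)
  m1 <- cbind(curve, y = s$y1)
  m2 <- cbind(curve, y = s$y2)
  series <- analytic_single_series(K, dlt, p, ratios)
  fit <- suppressWarnings(fit_two_site(m1, m2, series, mode = "summed"))
  # the equivalent single site at doubled concentration
  single <- single_site_shift(l_tot / (2 * p),
                              single_site_params(K, 2 * dlt, 2 * p))
  pred <- two_site_shift(l_tot, two_site_params(fit$k1, fit$k2, fit$d1,
                                                fit$d2, p))
  expect_lt(max(abs(pred - single)), 1e-7)
})

test_that("an inert second site leaves its K unidentifiable and flagged by its SE", {
  # Note: delta2 = 0 alone does NOT remove K2 from the model — an
  # amplitude-less site still depletes free ligand through the shared mass
  # balance. K2 only loses identifiability when site 2 is inert (K2 far above
  # the ligand range, so it neither shifts nor sequesters).
  ratios <- ten_ratio_schedule
  p <- 0.08
  tp <- two_site_params(0.1, 900, 0.12, 1e-9, p)
  s <- two_site_site_shifts(ratios * p, tp)
  curve <- data.frame(point_index = seq_along(ratios), ratio = ratios,
                      ligand_conc = ratios * p)
  withr::with_seed(55, {
    m1 <- cbind(curve, y = s$y1 + c(0, rnorm(length(ratios) - 1, 0, 0.001)))
    m2 <- cbind(curve, y = pmax(s$y2 * 0 +
                                  c(0, rnorm(length(ratios) - 1, 0, 1e-4)), 0))
  })
  series <- analytic_single_series(0.1, 0.12, p, ratios)
  fit <- fit_two_site(m1, m2, series, mode = "joint")
  # K1 is still well determined; K2 carries no information
  expect_lt(abs(fit$k1 - 0.1) / 0.1, 0.05)
  expect_lt(fit$k1_sd / fit$k1, 0.5)
  expect_true(!is.finite(fit$k2_sd) || fit$k2_sd > fit$k2)
})

test_that("fit_two_site rejects short or misaligned curves", {
  ratios <- seven_ratio_schedule[1:5]
  curve <- data.frame(point_index = seq_along(ratios), ratio = ratios,
                      ligand_conc = ratios * 0.08, y = seq_along(ratios) * 0.01)
  series <- analytic_single_series(0.1, 0.1, 0.08, ratios)
  expect_error(fit_two_site(curve, curve, series, mode = "joint"), ">= 6")
})

test_that("reports render units, convergence and omit empty sections", {
  fit <- structure(list(residue_ids = c(27L, 28L), kd = 0.237,
                        kd_sd = 0.0157, ddmax = 0.15, ddmax_sd = 0.003,
                        n_points = 10L, converged = TRUE,
                        residual_rms = 0.001, a = 0.08),
                   class = "single_site_fit")
  rep_obj <- report(list(ww4 = fit))
  expect_equal(rep_obj$fits$ww4$kd_uM, 237)
  txt <- cspfit:::render_report_text(rep_obj)
  expect_true(any(grepl("237 uM", txt)))
  expect_false(any(grepl("Exchange regimes", txt)))

  fit_bad <- fit; fit_bad$converged <- FALSE
  txt2 <- cspfit:::render_report_text(report(list(ww4 = fit_bad)))
  expect_true(any(grepl("not converged", txt2)))

  calls <- data.frame(residue_id = 1:2, regime = c("fast", "intermediate"),
                      evidence = c("", ""))
  txt3 <- cspfit:::render_report_text(report(list(ww4 = fit), calls = calls))
  expect_true(any(grepl("Exchange regimes", txt3)))

  # JSON output is machine-readable and carries both unit scales
  jf <- tempfile(fileext = ".json")
  report(list(ww4 = fit), json_path = jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$fits$ww4$kd_mM, 0.237)
  expect_equal(parsed$fits$ww4$kd_uM, 237)
})
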