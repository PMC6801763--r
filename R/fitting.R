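# Bounded Levenberg-Marquardt least squares with a forward-difference
# Jacobian. minpack-style fitters are not available in this environment, and
# the recovery tolerances here need tighter control over the cost tolerance
# than nls() exposes, so the fitter is explicit: box projection after each
# step, convergence on relative cost change < tol.
lm_fit <- function(resid_fn, start, lower, upper, tol = 1e-10,
                   maxit = 500L) {
  p <- pmin(pmax(start, lower), upper)
  r <- resid_fn(p)
  cost <- sum(r^2)
  lambda <- 1e-3
  np <- length(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(r), np)
    for (k in seq_len(np)) {
      h <- max(1e-8 * abs(p[k]), 1e-10)
      pk <- p
      pk[k] <- min(p[k] + h, upper[k])
      hk <- pk[k] - p[k]
      if (hk == 0) { pk[k] <- p[k] - h; hk <- -h }
      J[, k] <- (resid_fn(pk) - r) / hk
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    if (sqrt(sum(g^2)) < 1e-14 * max(1, cost)) { converged <- TRUE; break }
    improved <- FALSE
    for (try_i in 1:30) {
      step <- tryCatch(
        solve(A + lambda * diag(pmax(diag(A), 1e-12), np), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        p_new <- pmin(pmax(p + drop(step), lower), upper)
        r_new <- resid_fn(p_new)
        cost_new <- sum(r_new^2)
        if (is.finite(cost_new) && cost_new <= cost) {
          rel <- (cost - cost_new) / max(cost, 1e-300)
          p <- p_new; r <- r_new; cost <- cost_new
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 5
    }
    if (!improved || converged) {
      converged <- converged || !improved && cost < 1e-24
      if (!improved && cost <= 1e-20) converged <- TRUE
      if (!improved && !converged) converged <- lambda > 1e10 && FALSE
      break
    }
  }
  # asymptotic covariance: residual-variance-scaled inverse of J'J
  J <- matrix(0, length(r), np)
  for (k in seq_len(np)) {
    h <- max(1e-8 * abs(p[k]), 1e-10)
    pk <- p; pk[k] <- p[k] + h
    J[, k] <- (resid_fn(pk) - r) / h
  }
  dof <- max(length(r) - np, 1L)
  sigma2 <- cost / dof
  jtj <- crossprod(J)
  # a parameter the residuals do not depend on is structurally
  # non-identifiable: flag it with an unbounded SE instead of failing
  alive <- diag(jtj) > 1e-12 * max(diag(jtj), 1e-300)
  se <- rep(Inf, np)
  if (any(alive)) {
    covm <- tryCatch(sigma2 * solve(jtj[alive, alive, drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(covm)) {
      v <- diag(covm)
      se[alive] <- ifelse(v >= 0 & is.finite(v), sqrt(v), Inf)
    }
  }
  list(par = p, se = se, cost = cost, converged = converged,
       residual_rms = sqrt(cost / length(r)), n = length(r), iterations = it)
}

single_site_start <- function(ligand, y, a) {
  dd0 <- 1.2 * max(y)
  half <- max(y) / 2
  ord <- order(y)
  kd0 <- tryCatch(approx(y[ord], ligand[ord], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- a
  c(kd = kd0, ddmax = max(dd0, 1e-4))
}

fit_single_curve <- function(ratio, y, a, label_residues = integer(0)) {
  start <- single_site_start(ratio * a, y, a)
  resid_fn <- function(p) {
    single_site_shift(ratio, single_site_params(p[1], p[2], a)) - y
  }
  fit <- lm_fit(resid_fn, start = unname(start),
                lower = c(1e-6, 0), upper = c(1e3, 10))
  structure(list(residue_ids = label_residues,
                 kd = fit$par[1], kd_sd = fit$se[1],
                 ddmax = fit$par[2], ddmax_sd = fit$se[2],
                 n_points = fit$n, converged = fit$converged,
                 residual_rms = fit$residual_rms, a = a),
            class = "single_site_fit")
}

#' Fit the single-site fast-exchange model to one residue's CSP trajectory
#'
#' Nonlinear least squares of [single_site_shift()] over (K_d, saturation
#' shift), with standard errors from the residual-variance-scaled inverse of
#' J'J. Points flagged missing are excluded, never imputed; residues in
#' intermediate exchange (any missing nonzero-ligand point) are refused
#' because their observed positions are biased.
#'
#' @param profiles A `csp_profiles` data frame from [build_profiles()].
#' @param residue Residue id to fit.
#' @param series The [titration_series()] the profiles came from.
#' @param epsilon Non-binding floor, ppm: if every observed shift distance is
#'   below it the residue carries no binding signal and the fit is refused.
#' @return A `single_site_fit` object: `kd`, `kd_sd`, `ddmax`, `ddmax_sd`
#'   (mM / ppm), `n_points`, `converged`, `residual_rms`.
#' @export
fit_single_residue <- function(profiles, residue, series, epsilon = 0.005) {
  stopifnot(inherits(series, "titration_series"))
  prof <- profiles[profiles$residue_id == residue, , drop = FALSE]
  if (nrow(prof) == 0) stop(sprintf("residue %s not in profiles", residue))
  prof <- prof[order(prof$point_index), , drop = FALSE]
  if (any(prof$flag == "missing" & prof$ratio > 0)) {
    stop(sprintf(
      "residue %s is in intermediate exchange; peak positions are biased and cannot be fit",
      residue))
  }
  obs <- prof[prof$flag == "observed", , drop = FALSE]
  if (nrow(obs) < 4 || obs$point_index[1] != 1L) {
    stop(sprintf("residue %s: need >= 4 observed points including the free reference, have %d",
                 residue, nrow(obs)))
  }
  if (all(obs$delta_delta < epsilon)) {
    stop(sprintf("residue %s: no binding signal (all shift distances < %g ppm)",
                 residue, epsilon))
  }
  a <- series$points[[1]]$protein_conc
  fit_single_curve(obs$ratio, obs$delta_delta, a, label_residues = residue)
}

#' @export
print.single_site_fit <- function(x, ...) {
  cat(sprintf("single-site fit (%d points%s): %s\n", x$n_points,
              if (length(x$residue_ids) > 0) {
                sprintf(", residues %s", paste(x$residue_ids, collapse = ","))
              } else "",
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  K_D    = %s +/- %s\n", format_kd(x$kd), format_kd(x$kd_sd)))
  cat(sprintf("  dd_inf = %.4g +/- %.4g ppm; residual rms %.2g ppm\n",
              x$ddmax, x$ddmax_sd, x$residual_rms))
  invisible(x)
}

format_kd <- function(kd_mm) {
  if (!is.finite(kd_mm)) return(as.character(kd_mm))
  if (kd_mm < 1) sprintf("%.4g uM", kd_mm * 1000) else sprintf("%.4g mM", kd_mm)
}

#' Select binding-site hotspot residues (mean + 1 SD rule)
#'
#' At a chosen titration point (default the final one, which maximizes
#' dynamic range), computes the mean and sample standard deviation (n - 1
#' denominator) of the shift distances over the usable residues and selects
#' those with shift distance >= mean + SD. Residues in intermediate exchange
#' (missing points) are excluded from the statistics and reported separately
#' as qualitative binders; `residue_range` restricts the statistics to one
#' domain of a tandem construct.
#'
#' @param profiles A `csp_profiles` data frame.
#' @param point Titration point index to use; default the last.
#' @param residue_range Optional `c(lo, hi)` residue-id window.
#' @param site_label Free-text label for the selection.
#' @return A `hotspot_selection` object: `selected`, `threshold`, `mean`,
#'   `sd`, `point_used`, `excluded_intermediate`, `distances`.
#' @export
select_hotspots <- function(profiles, point = NULL, residue_range = NULL,
                            site_label = "site") {
  if (is.null(point)) point <- max(profiles$point_index)
  prof <- profiles
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    prof <- prof[prof$residue_id >= residue_range[1] &
                   prof$residue_id <= residue_range[2], , drop = FALSE]
  }
  inter <- sort(unique(prof$residue_id[prof$flag == "missing" &
                                         prof$ratio > 0]))
  at_pt <- prof[prof$point_index == point & prof$flag == "observed" &
                  !(prof$residue_id %in% inter), , drop = FALSE]
  at_pt <- at_pt[order(at_pt$residue_id), , drop = FALSE]
  if (nrow(at_pt) < 3) {
    stop(sprintf("hotspot selection needs >= 3 usable residues at point %d, have %d",
                 point, nrow(at_pt)))
  }
  m <- mean(at_pt$delta_delta)
  s <- sd(at_pt$delta_delta)
  thr <- m + s
  sel <- at_pt$residue_id[at_pt$delta_delta >= thr]
  structure(list(site_label = site_label, selected = sel, threshold = thr,
                 mean = m, sd = s, point_used = point,
                 excluded_intermediate = inter,
                 distances = data.frame(residue_id = at_pt$residue_id,
                                        delta_delta = at_pt$delta_delta)),
            class = "hotspot_selection")
}

#' @export
print.hotspot_selection <- function(x, ...) {
  cat(sprintf("hotspots '%s' at point %d: mean %.4g + sd %.4g -> threshold %.4g ppm\n",
              x$site_label, x$point_used, x$mean, x$sd, x$threshold))
  cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  if (length(x$excluded_intermediate) > 0) {
    cat(sprintf("  intermediate exchange (excluded): %s\n",
                paste(x$excluded_intermediate, collapse = ", ")))
  }
  invisible(x)
}

#' Per-point mean CSP curve over a set of residues
#'
#' @param profiles A `csp_profiles` data frame.
#' @param residues Residue ids to average over.
#' @return A data frame with `point_index`, `ratio`, `ligand_conc`, `y`
#'   (the per-point mean of the observed shift distances).
#' @export
site_mean_curve <- function(profiles, residues) {
  prof <- profiles[profiles$residue_id %in% residues &
                     profiles$flag == "observed", , drop = FALSE]
  stopifnot(nrow(prof) > 0)
  agg <- aggregate(prof$delta_delta,
                   by = list(point_index = prof$point_index), FUN = mean)
  pts <- prof[!duplicated(prof$point_index),
              c("point_index", "ratio", "ligand_conc")]
  out <- merge(pts, agg, by = "point_index")
  out <- out[order(out$point_index), , drop = FALSE]
  names(out)[names(out) == "x"] <- "y"
  rownames(out) <- NULL
  out
}

#' Fit a binding-site average curve
#'
#' Implements both readings of "hotspot residues were averaged to calculate
#' K_D": `"curve-average"` (default) averages the selected residues' shift
#' distances per point into one curve and fits it once; `"kd-average"` fits
#' every selected residue separately and averages the K_d estimates (SD of
#' the per-residue K_d's as the uncertainty).
#'
#' @param selection A [select_hotspots()] result.
#' @param profiles A `csp_profiles` data frame.
#' @param series The [titration_series()].
#' @param mode `"curve-average"` or `"kd-average"`.
#' @return A `single_site_fit`.
#' @export
fit_site_average <- function(selection, profiles, series,
                             mode = c("curve-average", "kd-average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(selection, "hotspot_selection"))
  if (length(selection$selected) == 0) stop("empty hotspot selection")
  a <- series$points[[1]]$protein_conc
  if (mode == "curve-average") {
    curve <- site_mean_curve(profiles, selection$selected)
    fit_single_curve(curve$ratio, curve$y, a,
                     label_residues = selection$selected)
  } else {
    fits <- lapply(selection$selected, function(res)
      fit_single_residue(profiles, res, series))
    kds <- vapply(fits, `[[`, numeric(1), "kd")
    dds <- vapply(fits, `[[`, numeric(1), "ddmax")
    structure(list(residue_ids = selection$selected,
                   kd = mean(kds),
                   kd_sd = if (length(kds) > 1) sd(kds) else fits[[1]]$kd_sd,
                   ddmax = mean(dds),
                   ddmax_sd = if (length(dds) > 1) sd(dds) else fits[[1]]$ddmax_sd,
                   n_points = fits[[1]]$n_points,
                   converged = all(vapply(fits, `[[`, logical(1), "converged")),
                   residual_rms = sqrt(mean(vapply(fits, function(f)
                     f$residual_rms^2, numeric(1)))),
                   a = a),
              class = "single_site_fit")
  }
}

#' Fit the two-site (tandem-domain) model
#'
#' Takes the two per-site hotspot mean curves of a tandem construct and
#' estimates (K1, K2, delta1, delta2). `mode = "summed"` reproduces the
#' study's procedure: the two site means are summed into a single curve and
#' [two_site_shift()] is fit to it — site identity is then assigned by an
#' amplitude heuristic (the larger fitted delta goes to the site whose mean
#' curve saturates higher), which a warning makes explicit. `mode = "joint"`
#' fits both site curves simultaneously with a shared free-ligand
#' concentration, preserving site identity by construction.
#'
#' @param site1_mean,site2_mean Site mean curves from [site_mean_curve()],
#'   defined on the same titration points.
#' @param series The [titration_series()].
#' @param mode `"summed"` (the study's procedure) or `"joint"`.
#' @param site1_label,site2_label Labels carried into the result.
#' @return A `two_site_fit` object: `k1`, `k1_sd`, `k2`, `k2_sd` (mM), `d1`,
#'   `d2` (ppm), `converged`, `residual_rms`, `mode`, site labels.
#' @export
fit_two_site <- function(site1_mean, site2_mean, series,
                         mode = c("summed", "joint"),
                         site1_label = "site1", site2_label = "site2") {
  mode <- match.arg(mode)
  stopifnot(identical(site1_mean$point_index, site2_mean$point_index))
  if (nrow(site1_mean) < 6) {
    stop(sprintf("two-site fit needs >= 6 points, have %d", nrow(site1_mean)))
  }
  p <- series$points[[1]]$protein_conc
  l_tot <- site1_mean$ligand_conc
  # starts from independent single-site fits of each site mean
  s1 <- fit_single_curve(site1_mean$ratio, site1_mean$y, p)
  s2 <- fit_single_curve(site2_mean$ratio, site2_mean$y, p)
  start <- c(max(s1$kd, 1e-5), max(s2$kd, 1e-5),
             max(s1$ddmax, 1e-4), max(s2$ddmax, 1e-4))
  lower <- c(1e-6, 1e-6, 0, 0)
  upper <- c(1e3, 1e3, 10, 10)
  if (mode == "summed") {
    y <- site1_mean$y + site2_mean$y
    resid_fn <- function(q) {
      two_site_shift(l_tot, two_site_params(q[1], q[2], q[3], q[4], p)) - y
    }
    fit <- lm_fit(resid_fn, start, lower, upper)
    q <- fit$par; se <- fit$se
    # label assignment heuristic: larger fitted delta -> higher-saturating site
    site1_higher <- max(site1_mean$y) >= max(site2_mean$y)
    d1_larger <- q[3] >= q[4]
    if (site1_higher != d1_larger) {
      q <- q[c(2, 1, 4, 3)]
      se <- se[c(2, 1, 4, 3)]
    }
    warning(paste("summed-mode two-site fit: site identity assigned by the",
                  "amplitude heuristic (larger delta to the higher-saturating",
                  "site mean); use mode='joint' to preserve identity"))
  } else {
    y <- c(site1_mean$y, site2_mean$y)
    idx1 <- seq_along(l_tot)
    resid_fn <- function(q) {
      s <- two_site_site_shifts(l_tot, two_site_params(q[1], q[2], q[3], q[4], p))
      c(s$y1, s$y2) - y
    }
    fit <- lm_fit(resid_fn, start, lower, upper)
    q <- fit$par; se <- fit$se
  }
  structure(list(k1 = q[1], k1_sd = se[1], k2 = q[2], k2_sd = se[2],
                 d1 = q[3], d2 = q[4], d1_sd = se[3], d2_sd = se[4],
                 converged = fit$converged, residual_rms = fit$residual_rms,
                 mode = mode, p = p,
                 site1_label = site1_label, site2_label = site2_label),
            class = "two_site_fit")
}

#' @export
print.two_site_fit <- function(x, ...) {
  cat(sprintf("two-site fit (%s mode): %s\n", x$mode,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  %s: K1 = %s +/- %s, delta1 = %.4g ppm\n", x$site1_label,
              format_kd(x$k1), format_kd(x$k1_sd), x$d1))
  cat(sprintf("  %s: K2 = %s +/- %s, delta2 = %.4g ppm\n", x$site2_label,
              format_kd(x$k2), format_kd(x$k2_sd), x$d2))
  cat(sprintf("  residual rms %.2g ppm\n", x$residual_rms))
  invisible(x)
}

fit_to_list <- function(fit) {
  if (inherits(fit, "single_site_fit")) {
    list(model = "single-site",
         residues = fit$residue_ids,
         kd_mM = fit$kd, kd_uM = fit$kd * 1000,
         kd_sd_mM = fit$kd_sd, kd_sd_uM = fit$kd_sd * 1000,
         ddmax_ppm = fit$ddmax, ddmax_sd_ppm = fit$ddmax_sd,
         n_points = fit$n_points, converged = fit$converged,
         residual_rms_ppm = fit$residual_rms)
  } else {
    list(model = "two-site", mode = fit$mode,
         site1 = list(label = fit$site1_label, kd_mM = fit$k1,
                      kd_uM = fit$k1 * 1000, kd_sd_mM = fit$k1_sd,
                      kd_sd_uM = fit$k1_sd * 1000, delta_ppm = fit$d1),
         site2 = list(label = fit$site2_label, kd_mM = fit$k2,
                      kd_uM = fit$k2 * 1000, kd_sd_mM = fit$k2_sd,
                      kd_sd_uM = fit$k2_sd * 1000, delta_ppm = fit$d2),
         converged = fit$converged, residual_rms_ppm = fit$residual_rms)
  }
}

#' Assemble a structured fit report
#'
#' Collects fits, hotspot selections and exchange calls into one structure;
#' optionally writes it as JSON and as a human-readable text table with K_D
#' rendered in both mM and µM.
#'
#' @param fits Named list of `single_site_fit` / `two_site_fit` objects.
#' @param selections Optional named list of [select_hotspots()] results.
#' @param calls Optional exchange-call data frame from [classify_exchange()].
#' @param label Report label.
#' @param json_path,text_path Optional output paths.
#' @return The report as a list, invisibly if written.
#' @export
report <- function(fits, selections = NULL, calls = NULL, label = "",
                   json_path = NULL, text_path = NULL) {
  stopifnot(is.list(fits), length(fits) > 0)
  rep_obj <- list(label = label,
                  fits = lapply(fits, fit_to_list))
  if (!is.null(selections)) {
    rep_obj$hotspots <- lapply(selections, function(s) {
      list(site_label = s$site_label, selected = s$selected,
           threshold_ppm = s$threshold, mean_ppm = s$mean, sd_ppm = s$sd,
           point_used = s$point_used,
           intermediate_exchange = s$excluded_intermediate)
    })
  }
  if (!is.null(calls) && nrow(calls) > 0) rep_obj$exchange_calls <- calls
  if (!is.null(json_path)) {
    jsonlite::write_json(rep_obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  lines <- render_report_text(rep_obj)
  if (!is.null(text_path)) writeLines(lines, text_path)
  if (is.null(json_path) && is.null(text_path)) rep_obj else invisible(rep_obj)
}

render_report_text <- function(rep_obj) {
  lines <- c(sprintf("Titration fit report: %s", rep_obj$label), "")
  for (nm in names(rep_obj$fits)) {
    f <- rep_obj$fits[[nm]]
    conv <- if (isTRUE(f$converged)) "" else "  [not converged]"
    if (f$model == "single-site") {
      lines <- c(lines, sprintf(
        "%s: K_D = %s +/- %s (%.6g mM), dd_inf = %.4g ppm, rms %.2g ppm%s",
        nm, format_kd(f$kd_mM), format_kd(f$kd_sd_mM), f$kd_mM,
        f$ddmax_ppm, f$residual_rms_ppm, conv))
    } else {
      lines <- c(lines, sprintf("%s (two-site, %s mode)%s:", nm, f$mode, conv),
                 sprintf("  %s: K_D = %s +/- %s, delta = %.4g ppm",
                         f$site1$label, format_kd(f$site1$kd_mM),
                         format_kd(f$site1$kd_sd_mM), f$site1$delta_ppm),
                 sprintf("  %s: K_D = %s +/- %s, delta = %.4g ppm",
                         f$site2$label, format_kd(f$site2$kd_mM),
                         format_kd(f$site2$kd_sd_mM), f$site2$delta_ppm))
    }
  }
  if (!is.null(rep_obj$hotspots)) {
    lines <- c(lines, "", "Hotspot selections (mean + 1 SD):")
    for (h in rep_obj$hotspots) {
      lines <- c(lines, sprintf(
        "  %s @ point %d: threshold %.4g ppm -> residues %s", h$site_label,
        h$point_used, h$threshold_ppm, paste(h$selected, collapse = ", ")))
      if (length(h$intermediate_exchange) > 0) {
        lines <- c(lines, sprintf(
          "    intermediate exchange (qualitative binders): %s",
          paste(h$intermediate_exchange, collapse = ", ")))
      }
    }
  }
  if (!is.null(rep_obj$exchange_calls)) {
    ec <- rep_obj$exchange_calls
    n_by <- table(ec$regime)
    lines <- c(lines, "", sprintf("Exchange regimes: %s",
                                  paste(sprintf("%s=%d", names(n_by), n_by),
                                        collapse = ", ")))
  }
  lines
}
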