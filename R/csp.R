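#' Gyromagnetic-ratio-weighted chemical shift perturbation
#'
#' Combined amide shift distance between a reference (free) and an observed
#' peak position:
#' \deqn{\Delta\delta_w = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}}
#' The default weight `alpha = 0.1014` is the magnitude of the 15N/1H
#' gyromagnetic-ratio quotient; the common empirical alternatives (0.14,
#' 0.154) are one argument away.
#'
#' @param dh_free,dn_free Free-state 1H and 15N shifts, ppm.
#' @param dh_i,dn_i Observed shifts at a titration point, ppm.
#' @param alpha Positive 15N weight; default 0.1014.
#' @return Weighted shift distance(s), ppm (a norm: nonnegative, zero iff
#'   both shift changes are zero).
#' @export
weighted_csp <- function(dh_free, dn_free, dh_i, dn_i, alpha = 0.1014) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  sqrt((dh_i - dh_free)^2 + (alpha * (dn_i - dn_free))^2)
}

#' Per-residue CSP trajectories across a titration
#'
#' For every residue assigned in the free (ratio 0) spectrum, computes the
#' weighted shift distance of each titration point relative to the free
#' reference. Residues absent from a later point (intermediate-exchange
#' broadening) are flagged `"missing"` there, never imputed; the free point
#' is 0 by construction.
#'
#' @param series A [titration_series()].
#' @param alpha 15N weight passed to [weighted_csp()].
#' @return A `csp_profiles` data frame with columns `residue_id`,
#'   `point_index`, `ratio`, `ligand_conc`, `delta_delta`, `flag`
#'   (`"observed"`/`"missing"`), ordered by residue then point, with the
#'   weight stored in `attr(, "alpha")`.
#' @export
build_profiles <- function(series, alpha = 0.1014) {
  stopifnot(inherits(series, "titration_series"))
  free <- series$points[[1]]$peaks
  later_res <- unique(unlist(lapply(series$points[-1],
                                    function(pt) pt$peaks$residue_id)))
  orphan <- setdiff(later_res, free$residue_id)
  if (length(orphan) > 0) {
    warning(sprintf("residue(s) absent at the free reference excluded: %s",
                    paste(orphan, collapse = ", ")))
  }
  rows <- lapply(free$residue_id, function(res) {
    h0 <- free$delta_h[free$residue_id == res]
    n0 <- free$delta_n[free$residue_id == res]
    per_point <- lapply(series$points, function(pt) {
      j <- match(res, pt$peaks$residue_id)
      if (is.na(j)) {
        data.frame(residue_id = res, point_index = pt$index, ratio = pt$ratio,
                   ligand_conc = pt$ligand_conc, delta_delta = NA_real_,
                   flag = "missing", stringsAsFactors = FALSE)
      } else {
        dd <- if (pt$index == 1L) 0 else {
          weighted_csp(h0, n0, pt$peaks$delta_h[j], pt$peaks$delta_n[j],
                       alpha = alpha)
        }
        data.frame(residue_id = res, point_index = pt$index, ratio = pt$ratio,
                   ligand_conc = pt$ligand_conc, delta_delta = dd,
                   flag = "observed", stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, per_point)
  })
  profiles <- do.call(rbind, rows)
  attr(profiles, "alpha") <- alpha
  class(profiles) <- c("csp_profiles", "data.frame")
  profiles
}

#' Classify each residue's exchange regime
#'
#' A residue is `"intermediate"` if its peak is missing at any nonzero-ligand
#' point, or if peak heights are available and any point's height falls below
#' `theta` times the free-state height (coalescence broadening);
#' `"unperturbed"` if every observed shift distance stays below the floor
#' `epsilon`; otherwise `"fast"`.
#'
#' @param profiles A `csp_profiles` data frame from [build_profiles()].
#' @param series Optional [titration_series()] supplying peak heights for the
#'   broadening test; heights are only used when present.
#' @param theta Broadening threshold as a fraction of free-state height,
#'   in (0, 1); default 0.3.
#' @param epsilon Unperturbed floor, ppm; default 0.005 (the scale of HSQC
#'   digital resolution).
#' @return A data frame with columns `residue_id`, `regime`, `evidence`.
#' @export
classify_exchange <- function(profiles, series = NULL, theta = 0.3,
                              epsilon = 0.005) {
  stopifnot(is.data.frame(profiles), theta > 0, theta < 1, epsilon >= 0)
  res_ids <- unique(profiles$residue_id)
  heights <- NULL
  if (!is.null(series)) {
    stopifnot(inherits(series, "titration_series"))
    heights <- lapply(series$points, function(pt)
      setNames(pt$peaks$height, pt$peaks$residue_id))
  }
  rows <- lapply(res_ids, function(res) {
    prof <- profiles[profiles$residue_id == res, , drop = FALSE]
    prof <- prof[order(prof$point_index), , drop = FALSE]
    miss <- prof$flag == "missing" & prof$ratio > 0
    regime <- NULL
    evidence <- ""
    if (any(miss)) {
      regime <- "intermediate"
      evidence <- sprintf("peak absent at point(s) %s",
                          paste(prof$point_index[miss], collapse = ", "))
    } else if (!is.null(heights)) {
      h <- vapply(seq_along(heights), function(i) {
        v <- heights[[i]][as.character(res)]
        if (length(v) == 0) NA_real_ else unname(v)
      }, numeric(1))
      h_free <- h[1]
      if (is.finite(h_free) && h_free > 0) {
        low <- which(is.finite(h) & h < theta * h_free)
        low <- setdiff(low, 1L)
        if (length(low) > 0) {
          regime <- "intermediate"
          evidence <- sprintf("height below %.0f%% of free state at point(s) %s",
                              100 * theta, paste(low, collapse = ", "))
        }
      }
    }
    if (is.null(regime)) {
      obs <- prof$delta_delta[prof$flag == "observed"]
      if (all(obs < epsilon)) {
        regime <- "unperturbed"
        evidence <- sprintf("max shift distance %.4g ppm below floor %g",
                            max(obs), epsilon)
      } else {
        regime <- "fast"
        evidence <- sprintf("all points observed, max shift distance %.4g ppm",
                            max(obs))
      }
    }
    data.frame(residue_id = res, regime = regime, evidence = evidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write exchange-regime calls to CSV
#'
#' @param calls Data frame from [classify_exchange()].
#' @param path Output path.
#' @export
write_exchange_calls <- function(calls, path) {
  write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
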