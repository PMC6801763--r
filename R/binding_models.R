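#' Parameters of the single-site fast-exchange binding model
#'
#' Bundles the dissociation constant, the saturation shift change and the
#' total protein concentration used by [single_site_shift()]. Concentrations
#' are millimolar throughout the package API.
#'
#' @param kd Dissociation constant K_d, mM. Must be >= 0 (0 is the
#'   stoichiometric tight-binding limit).
#' @param ddmax Saturation shift change (the limiting weighted chemical shift
#'   perturbation at full occupancy), ppm. Must be >= 0.
#' @param a Total protein concentration, mM. Must be > 0.
#' @return An object of class `single_site_params`.
#' @export
single_site_params <- function(kd, ddmax, a) {
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd), kd >= 0,
            is.numeric(ddmax), length(ddmax) == 1L, is.finite(ddmax), ddmax >= 0,
            is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  structure(list(kd = kd, ddmax = ddmax, a = a), class = "single_site_params")
}

#' Parameters of the two-site (tandem-domain) binding model
#'
#' Two independent ligand-binding sites on one receptor chain (2:1
#' ligand:protein stoichiometry), each with its own dissociation constant and
#' saturation shift change.
#'
#' @param k1,k2 Site dissociation constants, mM. Must be > 0.
#' @param d1,d2 Per-site saturation shift changes, ppm. Must be >= 0.
#' @param p Total protein (receptor chain) concentration, mM. Must be > 0.
#' @return An object of class `two_site_params`.
#' @export
two_site_params <- function(k1, k2, d1, d2, p) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1), k1 > 0,
            is.numeric(k2), length(k2) == 1L, is.finite(k2), k2 > 0,
            is.numeric(d1), length(d1) == 1L, is.finite(d1), d1 >= 0,
            is.numeric(d2), length(d2) == 1L, is.finite(d2), d2 >= 0,
            is.numeric(p), length(p) == 1L, is.finite(p), p > 0)
  structure(list(k1 = k1, k2 = k2, d1 = d1, d2 = d2, p = p),
            class = "two_site_params")
}

#' Single-site fast-exchange binding curve
#'
#' Closed-form observed shift change under 1:1 binding with ligand depletion:
#' \deqn{y = \frac{\Delta\delta_\infty}{2}\left(B + x - \sqrt{(B+x)^2 - 4x}\right),
#'   \quad B = 1 + K_d/a}
#' where `x = b/a` is the ligand:protein molar ratio. Equals
#' `ddmax * (fraction of protein bound)`; the depletion (quadratic isotherm)
#' form is required because protein concentration is comparable to K_d in the
#' titrations this models.
#'
#' @param x Ligand:protein molar ratio(s), >= 0. Vectorized.
#' @param params A [single_site_params()] object.
#' @return Observed weighted shift change(s), ppm.
#' @seealso [single_site_oracle()] for the independent numeric equilibrium
#'   solution used to validate this closed form.
#' @export
single_site_shift <- function(x, params) {
  stopifnot(inherits(params, "single_site_params"),
            is.numeric(x), all(is.finite(x)), all(x >= 0))
  B <- 1 + params$kd / params$a
  disc <- (B + x)^2 - 4 * x
  # B >= 1 guarantees disc = (B + x)^2 - 4x >= (1 + x)^2 - 4x = (1 - x)^2 >= 0
  stopifnot(all(disc >= -1e-12))
  (params$ddmax / 2) * (B + x - sqrt(pmax(disc, 0)))
}

# Plain bisection for a continuous function with f(lo) and f(hi) of opposite
# sign (or zero); runs to near machine precision. Kept free of any closed-form
# algebra so it can serve as an independent oracle.
bisect_root <- function(f, lo, hi, iter = 200L) {
  flo <- f(lo)
  if (flo == 0) return(lo)
  fhi <- f(hi)
  if (fhi == 0) return(hi)
  stopifnot(sign(flo) != sign(fhi))
  for (i in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    if (mid == lo || mid == hi) break
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  0.5 * (lo + hi)
}

#' Numeric equilibrium oracle for the single-site model
#'
#' Solves the 1:1 equilibrium directly from mass balance —
#' `(a - PL)(b - PL) = Kd * PL` — for the complex concentration `[PL]` by
#' bisection on `[0, min(a, b)]`, then returns `ddmax * [PL] / a`. Shares no
#' algebra with [single_site_shift()]; used to validate it.
#'
#' @inheritParams single_site_shift
#' @return Observed weighted shift change(s), ppm.
#' @export
single_site_oracle <- function(x, params) {
  stopifnot(inherits(params, "single_site_params"),
            is.numeric(x), all(is.finite(x)), all(x >= 0))
  a <- params$a
  kd <- params$kd
  vapply(x, function(xi) {
    b <- xi * a
    if (b == 0) return(0)
    resid <- function(pl) (a - pl) * (b - pl) - kd * pl
    pl <- bisect_root(resid, 0, min(a, b))
    params$ddmax * pl / a
  }, numeric(1))
}

two_site_mass_balance <- function(L, l_tot, params) {
  L + params$p * L / (params$k1 + L) + params$p * L / (params$k2 + L) - l_tot
}

#' Free-ligand concentration for two independent sites (cubic mass balance)
#'
#' For two independent binding sites on one receptor at total concentration
#' `p`, the free ligand `L` satisfies
#' \deqn{L + \frac{pL}{K_1+L} + \frac{pL}{K_2+L} = L_{tot}}
#' which is a cubic in `L` with exactly one root in `[0, L_tot]`. The cubic is
#' solved by the trigonometric (three-real-root) closed form; the physical
#' root is then polished with a few Newton steps so the mass-balance residual
#' is at machine precision even for ill-conditioned `K1 << K2` draws. When the
#' trigonometric method degenerates (cosine argument outside [-1, 1] by more
#' than 1e-12), the solver falls back to bisection with a warning.
#'
#' @param l_tot Total ligand concentration(s), mM, >= 0. Vectorized.
#' @param params A [two_site_params()] object.
#' @return Free ligand concentration(s) `L` in `[0, l_tot]`, mM.
#' @export
solve_two_site_free_ligand <- function(l_tot, params) {
  stopifnot(inherits(params, "two_site_params"),
            is.numeric(l_tot), all(is.finite(l_tot)), all(l_tot >= 0))
  vapply(l_tot, function(lt) two_site_free_one(lt, params), numeric(1))
}

two_site_free_one <- function(l_tot, params) {
  if (l_tot == 0) return(0)
  k1 <- params$k1; k2 <- params$k2; p <- params$p
  # L^3 + c2 L^2 + c1 L + c0 = 0, from clearing denominators in the balance
  c2 <- k1 + k2 + 2 * p - l_tot
  c1 <- k1 * k2 + p * (k1 + k2) - l_tot * (k1 + k2)
  c0 <- -l_tot * k1 * k2
  # depressed cubic t^3 + pt*t + qt = 0 with L = t - c2/3
  pt <- c1 - c2^2 / 3
  qt <- 2 * c2^3 / 27 - c2 * c1 / 3 + c0
  L <- NA_real_
  if (pt < 0) {
    m <- 2 * sqrt(-pt / 3)
    w <- 3 * qt / (pt * m)
    if (abs(w) > 1 + 1e-12) {
      warning("trigonometric cubic solution degenerate; falling back to bisection")
    } else {
      w <- max(-1, min(1, w))
      theta <- acos(w) / 3
      roots <- m * cos(theta - 2 * pi * (0:2) / 3) - c2 / 3
      tol <- 1e-9 * max(1, l_tot)
      cand <- roots[roots >= -tol & roots <= l_tot + tol]
      if (length(cand) > 0) {
        cand <- pmin(pmax(cand, 0), l_tot)
        L <- cand[which.min(abs(two_site_mass_balance(cand, l_tot, params)))]
      }
    }
  }
  if (!is.finite(L)) {
    L <- bisect_root(function(x) two_site_mass_balance(x, l_tot, params),
                     0, l_tot)
  }
  # Newton polish; f' = 1 + p*K1/(K1+L)^2 + p*K2/(K2+L)^2 >= 1, always safe
  for (i in 1:5) {
    f <- two_site_mass_balance(L, l_tot, params)
    if (abs(f) < 1e-15 * max(1, l_tot)) break
    fp <- 1 + p * k1 / (k1 + L)^2 + p * k2 / (k2 + L)^2
    L <- min(max(L - f / fp, 0), l_tot)
  }
  L
}

#' Independent bisection oracle for the two-site free-ligand root
#'
#' Solves the same mass balance as [solve_two_site_free_ligand()] by plain
#' bisection on `[0, l_tot]`, with no cubic algebra. Validation oracle only.
#'
#' @inheritParams solve_two_site_free_ligand
#' @return Free ligand concentration(s), mM.
#' @export
two_site_free_ligand_bisect <- function(l_tot, params) {
  stopifnot(inherits(params, "two_site_params"),
            is.numeric(l_tot), all(is.finite(l_tot)), all(l_tot >= 0))
  vapply(l_tot, function(lt) {
    if (lt == 0) return(0)
    bisect_root(function(x) two_site_mass_balance(x, lt, params), 0, lt)
  }, numeric(1))
}

#' Two-site (XY2) binding curve
#'
#' Observed summed shift change for a tandem construct with two independent
#' sites: \deqn{y = \delta_1 \frac{L}{K_1+L} + \delta_2 \frac{L}{K_2+L}}
#' with the free ligand `L` from [solve_two_site_free_ligand()]. This is the
#' model fitted to the sum of the two per-site hotspot mean curves.
#'
#' @inheritParams solve_two_site_free_ligand
#' @return Observed shift change(s), ppm.
#' @export
two_site_shift <- function(l_tot, params) {
  s <- two_site_site_shifts(l_tot, params)
  s$y1 + s$y2
}

#' Per-site components of the two-site binding curve
#'
#' @inheritParams solve_two_site_free_ligand
#' @return A list with numeric vectors `y1` and `y2` (ppm); their sum equals
#'   [two_site_shift()].
#' @export
two_site_site_shifts <- function(l_tot, params) {
  L <- solve_two_site_free_ligand(l_tot, params)
  list(y1 = params$d1 * L / (params$k1 + L),
       y2 = params$d2 * L / (params$k2 + L))
}
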