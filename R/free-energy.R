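#' Bjerrum length of a solvent
#'
#' The Bjerrum length lB = e^2 / (4 pi eps0 eps kB T) is the separation
#' at which two unit charges in a continuum solvent of dielectric
#' constant `dielectric_constant` interact with Coulomb energy kB*T.
#' It is the single measure of Coulomb strength used throughout the
#' model: about 0.71 nm for water and 1.7 nm for methanol at room
#' temperature, and it grows as the product eps*T falls (poorer solvent
#' for ions).
#'
#' @param temperature Kelvin temperature, > 0.
#' @param dielectric_constant relative dielectric constant, > 0.
#' @return Bjerrum length in nm.
#' @export
#' @examples
#' bjerrum_length(298.15, 78.4)   # water, ~0.71 nm
#' bjerrum_length(298.15, 32.7)   # methanol, ~1.7 nm
bjerrum_length <- function(temperature, dielectric_constant) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be positive (Kelvin)", call. = FALSE)
  }
  if (any(!is.finite(dielectric_constant)) || any(dielectric_constant <= 0)) {
    stop("`dielectric_constant` must be positive", call. = FALSE)
  }
  lB_m <- .const$e_charge^2 /
    (4 * pi * .const$eps0 * dielectric_constant * .const$kB * temperature)
  lB_m * 1e9
}

#' Debye screening constant
#'
#' kappa^2 = 4 pi lB sum_i c_i z_i^2, the inverse square of the Debye
#' screening length set by the dissolved small ions.  Concentrations are
#' supplied in mol/L and converted internally to number densities in
#' nm^-3.  Only added salt enters the sum; the chain's own counterions
#' are not included.  At fixed molar composition kappa still varies with
#' lB (as sqrt(lB)), so sweeps over Bjerrum length must recompute it.
#'
#' @param lB Bjerrum length, nm.
#' @param salt salt table as in [solvent_conditions()]; `NULL` or empty
#'   gives kappa = 0.
#' @return kappa in nm^-1.
#' @export
#' @examples
#' 1 / debye_kappa(0.714, salt_1_1(0.01))   # Debye length ~3.04 nm
debye_kappa <- function(lB, salt = NULL) {
  if (any(!is.finite(lB)) || any(lB <= 0)) {
    stop("`lB` must be positive (nm)", call. = FALSE)
  }
  salt <- .normalise_salt(salt)
  if (nrow(salt) == 0L) return(0)
  ionic <- sum(.molar_to_nm3(salt$conc_M) * salt$valence^2)  # nm^-3
  sqrt(4 * pi * lB * ionic)
}

# Screened-sum building blocks shared by both branches.
# ln(1 - exp(-kappa*b)) via expm1 for accuracy at small kappa*b; the
# derivative  d/db ln(1 - e^(-kb)) = k e^(-kb) / (1 - e^(-kb)).
.ln_term <- function(b, kappa) {
  v <- log(-expm1(-kappa * b))
  if (any(!is.finite(v))) {
    stop("electrostatic term diverges: kappa*b = ",
         format(min(kappa * b)), " is too small (1 - exp(-kappa*b) ",
         "underflows). Add salt or increase b; the unscreened limit ",
         "kappa -> 0 is outside this model.", call. = FALSE)
  }
  v
}
.ln_term_db <- function(b, kappa) {
  kappa * exp(-kappa * b) / (-expm1(-kappa * b))
}

.check_b <- function(b) {
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("bead spacing `b` must be positive (nm)", call. = FALSE)
  }
}

#' Debye-Hueckel branch free energy per bead
#'
#' g_dh(b) = (1/2) a b^2 - (lB/b) ln(1 - e^(-kappa b)), in units of
#' kB*T per bead: the Hooke spring energy plus the screened Coulomb
#' repulsion of the fully charged chain.  This branch describes the low
#' charge density regime b > z*lB, where no counterions are condensed;
#' the function itself evaluates anywhere b > 0 and callers enforce the
#' validity side.
#'
#' @param b bead spacing, nm (vectorised).
#' @param a spring constant, nm^-2.
#' @param lB Bjerrum length, nm.
#' @param kappa Debye screening constant, nm^-1.
#' @return free energy per bead, kB*T.
#' @export
g_dh <- function(b, a, lB, kappa) {
  .check_b(b)
  0.5 * a * b^2 - (lB / b) * .ln_term(b, kappa)
}

#' Counterion-condensation branch free energy per bead
#'
#' g_cc(b) = (1/2) a b^2 - (1/z)(2 - b/(z lB)) ln(1 - e^(-kappa b))
#'           - 1/z + b/(z^2 lB),
#' in kB*T per bead.  Above the condensation threshold (bead spacing
#' b < z*lB) counterions of valence z condense on the chain and cap the
#' net charge at one per length z*lB; the electrostatic terms combine
#' the reduced net charge, the translational entropy of the condensed
#' layer, and its volume determination.  At b = z*lB this expression
#' equals [g_dh()] exactly, so the two branches join continuously at the
#' threshold.
#'
#' @inheritParams g_dh
#' @param z unsigned counterion valence.
#' @return free energy per bead, kB*T.
#' @export
g_cc <- function(b, a, z, lB, kappa) {
  .check_b(b)
  0.5 * a * b^2 -
    (1 / z) * (2 - b / (z * lB)) * .ln_term(b, kappa) -
    1 / z + b / (z^2 * lB)
}

# Analytic b-derivatives, used by the equilibrium solvers.
.dg_dh_db <- function(b, a, lB, kappa) {
  a * b + (lB / b^2) * .ln_term(b, kappa) -
    (lB / b) * .ln_term_db(b, kappa)
}
.dg_cc_db <- function(b, a, z, lB, kappa) {
  a * b + (1 / (z^2 * lB)) * .ln_term(b, kappa) -
    (1 / z) * (2 - b / (z * lB)) * .ln_term_db(b, kappa) +
    1 / (z^2 * lB)
}

#' Effective spring constant under counterion stiffening
#'
#' a(b) = a0 + (1/(8e)) t (lB/b), with e Euler's number.  The factor
#' (1/(8e)) lB/b is the number of condensed counterions per bead close
#' enough to the chain axis to bridge adjacent beads; each is assumed to
#' add `t` to the spring constant.  Because a rises as b falls, the
#' stiffening is self-reinforcing (a cascading nonlinearity) and can
#' drive cooperative collapse.
#'
#' A warning is issued when `t > 0` and lB/b lies outside the
#' self-consistency window of the condensed-layer construction (see
#' [validity_window()]); the value is still returned.
#'
#' @param a0 bare spring constant, nm^-2.
#' @param t stiffening parameter, nm^-2.
#' @param lB Bjerrum length, nm.
#' @param b bead spacing, nm (vectorised).
#' @return effective spring constant, nm^-2.
#' @export
#' @examples
#' effective_spring_constant(0.1, 4, lB = 2, b = 1)  # 0.1 + 1/e
effective_spring_constant <- function(a0, t, lB, b) {
  .check_b(b)
  x <- lB / b
  if (t > 0) {
    w <- validity_window()
    if (any(x < w[1] | x > w[2])) {
      warning("lB/b = ", format(signif(x[which.max(abs(x - mean(w)))], 4)),
              " outside the condensed-layer validity window (",
              format(signif(w[1], 3)), ", ", format(signif(w[2], 3)), ")",
              call. = FALSE)
    }
  }
  a0 + t * x / (8 * exp(1))
}

#' Geometry of the condensed counterion layer
#'
#' For bead spacing b in the condensation regime (lB/b > 1) the
#' condensed layer occupies a cylinder of radius
#' R = sqrt(8e (lB/b - 1)) * b around the chain, holds an overall local
#' concentration of 1/(8 pi e lB b^2) counterions per unit volume, and
#' the subpopulation near enough to act on the springs — those within a
#' volume pi lB^2 b per bead — numbers (1/(8e)) lB/b per bead.  (e is
#' Euler's number throughout.)
#'
#' @param lB Bjerrum length, nm.
#' @param b bead spacing, nm; requires lB/b > 1.
#' @return object of class `condensed_layer` with fields `radius` (nm),
#'   `total_condensed_concentration` (nm^-3) and
#'   `active_counterions_per_bead` (dimensionless).
#' @export
condensed_layer <- function(lB, b) {
  .check_b(b)
  stopifnot(length(lB) == 1L, length(b) == 1L, is.finite(lB), lB > 0)
  x <- lB / b
  if (x <= 1) {
    stop("no condensed layer: lB/b = ", format(signif(x, 4)),
         " <= 1 (below the condensation threshold)", call. = FALSE)
  }
  e <- exp(1)
  structure(list(
    radius = sqrt(8 * e * (x - 1) * b^2),
    total_condensed_concentration = 1 / (8 * pi * e * lB * b^2),
    active_counterions_per_bead = x / (8 * e)
  ), class = "condensed_layer")
}

#' @export
print.condensed_layer <- function(x, ...) {
  cat("Condensed counterion layer\n")
  cat(sprintf("  cylinder radius:       %.6g nm\n", x$radius))
  cat(sprintf("  local concentration:   %.6g nm^-3\n",
              x$total_condensed_concentration))
  cat(sprintf("  active ions per bead:  %.6g\n",
              x$active_counterions_per_bead))
  invisible(x)
}

#' Self-consistency window of the condensed-layer construction
#'
#' The active-subpopulation picture requires the condensed-layer radius
#' R = sqrt(8e (lB/b - 1)) * b to exceed lB itself.  Writing x = lB/b,
#' the boundary R = lB is the quadratic x^2 - 8e x + 8e = 0, whose roots
#' x = 4e +/- sqrt(16 e^2 - 8 e) delimit the admissible ratio range —
#' about 1.05 < lB/b < 20.7.  Full-precision roots are returned.
#'
#' @return named numeric vector `c(lower, upper)` in units of lB/b.
#' @export
validity_window <- function() {
  e <- exp(1)
  d <- sqrt(16 * e^2 - 8 * e)
  c(lower = 4 * e - d, upper = 4 * e + d)
}
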