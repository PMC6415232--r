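#' Solvent and salt conditions
#'
#' Bundle the electrostatic environment of the chain: the Bjerrum length
#' `lB` of the solvent, given either directly or through a temperature /
#' dielectric-constant pair, and the dissolved salt that sets the Debye
#' screening constant.  `lB` measures the Coulomb strength of the solvent
#' (the distance at which two unit charges interact with energy kB*T);
#' larger `lB` means a poorer solvent for ions.
#'
#' Exactly one of the two specification modes must be used: either
#' `bjerrum` alone, or `dielectric` (with `temperature`, defaulting to
#' 298.15 K).  Supplying both is an error, since they could contradict
#' each other.
#'
#' @param bjerrum Bjerrum length in nm, or `NULL` to derive it from
#'   `temperature` and `dielectric`.
#' @param temperature Kelvin temperature; only used with `dielectric`.
#'   Defaults to 298.15 K when `dielectric` is given without it.
#' @param dielectric relative dielectric constant of the solvent
#'   (78.4 for water, 32.7 for methanol at room temperature).
#' @param salt salt composition: a data frame (or matrix) with columns
#'   `conc_M` (molar concentration) and `valence` (unsigned integer
#'   valence), one row per small-ion species.  A 1:1 salt at
#'   concentration c contributes two rows of concentration c and
#'   valence 1.  `NULL` or zero rows means no added salt (kappa = 0).
#'
#' @return An object of class `solvent_conditions` with elements
#'   `bjerrum_nm`, `salt` (normalised data frame), and, when derived,
#'   `temperature_K` and `dielectric`.
#' @seealso [bjerrum_length()], [debye_kappa()], [salt_1_1()]
#' @export
#' @examples
#' solvent_conditions(bjerrum = 2.0, salt = salt_1_1(0.01))
#' solvent_conditions(temperature = 298.15, dielectric = 78.4)
solvent_conditions <- function(bjerrum = NULL, temperature = NULL,
                               dielectric = NULL, salt = NULL) {
  if (!is.null(bjerrum) && !is.null(dielectric)) {
    stop("give either `bjerrum` or a `temperature`/`dielectric` pair, not both",
         call. = FALSE)
  }
  if (is.null(bjerrum)) {
    if (is.null(dielectric)) {
      stop("solvent underdetermined: give `bjerrum` or `dielectric` ",
           "(optionally with `temperature`)", call. = FALSE)
    }
    if (is.null(temperature)) temperature <- 298.15
    bjerrum <- bjerrum_length(temperature, dielectric)
  } else {
    if (!is.numeric(bjerrum) || length(bjerrum) != 1L || !is.finite(bjerrum) ||
        bjerrum <= 0) {
      stop("`bjerrum` must be a single positive number (nm)", call. = FALSE)
    }
  }
  salt <- .normalise_salt(salt)
  out <- list(bjerrum_nm = bjerrum, salt = salt,
              temperature_K = temperature, dielectric = dielectric)
  class(out) <- "solvent_conditions"
  out
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat("Solvent conditions\n")
  cat(sprintf("  Bjerrum length lB: %.6g nm\n", x$bjerrum_nm))
  if (!is.null(x$dielectric)) {
    cat(sprintf("  (from T = %.6g K, epsilon = %.6g)\n",
                x$temperature_K, x$dielectric))
  }
  if (nrow(x$salt) == 0L) {
    cat("  Salt: none (kappa = 0)\n")
  } else {
    for (i in seq_len(nrow(x$salt))) {
      cat(sprintf("  Salt species: %.6g M, valence %d\n",
                  x$salt$conc_M[i], x$salt$valence[i]))
    }
    cat(sprintf("  Debye kappa: %.6g nm^-1\n",
                debye_kappa(x$bjerrum_nm, x$salt)))
  }
  invisible(x)
}

# Accepts NULL, a two-column data frame/matrix, or a numeric vector of
# length 2 (conc, valence); returns a validated data frame.
.normalise_salt <- function(salt) {
  if (is.null(salt)) {
    return(data.frame(conc_M = numeric(0), valence = integer(0)))
  }
  if (is.numeric(salt) && length(salt) == 2L) {
    salt <- data.frame(conc_M = salt[1], valence = salt[2])
  }
  salt <- as.data.frame(salt)
  if (!all(c("conc_M", "valence") %in% names(salt))) {
    stop("`salt` needs columns `conc_M` and `valence`", call. = FALSE)
  }
  if (any(!is.finite(salt$conc_M)) || any(salt$conc_M < 0)) {
    stop("salt concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(salt$valence < 1) || any(salt$valence != round(salt$valence))) {
    stop("salt valences must be integers >= 1", call. = FALSE)
  }
  salt$valence <- as.integer(salt$valence)
  salt[c("conc_M", "valence")]
}

#' Symmetric 1:1 salt
#'
#' Convenience constructor for the salt table of a fully dissociated 1:1
#' electrolyte (e.g. NaCl) at molar concentration `conc_M`: two ion
#' species, each at `conc_M` with valence 1.
#'
#' @param conc_M molar concentration of the salt.
#' @return a two-row salt data frame for [solvent_conditions()].
#' @export
salt_1_1 <- function(conc_M) {
  stopifnot(is.numeric(conc_M), length(conc_M) == 1L, conc_M >= 0)
  data.frame(conc_M = c(conc_M, conc_M), valence = c(1L, 1L))
}

#' Mechanical and counterion parameters of the bead-spring chain
#'
#' The chain is a line of unit point charges joined by zero-rest-length
#' Hooke springs.  `a0` is the bare (reduced) spring constant in nm^-2,
#' energies being measured in kB*T.  `z` is the unsigned valence of the
#' counterions, which sets the condensation threshold at bead spacing
#' b = z*lB.  `t` couples locally active condensed counterions to the
#' spring constant through a = a0 + (1/(8e)) * t * (lB/b); `t = 0`
#' recovers a plain spring.
#'
#' @param a0 bare spring constant, nm^-2; must be > 0 (a chain with no
#'   restoring force has no equilibrium spacing).
#' @param z unsigned counterion valence, integer >= 1.
#' @param t spring-stiffening parameter, nm^-2, >= 0.  Default 0.
#' @return object of class `chain_params`.
#' @export
#' @examples
#' chain_params(a0 = 0.1)
#' chain_params(a0 = 0.1, t = 50)   # strong counterion stiffening
chain_params <- function(a0, z = 1L, t = 0) {
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0) {
    stop("`a0` must be a single positive number (nm^-2)", call. = FALSE)
  }
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    stop("`z` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single number >= 0 (nm^-2)", call. = FALSE)
  }
  structure(list(a0 = a0, z = as.integer(z), t = t), class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat(sprintf("Bead-spring chain: a0 = %.6g nm^-2, z = %d, t = %.6g nm^-2\n",
              x$a0, x$z, x$t))
  invisible(x)
}
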