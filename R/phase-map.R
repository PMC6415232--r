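.salt_label <- function(salt) {
  salt <- .normalise_salt(salt)
  if (nrow(salt) == 0L) return("no salt")
  paste(sprintf("%g M (z=%d)", salt$conc_M, salt$valence), collapse = " + ")
}

# Raw stationary point of one branch at a given lB, ignoring validity;
# NA when the branch has no interior minimum.  Used by the edge finders.
.branch_root <- function(branch, chain, salt, lB, b_range, tol = 1e-12) {
  kappa <- debye_kappa(lB, salt)
  a <- chain$a0; z <- chain$z
  if (branch == "dh") {
    dg <- function(b) .dg_dh_db(b, a, lB, kappa)
    gf <- function(b) g_dh(b, a, lB, kappa)
  } else {
    dg <- function(b) .dg_cc_db(b, a, z, lB, kappa)
    gf <- function(b) g_cc(b, a, z, lB, kappa)
  }
  fit <- .find_minimum(dg, gf, b_range[1], b_range[2], tol = tol)
  if (fit$found) fit$beq else NA_real_
}

#' Branch structure along a Bjerrum-length sweep
#'
#' Solves both free-energy branches at every Bjerrum length of the grid,
#' recomputing the Debye screening constant at each lB (at fixed molar
#' salt, kappa grows as sqrt(lB)).  The result is a tidy table, one row
#' per lB, recording which branches possess valid equilibria and whether
#' the chain is bistable there.
#'
#' @param chain a [chain_params()] with `t = 0`.
#' @param salt salt table as in [solvent_conditions()].
#' @param lB_grid positive increasing Bjerrum lengths, nm.
#' @param b_range search bracket for beq, nm.
#' @param tol solver tolerance, nm.
#' @return data frame with columns `lB`, `a0`, `z`, `salt`, `kappa`,
#'   `dh_beq`, `cc_beq` (NA where the branch has no valid equilibrium),
#'   and `bistable`.
#' @export
#' @examples
#' sweep_bjerrum(chain_params(a0 = 0.1), salt_1_1(0.01),
#'               lB_grid = seq(1.2, 3.0, by = 0.3))
sweep_bjerrum <- function(chain, salt, lB_grid, b_range = c(1e-3, 100),
                          tol = 1e-10) {
  stopifnot(inherits(chain, "chain_params"))
  if (any(lB_grid <= 0) || any(diff(lB_grid) <= 0)) {
    stop("`lB_grid` must be positive and strictly increasing", call. = FALSE)
  }
  salt <- .normalise_salt(salt)
  lab <- .salt_label(salt)
  rows <- lapply(lB_grid, function(lB) {
    sol <- solvent_conditions(bjerrum = lB, salt = salt)
    st <- is_bistable(chain, sol, b_range, tol)
    data.frame(
      lB = lB, a0 = chain$a0, z = chain$z, salt = lab,
      kappa = debye_kappa(lB, salt),
      dh_beq = if (st$dh$valid) st$dh$beq else NA_real_,
      cc_beq = if (st$cc$valid) st$cc$beq else NA_real_,
      bistable = st$bistable
    )
  })
  do.call(rbind, rows)
}

#' Bjerrum-length interval of bistability
#'
#' Locates the transition range of Bjerrum lengths within which both a
#' stretched (Debye-Hueckel) and a contracted (counterion-condensed)
#' equilibrium coexist.  Each edge is defined by a branch root crossing
#' the condensation threshold: at the lower edge the CC root first dips
#' below beq = z*lB (the contracted branch comes into existence), and at
#' the upper edge the DH root falls to beq = z*lB (the stretched branch
#' terminates).  A coarse sweep brackets each crossing, which is then
#' polished by bisection on lB.
#'
#' @param chain a [chain_params()] with `t = 0`.
#' @param salt salt table.
#' @param bracket lB interval searched, nm.
#' @param tol bisection tolerance on the edges, nm.
#' @param coarse_step step of the bracketing sweep, nm.
#' @param b_range bead-spacing bracket passed to the branch solver.
#' @return an `overlap_range` object with `lB_low`, `lB_high`, `exists`,
#'   plus the chain/salt descriptors; `exists = FALSE` (edges NA) when
#'   no bistability is found in the bracket.
#' @export
#' @examples
#' find_overlap_range(chain_params(a0 = 0.1), salt_1_1(0.01))
find_overlap_range <- function(chain, salt, bracket = c(0.5, 10),
                               tol = 1e-4, coarse_step = 0.05,
                               b_range = c(1e-3, 100)) {
  stopifnot(inherits(chain, "chain_params"))
  if (chain$t != 0) stop("overlap mapping requires t = 0", call. = FALSE)
  salt <- .normalise_salt(salt)
  z <- chain$z

  edge <- function(branch) {
    f <- function(lB) {
      r <- .branch_root(branch, chain, salt, lB, b_range)
      if (is.na(r)) NA_real_ else r - z * lB
    }
    lBs <- seq(bracket[1], bracket[2], by = coarse_step)
    fv <- vapply(lBs, f, numeric(1))
    ok <- which(!is.na(fv))
    if (length(ok) < 2L) return(NA_real_)
    i <- ok[-length(ok)]
    j <- ok[-1L]
    cross <- which(fv[i] * fv[j] < 0 & (j - i == 1L))
    if (length(cross) == 0L) return(NA_real_)
    k <- cross[1L]
    stats::uniroot(f, c(lBs[i[k]], lBs[j[k]]), tol = tol)$root
  }

  lB_low <- edge("cc")
  lB_high <- edge("dh")
  exists <- !is.na(lB_low) && !is.na(lB_high) && lB_low < lB_high
  structure(list(lB_low = if (exists) lB_low else NA_real_,
                 lB_high = if (exists) lB_high else NA_real_,
                 exists = exists, a0 = chain$a0, z = z,
                 salt = .salt_label(salt), tol = tol),
            class = "overlap_range")
}

#' @export
print.overlap_range <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("No bistable overlap found (a0 = %g nm^-2, %s)\n",
                x$a0, x$salt))
  } else {
    cat(sprintf("Bistable overlap: %.4f nm < lB < %.4f nm (a0 = %g nm^-2, z = %d, %s)\n",
                x$lB_low, x$lB_high, x$a0, x$z, x$salt))
  }
  invisible(x)
}

#' @export
as.data.frame.overlap_range <- function(x, ...) {
  data.frame(a0 = x$a0, z = x$z, salt = x$salt,
             lB_low = x$lB_low, lB_high = x$lB_high,
             width = x$lB_high - x$lB_low,
             beq_low = x$z * x$lB_low, beq_high = x$z * x$lB_high,
             exists = x$exists)
}

#' Funnel of transition regions over spring stiffness
#'
#' Maps the bistable overlap interval for each spring constant of a
#' grid.  In the (lB, beq) plane the per-a transition regions merge into
#' a funnel centred on the line beq = z*lB and tapering toward the
#' origin for stiff springs: the overlap width shrinks as a grows,
#' because stiff springs fluctuate less.  The returned table carries the
#' interval edges together with the bead spacings beq = z*lB at which
#' each branch meets the threshold, enough to redraw the funnel.
#'
#' @param a_grid positive spring constants, nm^-2.
#' @param salt salt table.
#' @param bracket,tol,coarse_step,b_range as in [find_overlap_range()].
#' @param z counterion valence.
#' @return data frame, one row per spring constant, columns as
#'   `as.data.frame.overlap_range`.
#' @export
funnel_map <- function(a_grid, salt, bracket = c(0.05, 10), tol = 1e-4,
                       coarse_step = 0.02, b_range = c(1e-3, 100), z = 1L) {
  stopifnot(all(a_grid > 0))
  rows <- lapply(a_grid, function(a) {
    ov <- find_overlap_range(chain_params(a0 = a, z = z), salt,
                             bracket = bracket, tol = tol,
                             coarse_step = coarse_step, b_range = b_range)
    as.data.frame(ov)
  })
  do.call(rbind, rows)
}

#' Collapse curves under counterion spring stiffening
#'
#' Sweeps the Bjerrum length for each stiffening parameter t and records
#' the equilibrium spacing of the collapse model ([solve_collapse()]),
#' the effective spring constant at equilibrium, and the ratio lB/beq
#' with a flag marking rows outside the condensed-layer validity window.
#' Three regimes emerge: t = 0 leaves only the mild passive contraction
#' of condensation; moderate t contracts appreciably only at large lB;
#' large t drives strong contraction from the condensation threshold on.
#'
#' @param a0 bare spring constant, nm^-2.
#' @param t_values stiffening parameters, nm^-2.
#' @param salt salt table.
#' @param lB_grid positive increasing Bjerrum lengths, nm.
#' @param b_range,tol,method passed to [solve_collapse()].
#' @param z counterion valence.
#' @return data frame with columns `t`, `lB`, `beq`, `a_effective`,
#'   `lB_over_b`, `in_window`.
#' @export
collapse_curve <- function(a0, t_values, salt, lB_grid,
                           b_range = c(1e-3, 100), tol = 1e-10,
                           method = "composite", z = 1L) {
  salt <- .normalise_salt(salt)
  w <- validity_window()
  rows <- lapply(t_values, function(t) {
    chain <- chain_params(a0 = a0, z = z, t = t)
    per_lB <- lapply(lB_grid, function(lB) {
      sol <- solvent_conditions(bjerrum = lB, salt = salt)
      res <- suppressWarnings(
        solve_collapse(chain, sol, b_range, tol, method = method))
      x <- lB / res$beq
      data.frame(t = t, lB = lB, beq = res$beq,
                 a_effective = res$a_effective, lB_over_b = x,
                 in_window = is.finite(x) && x > w[1] && x < w[2])
    })
    do.call(rbind, per_lB)
  })
  do.call(rbind, rows)
}
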