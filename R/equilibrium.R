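# Locate minima of a smooth 1-D free energy on (lo, hi): scan the
# analytic derivative on a log-spaced grid for - to + sign changes,
# polish each with uniroot, and return the minimum of lowest g.
.find_minimum <- function(dg, g, lo, hi, n_scan = 600L, tol = 1e-12) {
  bs <- exp(seq(log(lo), log(hi), length.out = n_scan))
  fv <- vapply(bs, dg, numeric(1))
  s <- sign(fv)
  idx <- which(s[-length(s)] < 0 & s[-1L] >= 0)  # descending -> ascending
  if (length(idx) == 0L) {
    return(list(beq = NA_real_, g = NA_real_, found = FALSE,
                iterations = 0L,
                reason = if (all(fv > 0)) "derivative positive throughout bracket (minimum at lower bound)"
                         else if (all(fv < 0)) "derivative negative throughout bracket (minimum at upper bound)"
                         else "no interior minimum in bracket"))
  }
  cand <- lapply(idx, function(i) {
    r <- stats::uniroot(dg, c(bs[i], bs[i + 1L]), tol = tol)
    list(beq = r$root, iterations = r$iter)
  })
  gs <- vapply(cand, function(cc) g(cc$beq), numeric(1))
  best <- cand[[which.min(gs)]]
  list(beq = best$beq, g = min(gs), found = TRUE,
       iterations = best$iterations, reason = "converged")
}

.new_equilibrium_result <- function(branch, beq, g, valid, a_effective,
                                    chain, lB, kappa, bracket, iterations,
                                    reason) {
  structure(list(branch = branch, beq = beq, g_at_beq = g, valid = valid,
                 a_effective = a_effective, z = chain$z, a0 = chain$a0,
                 t = chain$t, lB = lB, kappa = kappa,
                 diagnostics = list(bracket = bracket,
                                    iterations = iterations,
                                    reason = reason)),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium (%s branch): ", toupper(x$branch)))
  if (is.na(x$beq)) {
    cat("no equilibrium —", x$diagnostics$reason, "\n")
  } else {
    cat(sprintf("beq = %.6g nm, g = %.6g kBT, %s\n", x$beq, x$g_at_beq,
                if (x$valid) "valid" else
                  paste0("INVALID (", x$diagnostics$reason, ")")))
    cat(sprintf("  lB = %.6g nm, kappa = %.6g nm^-1, a_eff = %.6g nm^-2, z = %d\n",
                x$lB, x$kappa, x$a_effective, x$z))
  }
  invisible(x)
}

#' @export
as.data.frame.equilibrium_result <- function(x, ...) {
  data.frame(branch = x$branch, beq = x$beq, g_at_beq = x$g_at_beq,
             valid = x$valid, a_effective = x$a_effective, a0 = x$a0,
             t = x$t, z = x$z, lB = x$lB, kappa = x$kappa)
}

#' Equilibrium bead spacing on one free-energy branch
#'
#' Finds the equilibrium spring length beq as the minimum of the branch
#' free energy, i.e. the root of dg/db = 0 with positive curvature, for
#' fixed (z, a, lB, kappa).  The Debye-Hueckel branch is physical only
#' for beq >= z*lB (no condensation) and the counterion-condensation
#' branch only for beq <= z*lB; a root on the wrong side is returned
#' with `valid = FALSE` and a diagnostic rather than as an error, since
#' branch termination is exactly what delimits the bistable transition
#' range.  Equality with the threshold (within 1e-8 nm) counts as valid:
#' a branch terminates where its root meets beq = z*lB.
#'
#' @param branch `"dh"` or `"cc"`.
#' @param chain a [chain_params()] with `t = 0` (use [solve_collapse()]
#'   for spring stiffening).
#' @param solvent a [solvent_conditions()].
#' @param b_range search bracket for beq, nm.  The default spans all
#'   regimes of interest with wide margin.
#' @param tol convergence tolerance on beq, nm.
#' @return an `equilibrium_result`: branch, `beq`, `g_at_beq`, `valid`,
#'   `a_effective` and diagnostics (bracket, iterations, reason).
#' @export
#' @examples
#' sol <- solvent_conditions(bjerrum = 2.0, salt = salt_1_1(0.01))
#' solve_branch("dh", chain_params(a0 = 0.1), sol)   # stretched state
#' solve_branch("cc", chain_params(a0 = 0.1), sol)   # contracted state
solve_branch <- function(branch = c("dh", "cc"), chain, solvent,
                         b_range = c(1e-3, 100), tol = 1e-10) {
  branch <- match.arg(branch)
  stopifnot(inherits(chain, "chain_params"),
            inherits(solvent, "solvent_conditions"))
  if (chain$t != 0) {
    stop("`solve_branch` handles rigid springs only (t = 0); ",
         "use `solve_collapse` for counterion stiffening", call. = FALSE)
  }
  lB <- solvent$bjerrum_nm
  kappa <- debye_kappa(lB, solvent$salt)
  a <- chain$a0
  z <- chain$z
  if (branch == "dh") {
    dg <- function(b) .dg_dh_db(b, a, lB, kappa)
    gf <- function(b) g_dh(b, a, lB, kappa)
  } else {
    dg <- function(b) .dg_cc_db(b, a, z, lB, kappa)
    gf <- function(b) g_cc(b, a, z, lB, kappa)
  }
  fit <- .find_minimum(dg, gf, b_range[1], b_range[2], tol = min(tol, 1e-12))
  if (!fit$found) {
    return(.new_equilibrium_result(branch, NA_real_, NA_real_, FALSE, a,
                                   chain, lB, kappa, b_range,
                                   fit$iterations,
                                   paste("no equilibrium on this branch:",
                                         fit$reason)))
  }
  thr <- z * lB
  band <- 1e-8  # |beq - z*lB| below this counts as "at threshold"
  valid <- if (branch == "dh") fit$beq >= thr - band else fit$beq <= thr + band
  reason <- if (valid) "converged" else
    sprintf("root b = %.6g nm on the wrong side of the condensation threshold z*lB = %.6g nm",
            fit$beq, thr)
  .new_equilibrium_result(branch, fit$beq, fit$g, valid, a, chain, lB,
                          kappa, b_range, fit$iterations, reason)
}

#' Piecewise free-energy landscape across the condensation threshold
#'
#' Samples the physical free energy g(b): the counterion-condensation
#' branch for b below the threshold z*lB and the Debye-Hueckel branch
#' above it.  The two branches join continuously at the threshold, which
#' is inserted into the grid.  Interior local minima are located on the
#' samples and polished against the analytic derivative of their branch;
#' when minima exist on both sides, the junction itself is the local
#' maximum separating the stretched and contracted states.
#'
#' @inheritParams solve_branch
#' @param b_grid strictly increasing positive bead spacings spanning the
#'   junction z*lB.
#' @return a `free_energy_profile`: data frame `samples` with columns
#'   `b`, `g`, `branch`; the `junction` abscissa; data frame `minima`;
#'   and `maximum` (the junction point, or `NULL` if not a maximum).
#' @export
free_energy_profile <- function(chain, solvent, b_grid) {
  stopifnot(inherits(chain, "chain_params"),
            inherits(solvent, "solvent_conditions"))
  if (chain$t != 0) {
    stop("profiles are defined for t = 0 chains", call. = FALSE)
  }
  if (any(diff(b_grid) <= 0) || any(b_grid <= 0)) {
    stop("`b_grid` must be positive and strictly increasing", call. = FALSE)
  }
  lB <- solvent$bjerrum_nm
  kappa <- debye_kappa(lB, solvent$salt)
  z <- chain$z
  a <- chain$a0
  junction <- z * lB
  if (min(b_grid) >= junction || max(b_grid) <= junction) {
    stop("`b_grid` must span the condensation threshold z*lB = ",
         format(signif(junction, 6)), " nm", call. = FALSE)
  }
  b <- sort(unique(c(b_grid, junction)))
  branch <- ifelse(b < junction, "cc", ifelse(b > junction, "dh", "junction"))
  g <- ifelse(b <= junction,
              g_cc(b, a, z, lB, kappa),
              g_dh(b, a, lB, kappa))
  samples <- data.frame(b = b, g = g, branch = branch)

  n <- length(b)
  int <- 2:(n - 1L)
  is_min <- g[int] < g[int - 1L] & g[int] < g[int + 1L]
  minima <- data.frame(b = numeric(0), g = numeric(0), branch = character(0))
  for (i in int[is_min]) {
    br <- if (b[i] < junction) "cc" else "dh"
    dg <- if (br == "cc") {
      function(x) .dg_cc_db(x, a, z, lB, kappa)
    } else {
      function(x) .dg_dh_db(x, a, lB, kappa)
    }
    lo <- b[i - 1L]; hi <- b[i + 1L]
    bm <- if (dg(lo) < 0 && dg(hi) > 0) {
      stats::uniroot(dg, c(lo, hi), tol = 1e-12)$root
    } else b[i]
    gm <- if (br == "cc") g_cc(bm, a, z, lB, kappa) else g_dh(bm, a, lB, kappa)
    minima <- rbind(minima, data.frame(b = bm, g = gm, branch = br))
  }
  j <- which(b == junction)
  maximum <- NULL
  if (j > 1L && j < n && g[j] > g[j - 1L] && g[j] > g[j + 1L]) {
    maximum <- c(b = junction, g = g[j])
  }
  structure(list(samples = samples, junction = junction, minima = minima,
                 maximum = maximum, chain = chain, lB = lB, kappa = kappa),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d samples, junction z*lB = %.6g nm\n",
              nrow(x$samples), x$junction))
  if (nrow(x$minima)) {
    for (i in seq_len(nrow(x$minima))) {
      cat(sprintf("  minimum (%s): b = %.6g nm, g = %.6g kBT\n",
                  toupper(x$minima$branch[i]), x$minima$b[i], x$minima$g[i]))
    }
  } else cat("  no interior minima on the grid\n")
  if (!is.null(x$maximum)) {
    cat(sprintf("  maximum at junction: g = %.6g kBT\n", x$maximum["g"]))
  }
  invisible(x)
}

#' Coexistence of stretched and contracted states
#'
#' A chain is bistable when both branches possess valid minima on their
#' own sides of the condensation threshold: a stretched, counterion-free
#' state (DH) and a contracted, counterion-condensed state (CC).  The
#' spring length then fluctuates between the two minima.
#'
#' @inheritParams solve_branch
#' @return list with `bistable` (logical) and the two
#'   `equilibrium_result`s, `dh` and `cc`.
#' @export
is_bistable <- function(chain, solvent, b_range = c(1e-3, 100),
                        tol = 1e-10) {
  dh <- solve_branch("dh", chain, solvent, b_range, tol)
  cc <- solve_branch("cc", chain, solvent, b_range, tol)
  list(bistable = isTRUE(dh$valid) && isTRUE(cc$valid) &&
         !is.na(dh$beq) && !is.na(cc$beq),
       dh = dh, cc = cc)
}

#' Equilibrium spacing with condensed-counterion spring stiffening
#'
#' Solves the collapse model in which condensed counterions stiffen the
#' springs, a(b) = a0 + (1/(8e)) t (lB/b).  By default the b-dependent
#' spring constant is substituted into the spring term and the composite
#' free energy (1/2) a(b) b^2 + (electrostatic CC terms) is minimised
#' directly, so the stiffening feedback is honoured by the minimisation
#' itself.  `method = "iterative"` instead freezes a, solves the rigid
#' CC branch, updates a from the new beq, and repeats to a fixed point —
#' an explicit rendering of the cascading picture, kept for comparison
#' (the two schemes weight the stiffening force slightly differently but
#' produce the same qualitative regimes).
#'
#' A warning reports a solution whose lB/beq ratio leaves the
#' condensed-layer validity window; a minimiser pushed to the lower
#' bracket edge is reported as "collapsed to bound" with `valid = FALSE`
#' rather than silently clipped.
#'
#' @param chain a [chain_params()], typically with `t > 0`.
#' @inheritParams solve_branch
#' @param method `"composite"` (default) or `"iterative"`.
#' @return an `equilibrium_result` on the CC branch with `a_effective`
#'   evaluated at beq.
#' @export
#' @examples
#' sol <- solvent_conditions(bjerrum = 5, salt = salt_1_1(0.01))
#' solve_collapse(chain_params(a0 = 0.1, t = 50), sol)
solve_collapse <- function(chain, solvent, b_range = c(1e-3, 100),
                           tol = 1e-10, method = c("composite", "iterative")) {
  method <- match.arg(method)
  stopifnot(inherits(chain, "chain_params"),
            inherits(solvent, "solvent_conditions"))
  lB <- solvent$bjerrum_nm
  kappa <- debye_kappa(lB, solvent$salt)
  a0 <- chain$a0; t <- chain$t; z <- chain$z
  ce <- 1 / (8 * exp(1))

  if (method == "composite") {
    # g(b) = 1/2 (a0 + ce t lB / b) b^2 + electrostatic CC terms
    gf <- function(b) {
      0.5 * (a0 + ce * t * lB / b) * b^2 -
        (1 / z) * (2 - b / (z * lB)) * .ln_term(b, kappa) -
        1 / z + b / (z^2 * lB)
    }
    dg <- function(b) {
      a0 * b + 0.5 * ce * t * lB +
        (1 / (z^2 * lB)) * .ln_term(b, kappa) -
        (1 / z) * (2 - b / (z * lB)) * .ln_term_db(b, kappa) +
        1 / (z^2 * lB)
    }
    fit <- .find_minimum(dg, gf, b_range[1], b_range[2],
                         tol = min(tol, 1e-12))
    if (!fit$found) {
      return(.new_equilibrium_result("cc", NA_real_, NA_real_, FALSE, NA_real_,
                                     chain, lB, kappa, b_range, 0L,
                                     paste("collapsed to bound:", fit$reason)))
    }
    beq <- fit$beq
    g_at <- fit$g
    iters <- fit$iterations
  } else {
    rigid <- chain_params(a0 = a0, z = z, t = 0)
    a_cur <- a0
    beq <- NA_real_
    iters <- 0L
    repeat {
      iters <- iters + 1L
      rigid$a0 <- a_cur
      res <- solve_branch("cc", rigid, solvent, b_range, tol)
      if (is.na(res$beq)) {
        return(.new_equilibrium_result("cc", NA_real_, NA_real_, FALSE,
                                       NA_real_, chain, lB, kappa, b_range,
                                       iters,
                                       "self-consistent iteration lost the CC minimum"))
      }
      beq <- res$beq
      a_new <- a0 + ce * t * lB / beq
      if (abs(a_new - a_cur) < 1e-12 || iters >= 200L) break
      a_cur <- a_new
    }
    g_at <- g_cc(beq, a_cur, z, lB, kappa)
  }

  a_eff <- a0 + ce * t * lB / beq
  thr <- z * lB
  valid <- beq <= thr + 1e-8
  x <- lB / beq
  w <- validity_window()
  reason <- "converged"
  if (!valid) {
    reason <- sprintf("root b = %.6g nm above the condensation threshold z*lB = %.6g nm",
                      beq, thr)
  }
  if (x < w[1] || x > w[2]) {
    warning("solution lB/b = ", format(signif(x, 4)),
            " lies outside the condensed-layer validity window (",
            format(signif(w[1], 3)), ", ", format(signif(w[2], 3)), ")",
            call. = FALSE)
  }
  .new_equilibrium_result("cc", beq, g_at, valid, a_eff, chain, lB, kappa,
                          b_range, iters, reason)
}
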