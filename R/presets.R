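#' Standard figure presets
#'
#' Pre-packaged run configurations for the model's canonical sweeps.
#' Each preset fixes the parameters that define the corresponding
#' scenario; grids that are a matter of plotting resolution use sensible
#' defaults.
#'
#' \describe{
#'   \item{fig1}{equilibrium spacing vs spring constant on the
#'     condensed branch, lB = 1.7 nm (methanol), 1:1 salt at 0.01 M and
#'     0.001 M.}
#'   \item{fig2}{both branch equilibria vs Bjerrum length, a = 0.1
#'     nm^-2, 0.01 M 1:1 salt — the bistable transition range.}
#'   \item{fig3}{piecewise free-energy landscape at lB = 2.0 nm inside
#'     the transition range, same chain and salt as fig2.}
#'   \item{fig4}{transition regions for spring constants 5.0, 1.0 and
#'     0.1 nm^-2 (the funnel), 0.01 M 1:1 salt.}
#'   \item{fig5}{condensed-branch equilibrium spacing far into the
#'     strong-coupling regime, a = 0.1 nm^-2, 0.01 M 1:1 salt.}
#'   \item{fig6}{collapse curves for stiffening parameters t = 0, 4 and
#'     50 nm^-2, a0 = 0.1 nm^-2, 0.01 M 1:1 salt.}
#' }
#'
#' @param name one of `"fig1"` ... `"fig6"`.
#' @return a named list (class `figure_preset`) describing the run:
#'   `name`, `subcommand`, and the parameter set.
#' @seealso [run_preset()]
#' @export
figure_preset <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5",
                                   "fig6")) {
  name <- match.arg(name)
  p <- switch(name,
    fig1 = list(subcommand = "solve_sweep_a", branch = "cc",
                bjerrum = 1.7, z = 1L,
                salt_conc = c(0.01, 0.001),
                a_grid = exp(seq(log(0.05), log(5), length.out = 41))),
    fig2 = list(subcommand = "phase", a0 = 0.1, z = 1L, salt_conc = 0.01,
                lB_grid = seq(1.0, 3.5, by = 0.05)),
    fig3 = list(subcommand = "profile", a0 = 0.1, z = 1L, salt_conc = 0.01,
                bjerrum = 2.0,
                b_grid = seq(0.4, 5.0, by = 0.005)),
    fig4 = list(subcommand = "funnel", z = 1L, salt_conc = 0.01,
                a_grid = c(5.0, 1.0, 0.1)),
    fig5 = list(subcommand = "phase", a0 = 0.1, z = 1L, salt_conc = 0.01,
                lB_grid = seq(2.0, 40, by = 0.5)),
    fig6 = list(subcommand = "collapse", a0 = 0.1, z = 1L, salt_conc = 0.01,
                t_values = c(0, 4, 50),
                lB_grid = seq(1.1, 20, by = 0.25))
  )
  structure(c(list(name = name), p), class = "figure_preset")
}

#' Run a figure preset
#'
#' Executes the computation encoded by a [figure_preset()] and returns
#' its result table.
#'
#' @param name preset name, `"fig1"` ... `"fig6"`.
#' @param tol solver tolerance, nm.
#' @return a data frame (for `fig3`, the profile samples; minima and the
#'   junction maximum are attached as attributes `minima` / `maximum`).
#' @export
#' @examples
#' head(run_preset("fig2"))
run_preset <- function(name, tol = 1e-10) {
  p <- figure_preset(name)
  switch(p$subcommand,
    solve_sweep_a = {
      sol_by_salt <- lapply(p$salt_conc, function(cm)
        solvent_conditions(bjerrum = p$bjerrum, salt = salt_1_1(cm)))
      rows <- list()
      for (i in seq_along(p$salt_conc)) {
        for (a in p$a_grid) {
          res <- solve_branch(p$branch, chain_params(a0 = a, z = p$z),
                              sol_by_salt[[i]], tol = tol)
          rows[[length(rows) + 1L]] <-
            data.frame(a0 = a, salt_M = p$salt_conc[i], branch = p$branch,
                       beq = res$beq, valid = res$valid)
        }
      }
      do.call(rbind, rows)
    },
    phase = sweep_bjerrum(chain_params(a0 = p$a0, z = p$z),
                          salt_1_1(p$salt_conc), p$lB_grid, tol = tol),
    profile = {
      prof <- free_energy_profile(
        chain_params(a0 = p$a0, z = p$z),
        solvent_conditions(bjerrum = p$bjerrum, salt = salt_1_1(p$salt_conc)),
        p$b_grid)
      out <- prof$samples
      attr(out, "minima") <- prof$minima
      attr(out, "maximum") <- prof$maximum
      out
    },
    funnel = funnel_map(p$a_grid, salt_1_1(p$salt_conc), z = p$z),
    collapse = collapse_curve(p$a0, p$t_values, salt_1_1(p$salt_conc),
                              p$lB_grid, tol = tol, z = p$z)
  )
}
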