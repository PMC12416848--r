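#' Dynamical model parameters
#'
#' Parameters of the generalized Lotka-Volterra dynamics with Type II
#' functional responses and of the equilibration procedure.
#'
#' @param delta Cost per beneficial positive interaction (1/time); each link a
#'   species gains from (as consumer or mutualist) subtracts `delta` from its
#'   intrinsic growth rate.
#' @param h_m,h_p Saturation (handling/satiation) times of mutualistic and
#'   consumer intake.
#' @param x_ext Extinction threshold: species whose abundance falls below it
#'   are removed; new species are introduced at exactly this abundance.
#' @param eq_rel_tol Equilibrium criterion: integration stops once the
#'   relative change of every abundance across a check window is below this
#'   (default `1e-4`, i.e. 0.01\%).
#' @param t_check Length (time units) of one integration window between
#'   equilibrium/extinction checks.
#' @param t_max Cap on total integration time per equilibration; if reached
#'   without convergence the final state is used as-is with a warning flag.
#' @param rtol,atol Relative/absolute tolerances passed to the ODE solver.
#' @return A list of class `glv_params`.
#' @export
glv_params <- function(delta = 0.01, h_m = 0.1, h_p = 0.1, x_ext = 1e-6,
                       eq_rel_tol = 1e-4, t_check = 10, t_max = 1e5,
                       rtol = 1e-8, atol = 1e-12) {
  stopifnot(delta >= 0, h_m >= 0, h_p >= 0, x_ext > 0, x_ext < 1,
            eq_rel_tol > 0, t_check > 0, t_max >= t_check,
            rtol > 0, atol > 0)
  structure(list(delta = delta, h_m = h_m, h_p = h_p, x_ext = x_ext,
                 eq_rel_tol = eq_rel_tol, t_check = t_check, t_max = t_max,
                 rtol = rtol, atol = atol),
            class = "glv_params")
}

#' Right-hand side of the community dynamics
#'
#' Evaluates `dx/dt` for every species: logistic self-regulation, the
#' per-positive-interaction cost `delta * n+`, linear competition, Type II
#' saturated consumer gains and mutualistic gains, and resource losses
#' saturated by each consumer's total intake (the consumer's denominator, not
#' the resource's).
#'
#' @param community A `glv_community`.
#' @param params A [glv_params()] object.
#' @param x Abundance vector at which to evaluate (defaults to the
#'   community's current abundances).
#' @return Numeric vector of time-derivatives, named by species id.
#' @export
growth_rhs <- function(community, params = glv_params(), x = community$x) {
  S <- n_species(community)
  if (length(x) != S) stop("abundance vector length does not match community")
  if (any(x < 0)) stop("negative abundance passed to growth_rhs")
  net <- community$net
  if (any(!vapply(net, function(M) all(is.finite(M)), logical(1))))
    stop("non-finite interaction matrix entries")
  stats::setNames(x * percapita_growth(x, net, community$traits, params),
                  community$species_ids)
}

# vectorized per-capita growth rate g_i; shared by growth_rhs and the
# establishment test
percapita_growth <- function(x, net, traits, params) {
  A <- drop(net$pplus %*% x)
  M <- drop(net$m %*% x)
  Dp <- 1 + params$h_p * A
  Dm <- 1 + params$h_m * M
  npos <- rowSums(net$m > 0) + rowSums(net$pplus > 0)
  traits$r - params$delta * npos - traits$s * x -
    drop(net$c %*% x) - drop(net$pminus %*% (x / Dp)) +
    A / Dp + M / Dm
}

# stage community parameters into the compiled model
glv_stage_community <- function(community, params) {
  S <- n_species(community)
  net <- community$net
  .Call("glv_stage", as.integer(S),
        as.numeric(params$delta), as.numeric(params$h_p),
        as.numeric(params$h_m),
        as.numeric(community$traits$r), as.numeric(community$traits$s),
        as.numeric(positive_interaction_counts(net)),
        as.numeric(net$c), as.numeric(net$pplus),
        as.numeric(net$pminus), as.numeric(net$m),
        PACKAGE = "ecoassembly")
  invisible(NULL)
}

# integrate one window of t time units with the compiled RHS + Jacobian
integrate_window <- function(x, t, params) {
  out <- deSolve::ode(y = x, times = c(0, t), func = "glv_derivs",
                      parms = NULL, dllname = "ecoassembly",
                      jacfunc = "glv_jac", jactype = "fullusr",
                      method = "lsoda", rtol = params$rtol,
                      atol = params$atol, maxsteps = 50000)
  if (nrow(out) < 2 || any(!is.finite(out[nrow(out), -1])))
    stop("ODE integration failed (non-finite state or step-size collapse)")
  pmax(as.numeric(out[nrow(out), -1]), 0)
}

#' Integrate a community to its ecological equilibrium
#'
#' Integrates the dynamics forward in windows of `t_check` time units.  After
#' each window, species whose abundance fell below `x_ext` are removed (and
#' the matrices shrunk) before integration continues.  Equilibrium is declared
#' when the relative change of every abundance across one window is below
#' `eq_rel_tol`; integration gives up at `t_max` and returns the final state
#' unconverged.
#'
#' @param community A `glv_community` with all abundances at or above
#'   `x_ext`.
#' @param params A [glv_params()] object.
#' @param n_windows If not `NULL`, integrate exactly this many windows
#'   (no convergence test); used for fixed-interval assembly.
#' @return A list with elements `community`, `converged` (logical),
#'   `extinct_ids` (character) and `time` (total time integrated).
#' @export
equilibrate <- function(community, params = glv_params(), n_windows = NULL) {
  extinct <- character(0)
  t_total <- 0
  converged <- FALSE
  if (n_species(community) == 0)
    return(list(community = community, converged = TRUE,
                extinct_ids = extinct, time = 0))
  if (any(community$x < params$x_ext))
    stop("all abundances must start at or above x_ext")
  glv_stage_community(community, params)
  windows_left <- if (is.null(n_windows)) Inf else n_windows
  while (windows_left > 0) {
    x_old <- community$x
    x_new <- integrate_window(x_old, params$t_check, params)
    t_total <- t_total + params$t_check
    windows_left <- windows_left - 1
    dead <- x_new < params$x_ext
    if (any(dead)) {
      extinct <- c(extinct, community$species_ids[dead])
      community$x <- x_new
      community <- remove_species(community, community$species_ids[dead])
      if (n_species(community) == 0) { converged <- TRUE; break }
      glv_stage_community(community, params)
      next   # membership changed: no convergence test this window
    }
    community$x <- x_new
    if (is.null(n_windows) &&
        max(abs(x_new - x_old) / x_old) < params$eq_rel_tol) {
      converged <- TRUE
      break
    }
    if (is.null(n_windows) && t_total >= params$t_max) break
  }
  if (!is.null(n_windows)) converged <- NA
  list(community = community, converged = converged,
       extinct_ids = extinct, time = t_total)
}
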