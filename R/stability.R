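#' Community matrix (Jacobian) at a point
#'
#' Closed-form derivatives of the dynamics' right-hand side
#' `f_i = x_i g_i(x)`: `J[i, j] = d f_i / d x_j`.  The Type II terms
#' differentiate to `pplus[i, j] / Dp_i^2` (consumer gain),
#' `m[i, j] / Dm_i^2` (mutualistic gain), and the resource-loss term yields
#' both a direct `-pminus[i, j] / Dp_j` part and a relief part through the
#' consumers' saturating denominators.  The constant `delta` cost only enters
#' the diagonal through the `x_i` prefactor.
#'
#' @param community A `glv_community`.
#' @param params A [glv_params()] object.
#' @param x Point of linearization (defaults to the community's abundances,
#'   typically an equilibrium from [equilibrate()]).
#' @return An S x S real matrix.
#' @export
jacobian_at <- function(community, params = glv_params(), x = community$x) {
  S <- n_species(community)
  if (length(x) != S) stop("abundance vector length does not match community")
  net <- community$net
  tr <- community$traits
  A <- drop(net$pplus %*% x)
  M <- drop(net$m %*% x)
  Dp <- 1 + params$h_p * A
  Dm <- 1 + params$h_m * M
  g <- percapita_growth(x, net, tr, params)
  # dg_i/dx_j, assembled term by term
  v <- x * params$h_p / Dp^2
  dg <- -net$c -
    sweep(net$pminus, 2, Dp, "/") +
    net$pminus %*% (v * net$pplus) +
    net$pplus / Dp^2 +
    net$m / Dm^2
  diag(dg) <- diag(dg) - tr$s
  J <- x * dg
  diag(J) <- diag(J) + g
  J
}

# central finite-difference Jacobian; independent cross-check of jacobian_at
jacobian_fd <- function(community, params = glv_params(), x = community$x) {
  S <- n_species(community)
  f <- function(y) {
    co <- community; co$x <- y
    unname(growth_rhs(co, params, y))
  }
  J <- matrix(0, S, S)
  for (j in seq_len(S)) {
    h <- max(1e-7, 1e-4 * x[j])
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

#' Eigenspectrum of a community matrix
#'
#' All eigenvalues, with multiplicity, of a real square matrix; complex
#' eigenvalues come in conjugate pairs.
#'
#' @param J A real square matrix (typically from [jacobian_at()]).
#' @return A list of class `eigenspectrum` with `values` (complex vector)
#'   and `community_size`.
#' @export
eigenspectrum <- function(J) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square")
  if (any(!is.finite(J))) stop("J contains non-finite entries")
  structure(list(values = as.complex(eigen(J, only.values = TRUE)$values),
                 community_size = nrow(J)),
            class = "eigenspectrum")
}

#' Linear stability of an equilibrium
#'
#' An equilibrium is linearly stable when every eigenvalue of the community
#' matrix has a negative real part; the tolerance absorbs numerically-zero
#' modes.
#'
#' @param spectrum An [eigenspectrum()] object.
#' @param tol Stability tolerance on the leading real part (default `1e-8`).
#' @return Logical flag.
#' @export
is_linearly_stable <- function(spectrum, tol = 1e-8) {
  stopifnot(inherits(spectrum, "eigenspectrum"),
            length(spectrum$values) > 0)
  max(Re(spectrum$values)) < tol
}

#' Tidy an eigenspectrum into (re, im) rows
#' @param x An [eigenspectrum()] object.
#' @param ... Unused.
#' @return A tibble with columns `re` and `im`, one row per eigenvalue.
#' @export
tidy.eigenspectrum <- function(x, ...) {
  tibble::tibble(re = Re(x$values), im = Im(x$values))
}

#' @export
print.eigenspectrum <- function(x, ...) {
  cat(sprintf("<eigenspectrum> S = %d, max Re(lambda) = %.4g\n",
              x$community_size, max(Re(x$values))))
  invisible(x)
}

#' Plot an eigenspectrum on the complex plane
#' @param object An [eigenspectrum()] object.
#' @param ... Unused.
#' @return A ggplot: eigenvalues as points in the (Re, Im) plane with the
#'   stability boundary at zero.
#' @export
autoplot.eigenspectrum <- function(object, ...) {
  df <- tidy.eigenspectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Re(λ)", y = "Im(λ)") +
    ggplot2::theme_minimal()
}
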