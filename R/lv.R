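#' Lotka-Volterra competition derivatives
#'
#' The right-hand side of the shared-sum competition system: species i obeys
#' `dN_i/dt = r_i * N_i * (1 - sum_j(N_j) / K_i)`.  Every bracket contains
#' the summed density of all competitors, i.e. all pairwise competition
#' coefficients equal 1.
#'
#' @param densities Non-negative densities `N_i`.
#' @param rates Intrinsic growth rates `r_i` (may be negative above a
#'   species' critical maximum).
#' @param capacities Carrying capacities `K_i` (> 0).
#' @return Numeric vector of time-derivatives, same length as `densities`.
#' @export
#' @examples
#' lv_derivatives(c(0.2, 0.2, 0.2), c(0.5, 0.3, 0.1), c(1, 1, 1))
lv_derivatives <- function(densities, rates, capacities) {
  n <- length(densities)
  if (length(rates) != n || length(capacities) != n) {
    stop("densities, rates and capacities must have equal length", call. = FALSE)
  }
  stopifnot(all(capacities > 0))
  rates * densities * (1 - sum(densities) / capacities)
}

#' Integration settings for steady-state runs
#'
#' @param deriv_tol Convergence tolerance on `max |dN_i/dt|`
#'   (density per unit time); integration stops once every derivative is
#'   below it.  The equal-capacity system relaxes onto a neutrally stable
#'   manifold, so a derivative criterion (not a state-difference one) is used.
#' @param horizon Maximum integration time (time units).
#' @param extinction_tol Densities below `extinction_tol * mean(K)` at
#'   termination are reported as exactly 0.
#' @param rtol,atol Relative/absolute integrator tolerances passed to
#'   [deSolve::lsodar()] (stiff-capable, automatic method switching).
#' @return A list of class `steady_control`.
#' @export
steady_control <- function(deriv_tol = 1e-9, horizon = 1e4,
                           extinction_tol = 1e-9, rtol = 1e-8, atol = 1e-12) {
  stopifnot(deriv_tol > 0, horizon > 0, extinction_tol >= 0,
            rtol > 0, atol > 0)
  structure(
    list(deriv_tol = deriv_tol, horizon = horizon,
         extinction_tol = extinction_tol, rtol = rtol, atol = atol),
    class = "steady_control"
  )
}

# shared deSolve plumbing -----------------------------------------------------

lv_rhs <- function(t, y, p) {
  list(p$rates * y * (1 - sum(y) / p$k))
}

lv_integrate <- function(y0, rates, k, times, control, root = TRUE) {
  parms <- list(rates = rates, k = k)
  rootfun <- if (root) {
    function(t, y, p) max(abs(p$rates * y * (1 - sum(y) / p$k))) - control$deriv_tol
  } else NULL
  out <- deSolve::lsodar(
    y = y0, times = times, func = lv_rhs, parms = parms,
    rootfunc = rootfun, rtol = control$rtol, atol = control$atol
  )
  if (anyNA(out) || any(!is.finite(out))) {
    bad <- which(apply(out, 1L, function(r) any(!is.finite(r))))[1]
    stop("integration produced a non-finite state at t = ", out[bad, 1],
         " (state: ", paste(signif(out[bad, -1], 6), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

#' Integrate a community to steady state at one temperature
#'
#' Evaluates each species' growth rate at the environmental temperature,
#' integrates the shared-sum Lotka-Volterra system from the community's
#' initial densities, and stops when every derivative magnitude falls below
#' `control$deriv_tol` (or at the horizon, flagged unconverged).  Densities
#' below the extinction threshold are reported as exactly 0.
#'
#' @param community A community data frame (see [community()]).
#' @param temp Environmental temperature, degrees Celsius.
#' @param control A [steady_control()] list.
#' @return An object of class `lv_steady`; use [tidy()] for per-species
#'   densities and [glance()] for convergence diagnostics.
#' @export
#' @examples
#' st <- steady_state(default_community(), temp = 37)
#' tidy(st)
#' glance(st)
steady_state <- function(community, temp, control = steady_control()) {
  community <- as_community(community)
  stopifnot(is.numeric(temp), length(temp) == 1L, is.finite(temp))
  rates <- growth_rate(community, temp)$rate
  k <- community$k
  y0 <- community$n0
  names(y0) <- community$species_id

  out <- lv_integrate(y0, rates, k, c(0, control$horizon), control)
  final <- out[nrow(out), , drop = TRUE]
  t_final <- final[[1]]
  dens <- pmax(as.numeric(final[-1]), 0)
  dens[dens < control$extinction_tol * mean(k)] <- 0
  max_deriv <- max(abs(lv_derivatives(dens, rates, k)))
  converged <- !is.null(attr(out, "troot")) || max_deriv < control$deriv_tol
  if (converged) {
    # a converged species whose per-capita growth r_i (1 - S/K_i) is still
    # strictly negative is decaying exponentially toward 0: its steady state
    # is exact extinction, even though the derivative criterion halts the
    # integrator at a tiny positive density.  Species frozen on the shared
    # capacity manifold (bracket ~ 0) are untouched.
    per_capita <- rates * (1 - sum(dens) / k)
    dens[per_capita < -1000 * control$deriv_tol] <- 0
  }

  total <- sum(dens)
  structure(
    list(
      densities = tibble::tibble(
        species_id = community$species_id,
        density = dens,
        relative_density = if (total > 0) dens / total else rep(0, length(dens)),
        rate = rates
      ),
      temperature = temp,
      converged = converged,
      t_final = t_final,
      max_abs_derivative = max_deriv,
      community = community,
      control = control
    ),
    class = "lv_steady"
  )
}

#' Time course of a community at one temperature
#'
#' Full trajectory at requested output times (no early stopping), mainly for
#' diagnostics and for checking against closed-form solutions.
#'
#' @inheritParams steady_state
#' @param times Strictly increasing output times starting at 0.
#' @return Tibble `time`, `species_id`, `density`.
#' @export
lv_trajectory <- function(community, temp, times, control = steady_control()) {
  community <- as_community(community)
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  rates <- growth_rate(community, temp)$rate
  y0 <- community$n0
  names(y0) <- community$species_id
  out <- lv_integrate(y0, rates, community$k, times, control, root = FALSE)
  tibble::as_tibble(as.data.frame(out)) |>
    tidyr::pivot_longer(-"time", names_to = "species_id",
                        values_to = "density")
}

#' @export
print.lv_steady <- function(x, ...) {
  cat("<lv_steady> ", nrow(x$densities), " species at ", x$temperature,
      " degC; ", if (x$converged) "converged" else "NOT converged",
      " at t = ", format(x$t_final), " (max |dN/dt| = ",
      format(x$max_abs_derivative, digits = 3), ")\n", sep = "")
  print(x$densities)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.lv_steady <- function(x, ...) {
  dplyr::mutate(x$densities, extinct = .data$density == 0)
}

#' @importFrom generics glance
#' @export
glance.lv_steady <- function(x, ...) {
  tibble::tibble(
    temperature = x$temperature,
    n_species = nrow(x$densities),
    n_extinct = sum(x$densities$density == 0),
    total_density = sum(x$densities$density),
    converged = x$converged,
    t_final = x$t_final,
    max_abs_derivative = x$max_abs_derivative
  )
}

#' Identify the dominant species of a steady state
#'
#' @param state An `lv_steady` object, or a numeric vector of densities
#'   named by species.
#' @param tie_tol Relative tolerance: if the top two densities are within
#'   `tie_tol` of each other the outcome is reported as `"tie"` rather than
#'   silently broken.
#' @return A single string: the dominant species id, `"tie"`, or `"none"`
#'   when every species is extinct.
#' @export
#' @examples
#' dominant_species(c(S1 = 0.5, S2 = 0.3, S3 = 0.2))
#' dominant_species(c(S1 = 0.4, S2 = 0.4))
dominant_species <- function(state, tie_tol = 1e-6) {
  dens <- if (inherits(state, "lv_steady")) {
    stats::setNames(state$densities$density, state$densities$species_id)
  } else {
    stopifnot(is.numeric(state), !is.null(names(state)))
    state
  }
  if (all(dens <= 0)) return("none")
  ord <- order(dens, decreasing = TRUE)
  top <- dens[ord[1]]
  if (length(dens) > 1L && dens[ord[2]] >= top * (1 - tie_tol)) return("tie")
  names(dens)[ord[1]]
}

#' @export
autoplot.lv_steady <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$species_id, y = .data$density,
                               fill = .data$species_id)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "steady-state density",
      title = paste0("Steady state at ", object$temperature, " °C")
    ) +
    ggplot2::theme_minimal()
}
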