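#' Sweep the competition model across an environmental temperature range
#'
#' Integrates the community to steady state independently at every grid
#' temperature (each point is a cold start from the community's initial
#' densities; no thermal history carries over) and annotates each point with
#' the dominant species.
#'
#' @param community A community data frame (see [community()]).
#' @param t_start,t_end Sweep bounds, degrees Celsius (defaults 25 and 45).
#' @param step Grid spacing, degrees Celsius (default 0.1).
#' @param control A [steady_control()] list.
#' @param tie_tol Relative tolerance for reporting dominance ties.
#' @return An object of class `lv_sweep`.  [tidy()] returns the long table
#'   (`temperature`, `species_id`, `density`, `relative_density`, `rate`,
#'   `dominant_flag`, `converged`); [glance()] a one-row summary;
#'   [autoplot()] the density-versus-temperature figure.
#' @export
#' @examples
#' sw <- run_temperature_sweep(default_community(), step = 1)
#' dominance_intervals(sw)
run_temperature_sweep <- function(community, t_start = 25, t_end = 45,
                                  step = 0.1, control = steady_control(),
                                  tie_tol = 1e-6) {
  community <- as_community(community)
  grid <- temperature_grid(t_start, t_end, step)

  states <- purrr::map(grid, function(temp) {
    tryCatch(
      steady_state(community, temp, control),
      error = function(e) {
        stop("temperature sweep failed at T = ", temp, " degC: ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })

  dominance <- tibble::tibble(
    temperature = grid,
    dominant = purrr::map_chr(states, dominant_species, tie_tol = tie_tol)
  )
  results <- purrr::map2(states, grid, function(st, temp) {
    dplyr::mutate(st$densities, temperature = temp, converged = st$converged,
                  .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(dominance, by = "temperature") |>
    dplyr::mutate(dominant_flag = .data$species_id == .data$dominant) |>
    dplyr::select("temperature", "species_id", "density", "relative_density",
                  "rate", "dominant_flag", "converged")

  structure(
    list(results = results, dominance = dominance, grid = grid,
         community = community, control = control, tie_tol = tie_tol,
         step = step),
    class = "lv_sweep"
  )
}

#' @export
print.lv_sweep <- function(x, ...) {
  cat("<lv_sweep> ", nrow(x$community), " species over ",
      length(x$grid), " temperatures (", min(x$grid), "-", max(x$grid),
      " degC, step ", x$step, ")\n", sep = "")
  print(dominance_intervals(x))
  invisible(x)
}

#' @export
tidy.lv_sweep <- function(x, ...) x$results

#' @export
glance.lv_sweep <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$community),
    n_temperatures = length(x$grid),
    t_start = min(x$grid),
    t_end = max(x$grid),
    step = x$step,
    n_unconverged = sum(!dplyr::distinct(
      x$results, .data$temperature, .data$converged)$converged),
    n_ties = sum(x$dominance$dominant == "tie"),
    n_all_extinct = sum(x$dominance$dominant == "none"),
    monotone_handover = monotone_handover(x),
    intermediate_persists = intermediate_persistence(x)
  )
}

#' Contiguous temperature intervals of dominance
#'
#' Run-length encodes the per-temperature dominant species into maximal
#' closed intervals, ordered by temperature.  Grid points with a tie or with
#' no survivor break runs and are not reported as intervals.
#'
#' @param sweep An `lv_sweep` object.
#' @return Tibble `species_id`, `t_lo`, `t_hi`, `n_points`.
#' @export
dominance_intervals <- function(sweep) {
  stopifnot(inherits(sweep, "lv_sweep"))
  dom <- sweep$dominance
  runs <- rle(dom$dominant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !(runs$values %in% c("tie", "none"))
  tibble::tibble(
    species_id = runs$values[keep],
    t_lo = dom$temperature[starts[keep]],
    t_hi = dom$temperature[ends[keep]],
    n_points = runs$lengths[keep]
  )
}

#' Is the dominance hand-over monotone in thermal optimum?
#'
#' TRUE when, scanning the grid from cold to hot and skipping ties and
#' all-extinct points, the dominant species' `t_opt` never decreases — the
#' signature pattern in which dominance hands over from low-optimum to
#' high-optimum competitors as the environment warms.
#'
#' @param sweep An `lv_sweep` object.
#' @return Logical scalar.
#' @export
monotone_handover <- function(sweep) {
  stopifnot(inherits(sweep, "lv_sweep"))
  dom <- sweep$dominance$dominant
  dom <- dom[!(dom %in% c("tie", "none"))]
  if (length(dom) == 0L) return(TRUE)
  t_opt <- sweep$community$t_opt[match(dom, sweep$community$species_id)]
  !is.unsorted(t_opt)
}

#' Does the intermediate-optimum species persist where it can grow?
#'
#' For communities of three or more species, checks that every species with
#' an intermediate thermal optimum (neither the lowest nor the highest
#' `t_opt`) holds more than `share_min` of total density at every grid point
#' where its own growth rate is positive.  Vacuously TRUE for two-species
#' communities.
#'
#' @param sweep An `lv_sweep` object.
#' @param share_min Minimum relative density (default 0.01, i.e. 1 percent).
#' @return Logical scalar.
#' @export
intermediate_persistence <- function(sweep, share_min = 0.01) {
  stopifnot(inherits(sweep, "lv_sweep"))
  comm <- sweep$community
  mid <- comm$species_id[comm$t_opt > min(comm$t_opt) &
                           comm$t_opt < max(comm$t_opt)]
  if (length(mid) == 0L) return(TRUE)
  rel <- dplyr::filter(sweep$results, .data$species_id %in% mid,
                       .data$rate > 0)
  all(rel$relative_density > share_min)
}

#' @export
autoplot.lv_sweep <- function(object, relative = TRUE, ...) {
  dat <- tidy(object)
  y <- if (relative) "relative_density" else "density"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$temperature, y = .data[[y]],
                                    colour = .data$species_id)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "environmental temperature (°C)",
      y = if (relative) "relative steady-state density" else
        "steady-state density",
      colour = "species",
      title = "Steady-state outcome across the temperature sweep"
    ) +
    ggplot2::theme_minimal()
}

#' Write a sweep as a tidy TSV
#'
#' One observation per row: `scenario_id`, `temperature`, `species_id`,
#' `density`, `relative_density`, `dominant_flag`, `converged`.
#'
#' @param sweep An `lv_sweep` object.
#' @param path Output file path.
#' @param scenario_id Label recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path, scenario_id = "default") {
  stopifnot(inherits(sweep, "lv_sweep"))
  out <- dplyr::mutate(tidy(sweep), scenario_id = scenario_id, .before = 1) |>
    dplyr::select("scenario_id", "temperature", "species_id", "density",
                  "relative_density", "dominant_flag", "converged")
  readr::write_tsv(out, path)
  invisible(path)
}
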