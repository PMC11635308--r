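#' Define a competing community
#'
#' A community is an ordinary tibble with one row per species, carrying the
#' thermal-performance-curve parameters alongside the Lotka-Volterra
#' demographic parameters.  Columns: `species_id`, `t_min`, `t_opt`, `t_max`
#' (degrees Celsius), `r_peak` (per unit time), `death_slope` (per unit time
#' per degree), `form` (registered curve form), `k` (carrying capacity,
#' density units), `n0` (initial density).
#'
#' @param species_id Character vector of unique species labels.
#' @param t_min,t_opt,t_max Cardinal temperatures per species, with
#'   `t_min < t_opt < t_max`.
#' @param r_peak Peak growth rate per species (default 1).
#' @param death_slope Slope of net decline above `t_max` (default 0.1 per
#'   degree per unit time; 0 disables death).
#' @param form Curve form name(s), see [tpc_forms()].
#' @param k Carrying capacities (> 0, default 1).
#' @param n0 Initial densities (>= 0, at least one positive).  Default is
#'   1 percent of the mean carrying capacity for every species, placing all
#'   competitors on an equal footing.
#' @return A validated community tibble.
#' @export
#' @examples
#' community(c("A", "B"), t_min = 0, t_opt = c(30, 35), t_max = c(36, 40))
community <- function(species_id, t_min, t_opt, t_max, r_peak = 1,
                      death_slope = 0.1, form = "beta", k = 1, n0 = NULL) {
  n <- length(species_id)
  if (is.null(n0)) n0 <- 0.01 * mean(rep_len(k, n))
  out <- tibble::tibble(
    species_id = as.character(species_id),
    t_min = rep_len(as.numeric(t_min), n),
    t_opt = rep_len(as.numeric(t_opt), n),
    t_max = rep_len(as.numeric(t_max), n),
    r_peak = rep_len(as.numeric(r_peak), n),
    death_slope = rep_len(as.numeric(death_slope), n),
    form = rep_len(as.character(form), n),
    k = rep_len(as.numeric(k), n),
    n0 = rep_len(as.numeric(n0), n)
  )
  as_community(out)
}

#' Validate a data frame as a community
#'
#' Checks the column set, the cardinal-temperature ordering of every species,
#' positivity of capacities and peak rates, and that at least one species
#' starts at positive density.
#'
#' @param x A data frame with the columns documented in [community()].
#' @return The validated community as a tibble.
#' @export
as_community <- function(x) {
  needed <- c("species_id", "t_min", "t_opt", "t_max", "r_peak",
              "death_slope", "form", "k", "n0")
  if (!is.data.frame(x)) stop("community must be a data frame", call. = FALSE)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("community is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[needed]
  if (nrow(x) < 1L) stop("community must contain at least one species", call. = FALSE)
  if (anyDuplicated(x$species_id)) {
    stop("species_id values must be unique", call. = FALSE)
  }
  validate_tpc_params(x$t_min, x$t_opt, x$t_max, x$r_peak, x$death_slope,
                      where = "community")
  for (f in unique(x$form)) tpc_form_fn(f)
  if (any(!(x$k > 0))) stop("carrying capacities k must be > 0", call. = FALSE)
  if (any(x$n0 < 0)) stop("initial densities n0 must be >= 0", call. = FALSE)
  if (!any(x$n0 > 0)) stop("at least one initial density must be > 0", call. = FALSE)
  x
}

#' The default three-species community
#'
#' Three competitors sharing `t_min` = 0 degrees Celsius with staggered
#' optima bracketing 37 degrees Celsius, the long-term mean maximum ocean
#' temperature used as the reference environmental ceiling: S3 (t_opt 32,
#' t_max 37), S1 (t_opt 37, t_max 41), S2 (t_opt 42, t_max 46).  All curves
#' are right-skewed (skewness ratio well below 1), peak growth is normalized
#' to 1 per unit time, net decline above t_max is 0.1 per degree, carrying
#' capacities are equal at 1, and every species starts at 1 percent of
#' capacity.
#'
#' @param death_slope Decline slope above `t_max`; set 0 to clamp hot-side
#'   rates at zero instead of going negative.
#' @return A community tibble ordered by increasing `t_opt` (S3, S1, S2).
#' @export
#' @examples
#' default_community()
default_community <- function(death_slope = 0.1) {
  community(
    species_id = c("S3", "S1", "S2"),
    t_min = 0,
    t_opt = c(32, 37, 42),
    t_max = c(37, 41, 46),
    r_peak = 1,
    death_slope = death_slope,
    form = "beta",
    k = 1,
    n0 = 0.01
  )
}

# strictly increasing temperature grid; grid arithmetic done on integers to
# keep 0.1-degree steps exact
temperature_grid <- function(t_start, t_end, step) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(step),
            step > 0)
  if (!(t_start < t_end)) {
    stop("t_start must be < t_end (got ", t_start, " >= ", t_end, ")",
         call. = FALSE)
  }
  n_steps <- floor((t_end - t_start) / step + 1e-9)
  t_start + step * (0:n_steps)
}
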