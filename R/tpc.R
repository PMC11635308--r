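# Registry of thermal-performance-curve (TPC) functional forms.  A form maps a
# temperature inside (t_min, t_max) to a unit-peak shape: value 1 at t_opt,
# 0 at both t_min and t_max, unimodal in between.  The full rate is
# r_peak * shape inside the thermal window, 0 at or below t_min, 0 at t_max,
# and -death_slope * (T - t_max) above t_max (net decline past the critical
# maximum, disabled when death_slope = 0).
.tpc_forms <- new.env(parent = emptyenv())

#' Register a thermal performance curve functional form
#'
#' A form function receives vectors `temp`, `t_min`, `t_opt`, `t_max`
#' (recycled to common length, with `t_min < temp < t_max` guaranteed) and
#' must return the unit-peak shape: 1 at `t_opt`, 0 at the endpoints, and
#' unimodal with its unique maximum at `t_opt`.
#'
#' @param name Single string naming the form.
#' @param fn Shape function `function(temp, t_min, t_opt, t_max)`.
#' @return `name`, invisibly.
#' @export
#' @examples
#' register_tpc_form("beta_sq", function(temp, t_min, t_opt, t_max) {
#'   q <- (t_opt - t_min) / (t_max - t_opt)
#'   (((t_max - temp) / (t_max - t_opt)) * ((temp - t_min) / (t_opt - t_min))^q)^2
#' })
register_tpc_form <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .tpc_forms)
  invisible(name)
}

#' List registered thermal performance curve forms
#' @return Character vector of form names.
#' @export
tpc_forms <- function() sort(ls(.tpc_forms))

tpc_form_fn <- function(form) {
  if (!is.character(form) || length(form) != 1L || !exists(form, envir = .tpc_forms)) {
    stop("unknown TPC form '", form, "'; registered forms: ",
         paste(tpc_forms(), collapse = ", "), call. = FALSE)
  }
  get(form, envir = .tpc_forms)
}

# Yan-Hunt beta form: skewness is controlled purely by the spacing of the
# three cardinal temperatures; exact maximum r_peak at t_opt, exact zeros at
# t_min and t_max.
tpc_shape_beta <- function(temp, t_min, t_opt, t_max) {
  q <- (t_opt - t_min) / (t_max - t_opt)
  ((t_max - temp) / (t_max - t_opt)) * ((temp - t_min) / (t_opt - t_min))^q
}

validate_tpc_params <- function(t_min, t_opt, t_max, r_peak, death_slope,
                                where = "tpc") {
  bad <- which(!(t_min < t_opt))
  if (length(bad)) {
    stop(where, ": t_min < t_opt violated (t_min = ", t_min[bad[1]],
         ", t_opt = ", t_opt[bad[1]], ")", call. = FALSE)
  }
  bad <- which(!(t_opt < t_max))
  if (length(bad)) {
    stop(where, ": t_opt < t_max violated (t_opt = ", t_opt[bad[1]],
         ", t_max = ", t_max[bad[1]], ")", call. = FALSE)
  }
  if (any(!(r_peak > 0))) stop(where, ": r_peak must be > 0", call. = FALSE)
  if (any(death_slope < 0)) stop(where, ": death_slope must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate a thermal performance curve
#'
#' Vectorised core mapping temperature to intrinsic growth rate.  The rate is
#' 0 at or below `t_min` (cold growth shuts down but does not kill), follows
#' the registered unimodal form on `(t_min, t_max)` with maximum `r_peak` at
#' `t_opt`, is exactly 0 at `t_max`, and declines linearly at `-death_slope`
#' per degree above `t_max` (net mortality near the critical maximum;
#' `death_slope = 0` clamps the hot side at 0 instead).
#'
#' @param temp Temperature(s), degrees Celsius. Must be finite.
#' @param t_min,t_opt,t_max Cardinal temperatures, degrees Celsius, with
#'   `t_min < t_opt < t_max`.
#' @param r_peak Maximum growth rate (per unit time), attained at `t_opt`.
#' @param death_slope Magnitude of the negative slope above `t_max`
#'   (rate per unit time per degree); 0 disables death.
#' @param form Name of a registered functional form (see [tpc_forms()]).
#' @return Numeric vector of growth rates, per unit time.
#' @export
#' @examples
#' tpc_rate(20, t_min = 0, t_opt = 30, t_max = 40) # 2 * (2/3)^3
#' tpc_rate(45, t_min = 0, t_opt = 37, t_max = 40, death_slope = 0.1) # -0.5
tpc_rate <- function(temp, t_min, t_opt, t_max, r_peak = 1, death_slope = 0,
                     form = "beta") {
  stopifnot(all(is.finite(temp)))
  validate_tpc_params(t_min, t_opt, t_max, r_peak, death_slope)
  fn <- tpc_form_fn(form)
  n <- max(length(temp), length(t_min), length(t_opt), length(t_max),
           length(r_peak), length(death_slope))
  temp <- rep_len(temp, n); t_min <- rep_len(t_min, n)
  t_opt <- rep_len(t_opt, n); t_max <- rep_len(t_max, n)
  r_peak <- rep_len(r_peak, n); death_slope <- rep_len(death_slope, n)

  out <- numeric(n)
  inside <- temp > t_min & temp < t_max
  if (any(inside)) {
    out[inside] <- r_peak[inside] *
      fn(temp[inside], t_min[inside], t_opt[inside], t_max[inside])
  }
  hot <- temp > t_max
  out[hot] <- -death_slope[hot] * (temp[hot] - t_max[hot])
  out
}

#' Growth rates of a community across temperatures
#'
#' Data-frame-first wrapper around [tpc_rate()]: evaluates every species'
#' curve at every requested temperature.
#'
#' @param community A community data frame (see [community()]).
#' @param temp Numeric vector of temperatures, degrees Celsius.
#' @return A tibble with columns `species_id`, `temperature`, `rate`, one row
#'   per species x temperature.
#' @export
#' @examples
#' growth_rate(default_community(), c(30, 37, 44))
growth_rate <- function(community, temp) {
  community <- as_community(community)
  purrr::pmap(community, function(species_id, t_min, t_opt, t_max, r_peak,
                                  death_slope, form, ...) {
    tibble::tibble(
      species_id = species_id, temperature = temp,
      rate = tpc_rate(temp, t_min, t_opt, t_max, r_peak, death_slope, form)
    )
  }) |>
    purrr::list_rbind()
}

#' Normalize curves to a common maximum growth rate
#'
#' Rescales each species' `r_peak` so every curve attains the same maximum
#' `r_common`, leaving the cardinal temperatures (and hence the skewness)
#' untouched.  Registered forms peak exactly at `t_opt`, so the rescale uses
#' the rate there.
#'
#' @param community A community data frame.
#' @param r_common Common peak growth rate, per unit time (> 0).
#' @return The community tibble with adjusted `r_peak`.
#' @export
normalize_curves <- function(community, r_common = 1) {
  community <- as_community(community)
  if (nrow(community) == 0L) stop("normalize_curves: empty community", call. = FALSE)
  stopifnot(is.numeric(r_common), length(r_common) == 1L, r_common > 0)
  peak <- purrr::pmap_dbl(community, function(t_min, t_opt, t_max, r_peak,
                                              death_slope, form, ...) {
    tpc_rate(t_opt, t_min, t_opt, t_max, r_peak, death_slope, form)
  })
  dplyr::mutate(community, r_peak = .data$r_peak * r_common / peak)
}

#' Skewness of each species' thermal performance curve
#'
#' The asymmetry ratio `(t_max - t_opt) / (t_opt - t_min)`.  Values below 1
#' describe the typical right-skewed curve whose decline above the optimum is
#' steeper than its rise below it; 1 is symmetric spacing.
#'
#' @param community A community data frame.
#' @return A tibble with columns `species_id`, `skewness`.
#' @export
#' @examples
#' tpc_skewness(default_community())
tpc_skewness <- function(community) {
  community <- as_community(community)
  tibble::tibble(
    species_id = community$species_id,
    skewness = (community$t_max - community$t_opt) /
      (community$t_opt - community$t_min)
  )
}

#' Tabulate curves on a temperature grid for plotting or export
#'
#' @param community A community data frame.
#' @param t_start,t_end,step Temperature grid, degrees Celsius.
#' @return Tibble `species_id`, `temperature`, `rate` (same layout as
#'   [growth_rate()]), suitable for `readr::write_tsv()`.
#' @export
tpc_table <- function(community, t_start = 25, t_end = 45, step = 0.1) {
  growth_rate(community, temperature_grid(t_start, t_end, step))
}
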