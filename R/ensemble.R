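#' All pairwise two-species matchups of a community
#'
#' @param community A community data frame with at least two species.
#' @return Named list of two-species community tibbles (names like
#'   `"S1_vs_S2"`), preserving each species' curve, capacity and initial
#'   density; `choose(n, 2)` entries.
#' @export
#' @examples
#' length(pairwise_matchups(default_community())) # 3
pairwise_matchups <- function(community) {
  community <- as_community(community)
  n <- nrow(community)
  if (n < 2L) stop("pairwise matchups need at least two species", call. = FALSE)
  pairs <- utils::combn(seq_len(n), 2L, simplify = FALSE)
  out <- purrr::map(pairs, function(idx) community[idx, ])
  names(out) <- purrr::map_chr(pairs, function(idx) {
    paste(community$species_id[idx], collapse = "_vs_")
  })
  out
}

#' Specification of a robustness ensemble
#'
#' Declares the seeded random variations applied to a base community:
#' skewness of all curves, spacing between adjacent thermal optima, and
#' de-normalized peak rates, plus every pairwise species subset.  One axis is
#' varied at a time.
#'
#' @param base_community Community to perturb (default [default_community()]).
#' @param skew_range Interval of skewness ratios `(t_max - t_opt) /
#'   (t_opt - t_min)` drawn on the skewness and normalization axes
#'   (default `c(0.05, 0.8)`, the right-skewed regime).
#' @param spacing_range Interval (degrees Celsius) of gaps between adjacent
#'   thermal optima drawn on the spacing axis (default `c(2, 8)`).
#' @param r_peak_range Interval of raw peak rates drawn on the normalization
#'   axis before the normalize switch is applied (default `c(0.5, 1.5)`).
#' @param normalize Should curves on the skewness and spacing axes be
#'   rescaled to a common peak of 1 (default TRUE)?  On the normalization
#'   axis the flag alternates across draws so that on/off is contrasted.
#' @param axes Which variation axes to draw; any of `"skewness"`,
#'   `"spacing"`, `"normalization"`.
#' @param n_draws Draws per axis (>= 1).
#' @param include_pairwise Also include every pairwise matchup of the base
#'   community as scenarios.
#' @param spacing_scale `"linear"` draws spacing uniformly over
#'   `spacing_range`; `"log"` draws it log-uniformly, appropriate when the
#'   range spans orders of magnitude (e.g. probing near-degenerate spacings).
#' @param seed Integer seed; identical spec + seed reproduces the ensemble
#'   bit-for-bit.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(base_community = default_community(),
                          skew_range = c(0.05, 0.8),
                          spacing_range = c(2, 8),
                          r_peak_range = c(0.5, 1.5),
                          normalize = TRUE,
                          axes = c("skewness", "spacing", "normalization"),
                          n_draws = 10,
                          include_pairwise = TRUE,
                          spacing_scale = c("linear", "log"),
                          seed = 1L) {
  base_community <- as_community(base_community)
  axes <- match.arg(axes, c("skewness", "spacing", "normalization"),
                    several.ok = TRUE)
  spacing_scale <- match.arg(spacing_scale)
  check_range <- function(r, name, lo_ok) {
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2] || r[1] <= lo_ok) {
      stop(name, " must be a non-empty positive interval", call. = FALSE)
    }
  }
  check_range(skew_range, "skew_range", 0)
  check_range(spacing_range, "spacing_range", 0)
  check_range(r_peak_range, "r_peak_range", 0)
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("n_draws must be >= 1", call. = FALSE)
  }
  structure(
    list(base_community = base_community, skew_range = skew_range,
         spacing_range = spacing_range, r_peak_range = r_peak_range,
         normalize = normalize, axes = axes, n_draws = as.integer(n_draws),
         include_pairwise = include_pairwise, spacing_scale = spacing_scale,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# one-axis perturbations ------------------------------------------------------

# common skewness s: t_max moves to t_opt + s * (t_opt - t_min), optimum fixed
apply_skewness <- function(comm, s) {
  dplyr::mutate(comm, t_max = .data$t_opt + s * (.data$t_opt - .data$t_min))
}

# gap d between adjacent optima, centred on the base community's median
# optimum; each species keeps its own (t_max - t_opt) offset and t_min
apply_spacing <- function(comm, d) {
  ord <- rank(comm$t_opt, ties.method = "first")
  centre <- stats::median(comm$t_opt)
  new_opt <- centre + (ord - (nrow(comm) + 1) / 2) * d
  dplyr::mutate(comm,
                t_max = new_opt + (.data$t_max - .data$t_opt),
                t_opt = new_opt)
}

# independent per-species skewness and raw peak rates
apply_denormalized <- function(comm, s_each, r_each) {
  dplyr::mutate(comm,
                t_max = .data$t_opt + s_each * (.data$t_opt - .data$t_min),
                r_peak = r_each)
}

draw_unif <- function(n, range, log_scale = FALSE) {
  if (log_scale) exp(stats::runif(n, log(range[1]), log(range[2])))
  else stats::runif(n, range[1], range[2])
}

#' Generate the seeded scenario ensemble
#'
#' Draws `n_draws` perturbed communities per requested axis (one factor
#' varied at a time, uniform over the declared range) and appends the
#' pairwise matchups.  Draws whose parameters violate the cardinal-
#' temperature ordering are rejected and redrawn; rejections are recorded in
#' the `rejections` attribute.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with columns `scenario_id`, `axis`, `draw`, `value`
#'   (the drawn skewness/spacing, NA for pairwise), `normalize`, and a
#'   `community` list-column; attribute `rejections` counts redraws.
#' @export
#' @examples
#' scn <- generate_scenarios(scenario_spec(n_draws = 2))
#' scn$scenario_id
generate_scenarios <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- spec$base_community
  rejections <- 0L

  draw_valid <- function(make) {
    for (attempt in 1:100) {
      # invalid draws (cardinal-temperature ordering violations) are
      # rejected and redrawn
      cand <- tryCatch(make(), error = function(e) NULL)
      if (!is.null(cand)) {
        ok <- tryCatch({as_community(cand$community); TRUE},
                       error = function(e) FALSE)
        if (ok) return(cand)
      }
      rejections <<- rejections + 1L
    }
    stop("could not draw a valid scenario after 100 attempts", call. = FALSE)
  }

  rows <- withr::with_seed(spec$seed, {
    purrr::map(spec$axes, function(axis) {
      purrr::map(seq_len(spec$n_draws), function(i) {
        cand <- draw_valid(function() {
          switch(axis,
            skewness = {
              s <- draw_unif(1, spec$skew_range)
              comm <- apply_skewness(base, s)
              if (spec$normalize) comm <- normalize_curves(comm, 1)
              list(community = comm, value = s, normalize = spec$normalize)
            },
            spacing = {
              d <- draw_unif(1, spec$spacing_range,
                             spec$spacing_scale == "log")
              comm <- apply_spacing(base, d)
              if (spec$normalize) comm <- normalize_curves(comm, 1)
              list(community = comm, value = d, normalize = spec$normalize)
            },
            normalization = {
              s_each <- draw_unif(nrow(base), spec$skew_range)
              r_each <- draw_unif(nrow(base), spec$r_peak_range)
              norm <- i %% 2L == 1L  # alternate on/off across draws
              comm <- apply_denormalized(base, s_each, r_each)
              if (norm) comm <- normalize_curves(comm, 1)
              list(community = comm, value = mean(s_each), normalize = norm)
            }
          )
        })
        tibble::tibble(
          scenario_id = sprintf("%s_%02d%s", axis, i,
                                if (axis == "normalization" && cand$normalize)
                                  "_norm" else if (axis == "normalization")
                                  "_raw" else ""),
          axis = axis, draw = i, value = cand$value,
          normalize = cand$normalize, community = list(cand$community)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })

  if (spec$include_pairwise && nrow(base) >= 2L) {
    pw <- pairwise_matchups(base)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      scenario_id = paste0("pairwise_", names(pw)),
      axis = "pairwise", draw = seq_along(pw), value = NA_real_,
      normalize = spec$normalize, community = unname(pw)
    ))
  }
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("scenario spec produced no scenarios", call. = FALSE)
  }
  attr(rows, "rejections") <- rejections
  rows
}

#' Evaluate robustness of the dominance pattern across an ensemble
#'
#' Runs a full temperature sweep for every scenario and records, per
#' scenario, whether the monotone low-to-high-optimum dominance hand-over
#' holds, whether intermediate-optimum species persist above 1 percent
#' relative density wherever they can grow, whether any grid point was
#' tie-flagged, and whether all points converged.  Failed sweeps are caught
#' and counted, not fatal.
#'
#' @param scenarios Tibble from [generate_scenarios()] (columns
#'   `scenario_id` and `community` required).
#' @param t_start,t_end,step Sweep grid, degrees Celsius.
#' @param control A [steady_control()].
#' @param tie_tol Relative tolerance for dominance ties.
#' @param share_min Persistence threshold on relative density.
#' @return Object of class `robustness_summary`; [tidy()] gives per-scenario
#'   records, [glance()] the aggregate counts.
#' @export
evaluate_robustness <- function(scenarios, t_start = 25, t_end = 45,
                                step = 0.1, control = steady_control(),
                                tie_tol = 1e-6, share_min = 0.01) {
  if (!is.data.frame(scenarios) || nrow(scenarios) == 0L ||
      !all(c("scenario_id", "community") %in% names(scenarios))) {
    stop("scenarios must be a non-empty data frame with scenario_id and ",
         "community columns", call. = FALSE)
  }
  details <- vector("list", nrow(scenarios))
  records <- purrr::pmap(
    list(seq_len(nrow(scenarios)), scenarios$scenario_id,
         scenarios$community),
    function(row, id, comm) {
      res <- tryCatch(
        run_temperature_sweep(comm, t_start, t_end, step, control, tie_tol),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        return(tibble::tibble(
          scenario_id = id, failed = TRUE, monotone = NA,
          intermediate_persists = NA, any_tie = NA, all_converged = NA,
          n_ties = NA_integer_, message = conditionMessage(res)
        ))
      }
      details[[row]] <<- dplyr::mutate(tidy(res), scenario_id = id,
                                       .before = 1)
      g <- glance(res)
      tibble::tibble(
        scenario_id = id, failed = FALSE,
        monotone = monotone_handover(res),
        intermediate_persists = intermediate_persistence(res, share_min),
        any_tie = g$n_ties > 0L,
        all_converged = g$n_unconverged == 0L,
        n_ties = g$n_ties,
        message = NA_character_
      )
    }
  ) |> purrr::list_rbind()

  meta <- dplyr::select(scenarios, -"community")
  records <- dplyr::left_join(meta, records, by = "scenario_id")
  ok <- dplyr::filter(records, !.data$failed)
  structure(
    list(
      records = records,
      details = purrr::list_rbind(purrr::compact(details)),
      n_scenarios = nrow(records),
      n_failed = sum(records$failed),
      n_monotone = sum(ok$monotone),
      n_intermediate_persists = sum(ok$intermediate_persists),
      n_tied = sum(ok$any_tie),
      settings = list(t_start = t_start, t_end = t_end, step = step,
                      control = control, tie_tol = tie_tol,
                      share_min = share_min)
    ),
    class = "robustness_summary"
  )
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat("<robustness_summary> ", x$n_scenarios, " scenarios: ",
      x$n_monotone, " monotone hand-over, ", x$n_intermediate_persists,
      " intermediate persistence, ", x$n_tied, " with ties, ",
      x$n_failed, " failed\n", sep = "")
  invisible(x)
}

#' @export
tidy.robustness_summary <- function(x, ...) x$records

#' @export
glance.robustness_summary <- function(x, ...) {
  tibble::tibble(
    n_scenarios = x$n_scenarios,
    n_monotone = x$n_monotone,
    n_intermediate_persists = x$n_intermediate_persists,
    n_tied = x$n_tied,
    n_failed = x$n_failed
  )
}

#' @export
autoplot.robustness_summary <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::filter(!.data$failed) |>
    tidyr::pivot_longer(c("monotone", "intermediate_persists", "any_tie"),
                        names_to = "flag", values_to = "holds")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scenario_id, y = .data$flag,
                                    fill = .data$holds)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2b8cbe",
                                          `FALSE` = "#e34a33")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Robustness flags per scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write robustness results as TSVs
#'
#' @param summary A `robustness_summary`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_robustness_tsv <- function(summary, dir) {
  stopifnot(inherits(summary, "robustness_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "robustness_scenarios.tsv")
  p2 <- file.path(dir, "robustness_summary.tsv")
  readr::write_tsv(tidy(summary), p1)
  readr::write_tsv(glance(summary), p2)
  invisible(c(p1, p2))
}
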