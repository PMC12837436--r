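#' Linear trend of a group-mean volume trajectory
#'
#' Ordinary least-squares line and Pearson correlation for a set of
#' `(day, mean volume)` points, computed in closed form:
#' `slope = cov(day, volume) / var(day)`, `intercept = mean(volume) -
#' slope * mean(day)`, `r = cov / (sd_day * sd_volume)`. The published
#' trajectory analyses regress the per-day group means (four points per
#' group), so that is the default unit of analysis here; per-animal pooled
#' regression is available via [trend_by_group()].
#'
#' @param day numeric vector of postnatal days (or a 2-column matrix /
#'   data.frame of `(day, volume)` with `volume` omitted).
#' @param volume numeric vector of mean volumes (mL), same length.
#' @return A list of class `trend_result`: `slope` (mL/day), `intercept`
#'   (mL), `pearson_r` (`NA` with `constant_response = TRUE` when the
#'   response does not vary), `n_points`.
#' @export
trend_from_means <- function(day, volume = NULL) {
  if (is.null(volume)) {
    m <- as.data.frame(day)
    day <- m[[1]]; volume <- m[[2]]
  }
  stopifnot(length(day) == length(volume))
  if (length(day) < 2L || length(unique(day)) < 2L) {
    stop("trend requires at least two points with distinct days",
         call. = FALSE)
  }
  n <- length(day)
  sxx <- sum((day - mean(day))^2)
  sxy <- sum((day - mean(day)) * (volume - mean(volume)))
  syy <- sum((volume - mean(volume))^2)
  slope <- sxy / sxx
  intercept <- mean(volume) - slope * mean(day)
  constant <- syy == 0
  r <- if (constant) NA_real_ else sxy / sqrt(sxx * syy)
  if (constant) {
    warning("constant response: Pearson r undefined, slope 0", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 constant_response = constant, n_points = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("linear trend over %d points: slope %.4g mL/day, intercept %.4g mL, Pearson r %s\n",
              x$n_points, x$slope, x$intercept,
              if (is.na(x$pearson_r)) "undefined (constant response)"
              else sprintf("%.4f", x$pearson_r)))
  invisible(x)
}

#' Per-group trend analysis of a longitudinal volume table
#'
#' @param trajectories long table `(group, subject_id, day, volume_mL)` as
#'   from [build_trajectories()] or [make_cohort()].
#' @param unit `"group_means"` (default): regress the per-day group means, as
#'   in the trajectory figures; `"animals"`: pooled per-animal regression of
#'   all individual points.
#' @return Named list of `trend_result`, one per group.
#' @export
trend_by_group <- function(trajectories, unit = c("group_means", "animals")) {
  unit <- match.arg(unit)
  out <- lapply(split(trajectories, trajectories$group), function(g) {
    if (unit == "group_means") {
      m <- aggregate(volume_mL ~ day, data = g, FUN = mean)
      trend_from_means(m$day, m$volume_mL)
    } else {
      trend_from_means(g$day, g$volume_mL)
    }
  })
  out
}
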