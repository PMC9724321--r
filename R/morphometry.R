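#' Angular eccentricity of a prolate spheroid
#'
#' For equatorial (horizontal) semi-axis `a` and polar (vertical) semi-axis
#' `b` with `a <= b`, the angular eccentricity is `acos(a/b)`, in radians:
#' 0 for a sphere, approaching pi/2 as the spheroid becomes needle-like.
#'
#' @param a,b Semi-axes, um.
#' @param canonicalize If `TRUE` (default) the axes are sorted so `a <= b`
#'   before evaluation; if `FALSE`, `a > b` is a domain error.
#' @return Angular eccentricity in radians, in `[0, pi/2)`.
#' @export
angular_eccentricity <- function(a, b, canonicalize = TRUE) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("semi-axes must be positive", call. = FALSE)
  }
  if (canonicalize) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    a <- lo
    b <- hi
  } else if (any(a > b)) {
    stop("domain error: a > b gives acos argument > 1; ",
         "enable canonicalization or swap the axes", call. = FALSE)
  }
  acos(pmin(a / b, 1))
}

# alpha/sin(alpha) with its removable singularity at alpha = 0 taken as 1.
.alpha_over_sin <- function(alpha) {
  out <- rep(1, length(alpha))
  nz <- alpha >= 1e-8
  out[nz] <- alpha[nz] / sin(alpha[nz])
  out
}

#' Surface area of a prolate spheroid
#'
#' `2 * pi * (a^2 + a*b*alpha / sin(alpha))` with `alpha = acos(a/b)` the
#' angular eccentricity. The sphere limit (`a = b`, `alpha -> 0`) is handled
#' through the limit `alpha/sin(alpha) -> 1`, giving `4*pi*a^2`.
#'
#' @inheritParams angular_eccentricity
#' @return Surface area, um^2.
#' @examples
#' spheroid_surface_area(1, 1)  # 4*pi
#' spheroid_surface_area(1, 2)
#' @export
spheroid_surface_area <- function(a, b, canonicalize = TRUE) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("semi-axes must be positive", call. = FALSE)
  }
  if (canonicalize) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    a <- lo
    b <- hi
  }
  alpha <- angular_eccentricity(a, b, canonicalize = FALSE)
  2 * pi * (a^2 + a * b * .alpha_over_sin(alpha))
}

#' Volume of a prolate spheroid
#'
#' The default (`mode = "ab2"`) evaluates `(4/3) * pi * a * b^2`, with `a` the
#' horizontal and `b` the vertical semi-axis. The textbook prolate volume is
#' `(4/3) * pi * a^2 * b` (two equatorial axes, one polar); it is available as
#' `mode = "a2b"`. Both agree for spheres; for elongated cells `"ab2"`
#' overstates the volume by a factor `b/a`. The default is kept for
#' comparability with analyses that used the `a*b^2` form.
#'
#' @inheritParams angular_eccentricity
#' @param mode `"ab2"` (default) or `"a2b"`.
#' @return Volume, um^3.
#' @examples
#' spheroid_volume(1, 1)            # 4*pi/3, both modes
#' spheroid_volume(1, 2)            # (4/3)*pi*4
#' spheroid_volume(1, 2, mode = "a2b")
#' @export
spheroid_volume <- function(a, b, mode = c("ab2", "a2b"), canonicalize = TRUE) {
  mode <- match.arg(mode)
  if (any(a <= 0) || any(b <= 0)) {
    stop("semi-axes must be positive", call. = FALSE)
  }
  if (canonicalize) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    a <- lo
    b <- hi
  }
  if (mode == "ab2") 4 / 3 * pi * a * b^2 else 4 / 3 * pi * a^2 * b
}

#' Percent volume change relative to a reference
#'
#' `(v - v_ref) / v_ref * 100`; positive for swelling, negative for shrinkage.
#'
#' @param v Volume under the condition of interest, um^3.
#' @param v_ref Reference volume, um^3; must be positive.
#' @return Percent change.
#' @export
percent_volume_change <- function(v, v_ref) {
  if (any(v_ref <= 0)) stop("'v_ref' must be positive", call. = FALSE)
  (v - v_ref) / v_ref * 100
}

#' Per-cell shape metrics from axis measurements
#'
#' Converts a measurement-export table (full major/minor axis lengths, as a
#' line tool gives) into per-cell prolate-spheroid metrics: the axis lengths
#' are halved to semi-axes and sorted so the equatorial semi-axis `a` does not
#' exceed the polar semi-axis `b`, then angular eccentricity, surface area and
#' volume are computed per cell.
#'
#' @param measurements A data.frame with columns `cell_id`, `condition`,
#'   `major_axis_um`, `minor_axis_um`.
#' @param volume_mode Passed to [spheroid_volume()].
#' @return A data.frame with one row per cell: `cell_id`, `condition`, `a_um`,
#'   `b_um`, `alpha_ecc_rad`, `surface_area_um2`, `volume_um3`.
#' @export
cell_shape_metrics <- function(measurements, volume_mode = "ab2") {
  req <- c("cell_id", "condition", "major_axis_um", "minor_axis_um")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements))) {
    stop("'measurements' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  maj <- as.numeric(measurements$major_axis_um)
  min_ <- as.numeric(measurements$minor_axis_um)
  if (any(!is.finite(maj)) || any(!is.finite(min_)) ||
      any(maj <= 0) || any(min_ <= 0)) {
    stop("axis lengths must be finite and positive", call. = FALSE)
  }
  a <- pmin(maj, min_) / 2
  b <- pmax(maj, min_) / 2
  data.frame(
    cell_id = measurements$cell_id,
    condition = measurements$condition,
    a_um = a,
    b_um = b,
    alpha_ecc_rad = angular_eccentricity(a, b, canonicalize = FALSE),
    surface_area_um2 = spheroid_surface_area(a, b, canonicalize = FALSE),
    volume_um3 = spheroid_volume(a, b, mode = volume_mode, canonicalize = FALSE)
  )
}

#' Population summary of cell shape metrics, with volume changes
#'
#' Per-condition arithmetic mean, sample standard deviation (n - 1) and count
#' of cell volume and surface area. If a reference condition is named, the
#' percent change of each condition's mean volume relative to the reference
#' mean is reported.
#'
#' @param metrics Output of [cell_shape_metrics()].
#' @param reference Optional condition label to compare against.
#' @return A data.frame with one row per condition: `condition`, `n`,
#'   `mean_volume_um3`, `sd_volume_um3`, `mean_surface_area_um2`,
#'   `sd_surface_area_um2`, and (when `reference` is given)
#'   `volume_change_pct` versus the reference. SDs are `NA` for n = 1.
#' @export
summarize_population <- function(metrics, reference = NULL) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) {
    stop("insufficient data: 'metrics' is empty", call. = FALSE)
  }
  conds <- unique(as.character(metrics$condition))
  rows <- lapply(conds, function(cc) {
    v <- metrics$volume_um3[metrics$condition == cc]
    s <- metrics$surface_area_um2[metrics$condition == cc]
    data.frame(
      condition = cc, n = length(v),
      mean_volume_um3 = mean(v),
      sd_volume_um3 = if (length(v) > 1) stats::sd(v) else NA_real_,
      mean_surface_area_um2 = mean(s),
      sd_surface_area_um2 = if (length(s) > 1) stats::sd(s) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    if (!reference %in% out$condition) {
      stop(sprintf("reference condition '%s' not present", reference),
           call. = FALSE)
    }
    vref <- out$mean_volume_um3[out$condition == reference]
    out$volume_change_pct <- percent_volume_change(out$mean_volume_um3, vref)
  }
  rownames(out) <- NULL
  out
}
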