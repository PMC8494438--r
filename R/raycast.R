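#' Ray-cast visual occupancy of one eye pair
#'
#' Casts `n_rays` rays from each eye of a focal fish, each eye spanning
#' `span_deg` degrees from the direction of motion toward the back (leaving
#' 360 - 2 * span_deg of blind angle behind the fish; 30 degrees with the
#' defaults). Neighbours are rendered as line segments of length `body_length`
#' centred on their position along their heading. A neighbour's visual angle is
#' the number of rays it is the nearest hit of, times the angular resolution
#' `span_deg / n_rays` (~0.165 degrees with the defaults); occluded rays count
#' once, for the nearest fish.
#'
#' @param positions `n x 2` matrix of fish positions in one frame.
#' @param headings length-`n` vector of headings (radians).
#' @param focal index of the focal fish.
#' @param body_length rendered body length of the neighbours (same units as
#'   positions).
#' @param n_rays rays per eye (default 1000).
#' @param span_deg angular span of each eye in degrees (default 165).
#' @return list with `right_deg`, `left_deg` (total visual angle per eye,
#'   degrees), `per_neighbour` (matrix `n x 2`, columns right/left; `NA` row for
#'   the focal fish) and `resolution_deg`.
#' @export
raycast_occupancy <- function(positions, headings, focal, body_length,
                              n_rays = 1000L, span_deg = 165) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(length(headings) == n, focal >= 1L, focal <= n)
  if (is.na(headings[focal])) stopf("focal fish has undefined heading")
  res <- deg2rad(span_deg) / n_rays
  th <- headings[focal]
  # ray bearings relative to heading: right eye negative, left eye positive
  rel <- (seq_len(n_rays) - 0.5) * res
  ang <- c(th - rel, th + rel)           # first block right eye, second left
  ux <- cos(ang); uy <- sin(ang)
  o <- positions[focal, ]
  others <- setdiff(seq_len(n), focal)
  tmin <- rep(Inf, 2L * n_rays)
  owner <- rep(NA_integer_, 2L * n_rays)
  for (j in others) {
    if (is.na(headings[j])) next
    u2 <- c(cos(headings[j]), sin(headings[j]))
    a <- positions[j, ] - (body_length / 2) * u2
    d <- body_length * u2                # segment a -> a + d
    q <- a - o
    den <- ux * d[2] - uy * d[1]
    tt <- (q[1] * d[2] - q[2] * d[1]) / den
    ss <- (q[1] * uy - q[2] * ux) / den
    hit <- is.finite(tt) & tt > 1e-12 & ss >= 0 & ss <= 1 & tt < tmin
    tmin[hit] <- tt[hit]
    owner[hit] <- j
  }
  per <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("right", "left")))
  eye <- rep(c("right", "left"), each = n_rays)
  for (j in others) {
    per[j, "right"] <- sum(owner == j & eye == "right", na.rm = TRUE) * rad2deg(res)
    per[j, "left"] <- sum(owner == j & eye == "left", na.rm = TRUE) * rad2deg(res)
  }
  list(right_deg = sum(!is.na(owner[eye == "right"])) * rad2deg(res),
       left_deg = sum(!is.na(owner[eye == "left"])) * rad2deg(res),
       per_neighbour = per,
       resolution_deg = rad2deg(res))
}

#' Extract clutter-difference turning events
#'
#' Pairs every detected turning bout with the interocular clutter difference
#' (right-eye minus left-eye total visual angle, degrees; positive = more
#' clutter on the right) at bout onset, computed by ray casting against the
#' stored body orientations.
#'
#' @param recs list of [group_recording()] (or a single recording).
#' @param turn_threshold_deg turn classification threshold, degrees.
#' @param body_length rendered neighbour body length; default scales the
#'   simulator convention (20 px in a 1024 px arena) to the recording's arena.
#' @param ... passed to [detect_bouts()].
#' @return data frame of class `clutter_events`: `group_id`, `fish`, `t_s`,
#'   `clutter_diff_deg`, `direction` ("left"/"right").
#' @export
extract_clutter_events <- function(recs, turn_threshold_deg = 10,
                                   body_length = NULL, ...) {
  if (inherits(recs, "group_recording")) recs <- list(recs)
  out <- list()
  for (rec in recs) {
    bl <- if (is.null(body_length)) rec$arena_diameter * 20 / 1024 else body_length
    bouts <- detect_bouts(rec, turn_threshold_deg = turn_threshold_deg, ...)
    bouts <- bouts[bouts$is_turn, , drop = FALSE]
    if (!nrow(bouts)) next
    cd <- vapply(seq_len(nrow(bouts)), function(b) {
      f <- bouts$onset_frame[b]
      occ <- raycast_occupancy(matrix(rec$positions[f, , ], ncol = 2),
                               rec$orientations[f, ],
                               focal = bouts$fish[b], body_length = bl)
      occ$right_deg - occ$left_deg
    }, 1.0)
    out[[length(out) + 1L]] <- data.frame(
      group_id = rec$group_id, fish = bouts$fish, t_s = bouts$t_s,
      clutter_diff_deg = cd, direction = bouts$direction)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group_id = character(), fish = integer(), t_s = numeric(),
               clutter_diff_deg = numeric(), direction = character())
  class(res) <- c("clutter_events", "data.frame")
  res
}

#' Clutter-difference turning curve
#'
#' Proportion of right turns out of all turns per 5-degree bin of the
#' interocular clutter difference, with 95% CI from the normal approximation of
#' the binomial, p +/- 1.96 sqrt(p (1 - p) / n), clamped to \[0, 1\]. Bins with
#' no events are omitted.
#'
#' @param events a `clutter_events` data frame (see
#'   [extract_clutter_events()]), or any data frame with columns
#'   `clutter_diff_deg` and `direction`.
#' @param bin_width bin width in degrees (default 5).
#' @return object of class `turning_curve`: data frame with `bin_center_deg`,
#'   `p_right`, `ci_low`, `ci_high`, `n`; attribute `bin_width`.
#' @export
turning_curve <- function(events, bin_width = 5) {
  stopifnot(all(c("clutter_diff_deg", "direction") %in% names(events)))
  if (!nrow(events)) stopf("no turning events")
  center <- round(events$clutter_diff_deg / bin_width) * bin_width
  tab <- split(events$direction == "right", center)
  df <- data.frame(
    bin_center_deg = as.numeric(names(tab)),
    p_right = vapply(tab, mean, 1.0),
    n = vapply(tab, length, 1L))
  se <- sqrt(df$p_right * (1 - df$p_right) / df$n)
  df$ci_low <- pmax(0, df$p_right - 1.96 * se)
  df$ci_high <- pmin(1, df$p_right + 1.96 * se)
  df <- df[order(df$bin_center_deg),
           c("bin_center_deg", "p_right", "ci_low", "ci_high", "n")]
  rownames(df) <- NULL
  structure(df, class = c("turning_curve", "data.frame"), bin_width = bin_width)
}

#' @export
plot.turning_curve <- function(x, ...) {
  plot(x$bin_center_deg, x$p_right, type = "n", ylim = c(0, 1),
       xlab = "clutter difference right - left (deg)",
       ylab = "p(turn right)", ...)
  polygon(c(x$bin_center_deg, rev(x$bin_center_deg)),
          c(x$ci_low, rev(x$ci_high)), col = "grey85", border = NA)
  lines(x$bin_center_deg, x$p_right, lwd = 2)
  abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Symmetrized area under the turning curve
#'
#' Sum over bins of sign(bin centre) * (p(turn right) - 0.5) * (bin width / 5),
#' so that attraction toward clutter is positive and repulsion negative. The
#' bin at zero clutter difference contributes nothing. The absolute scale is a
#' package convention (per 5-degree bin); ratios between conditions are the
#' quantity meant for interpretation.
#'
#' @param curve a [turning_curve()].
#' @return a scalar; positive = attraction, negative = repulsion.
#' @export
symmetrized_auc <- function(curve) {
  stopifnot(inherits(curve, "turning_curve"))
  bw <- attr(curve, "bin_width")
  sum(sign(curve$bin_center_deg) * (curve$p_right - 0.5) * (bw / 5))
}
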