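#' Central-difference kinematics of a recording
#'
#' Velocity is the central difference v(t) = (x(t+dt) - x(t-dt)) / 2dt with dt
#' one frame; speed its norm; direction the unit vector (undefined, `NA`, where
#' speed is zero). First and last frames are undefined.
#'
#' @param rec a [group_recording()].
#' @return an object of class `kinematic_series`: list with `velocity`
#'   (`[n_frames, n_fish, 2]`), `speed` (`[n_frames, n_fish]`), `direction`
#'   (`[n_frames, n_fish]`, angle in radians, `NA` where undefined).
#' @export
compute_kinematics <- function(rec) {
  stopifnot(inherits(rec, "group_recording"))
  nf <- n_frames(rec)
  if (nf < 3L) stopf("need at least 3 frames for central differences")
  dt <- 1 / rec$frame_rate
  p <- rec$positions
  v <- array(NA_real_, dim(p))
  idx <- 2:(nf - 1)
  v[idx, , ] <- (p[idx + 1, , , drop = FALSE] - p[idx - 1, , , drop = FALSE]) / (2 * dt)
  vx <- array(v[, , 1], dim(p)[1:2])
  vy <- array(v[, , 2], dim(p)[1:2])
  speed <- sqrt(vx^2 + vy^2)
  direction <- atan2(vy, vx)
  direction[!is.finite(speed) | speed < 1e-12] <- NA_real_
  structure(list(velocity = v, speed = speed, direction = direction,
                 frame_rate = rec$frame_rate),
            class = "kinematic_series")
}

# mean over frames and fish of the distance to the nearest neighbour
mean_nn1 <- function(positions) {
  k <- dim(positions)[2]
  if (k < 2L) stopf("nearest-neighbour distance needs >= 2 fish")
  nn <- matrix(Inf, dim(positions)[1], k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    d <- sqrt((positions[, a, 1] - positions[, b, 1])^2 +
              (positions[, a, 2] - positions[, b, 2])^2)
    nn[, a] <- pmin(nn[, a], d)
    nn[, b] <- pmin(nn[, b], d)
  }
  mean(nn)
}

#' Aggregation index against cross-group shuffled controls
#'
#' Aggregation = -log(NN1 / NN1_shuffled), where NN1 is the mean (over time and
#' fish) nearest-neighbour distance of a real group and NN1_shuffled the same
#' quantity for control groups assembled by shuffling fish between groups such
#' that every member of a shuffled group comes from a different real group.
#' Positive values mean tighter than chance, 0 chance-level, negative values
#' dispersal.
#'
#' @param recs list of [group_recording()] of equal fish count; at least as
#'   many groups as fish per group (otherwise the shuffle constraint is
#'   unsatisfiable).
#' @param shuffle_seed seed for the shuffled-control construction.
#' @param n_shuffled number of shuffled control groups (default 100).
#' @return object of class `group_metrics`: per-group `aggregation`, `nn1`,
#'   the common `nn1_shuffled` baseline, and the mean aggregation.
#' @export
aggregation_index <- function(recs, shuffle_seed = 1L, n_shuffled = 100L) {
  stopifnot(is.list(recs), all(vapply(recs, inherits, TRUE, "group_recording")))
  k <- vapply(recs, n_fish, 1L)
  if (length(unique(k)) != 1L) stopf("groups must have equal fish counts")
  k <- k[1]
  if (length(recs) < k)
    stopf("need at least %d groups of %d fish for the cross-group shuffle", k, k)
  nfr <- min(vapply(recs, n_frames, 1L))
  nn1 <- vapply(recs, function(r)
    mean_nn1(r$positions[seq_len(nfr), , , drop = FALSE]), 1.0)
  # each shuffled group takes fish slot j from a distinct real group; keeping
  # the slot makes the construction exact for trivially identical groups
  nn1_shuf <- with_seed(shuffle_seed, {
    mean(vapply(seq_len(n_shuffled), function(s) {
      gsel <- sample(length(recs), k)         # one fish per distinct real group
      pos <- array(NA_real_, c(nfr, k, 2))
      for (j in seq_len(k))
        pos[, j, ] <- recs[[gsel[j]]]$positions[seq_len(nfr), j, ]
      mean_nn1(pos)
    }, 1.0))
  })
  agg <- -log(nn1 / nn1_shuf)
  structure(list(aggregation = agg, mean_aggregation = mean(agg),
                 nn1 = nn1, nn1_shuffled = nn1_shuf,
                 group_id = vapply(recs, `[[`, "", "group_id")),
            class = "group_metrics")
}

#' @export
print.group_metrics <- function(x, ...) {
  cat(sprintf("<group_metrics: %d groups, mean aggregation %.3f (nn1_shuffled %.3g)>\n",
              length(x$aggregation), x$mean_aggregation, x$nn1_shuffled))
  invisible(x)
}

#' Alignment (polarization) index
#'
#' alignment(t) = |sum_i d_i(t)| / N over the N unit direction-of-motion
#' vectors; bounded between 0 (incoherent) and 1 (all parallel). Frames where
#' any fish has an undefined direction are excluded.
#'
#' @param rec a [group_recording()].
#' @return list with `alignment` (per usable frame), `frames` (their indices)
#'   and `mean`.
#' @export
alignment_index <- function(rec) {
  kin <- compute_kinematics(rec)
  ok <- rowSums(is.na(kin$direction)) == 0L
  ok[c(1, length(ok))] <- FALSE
  if (!any(ok)) stopf("no frame has all directions defined")
  d <- kin$direction[ok, , drop = FALSE]
  al <- sqrt(rowSums(cos(d))^2 + rowSums(sin(d))^2) / ncol(d)
  list(alignment = al, frames = which(ok), mean = mean(al))
}

#' Detect swim bouts from a trajectory
#'
#' Bouts are segmented as local maxima of the speed trace exceeding a
#' threshold (default 1.5 x the median speed of that fish). The heading change
#' of a bout is the direction of motion `window` frames after the peak minus
#' `window` frames before; bouts with |heading change| above
#' `turn_threshold_deg` are classified as turns (sign: right turns positive).
#'
#' @param rec a [group_recording()].
#' @param turn_threshold_deg threshold separating forward swims from turns
#'   (degrees; default 10).
#' @param speed_threshold absolute speed threshold; default `NULL` uses
#'   1.5 x median speed per fish.
#' @param window frames on each side of the peak used for the heading change.
#' @return data frame: `fish`, `frame` (peak), `onset_frame`, `t_s`,
#'   `dheading_deg` (right positive), `is_turn`, `direction` ("left"/"right"
#'   or `NA` for forward swims).
#' @export
detect_bouts <- function(rec, turn_threshold_deg = 10, speed_threshold = NULL,
                         window = 2L) {
  kin <- compute_kinematics(rec)
  nf <- n_frames(rec)
  out <- list()
  for (i in seq_len(n_fish(rec))) {
    s <- kin$speed[, i]
    thr <- if (is.null(speed_threshold)) 1.5 * median(s, na.rm = TRUE)
           else speed_threshold
    idx <- which(!is.na(s))
    peaks <- idx[idx > window + 1 & idx < nf - window &
                   s[idx] > thr &
                   s[idx] >= c(NA, s)[idx] & s[idx] >= s[pmin(idx + 1, nf)]]
    if (!length(peaks)) next
    # collapse runs of adjacent peak frames
    peaks <- peaks[c(TRUE, diff(peaks) > window)]
    before <- kin$direction[peaks - window, i]
    after <- kin$direction[peaks + window, i]
    keep <- !is.na(before) & !is.na(after)
    peaks <- peaks[keep]
    if (!length(peaks)) next
    dh_math <- wrap_angle(after[keep] - before[keep])   # CCW positive
    dh_deg <- -rad2deg(dh_math)                         # right turns positive
    out[[length(out) + 1L]] <- data.frame(
      fish = i, frame = peaks, onset_frame = peaks - window,
      t_s = rec$t[peaks], dheading_deg = dh_deg,
      is_turn = abs(dh_deg) > turn_threshold_deg,
      direction = ifelse(abs(dh_deg) > turn_threshold_deg,
                         ifelse(dh_deg > 0, "right", "left"), NA))
  }
  if (!length(out))
    return(data.frame(fish = integer(), frame = integer(),
                      onset_frame = integer(), t_s = numeric(),
                      dheading_deg = numeric(), is_turn = logical(),
                      direction = character()))
  do.call(rbind, out)
}
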