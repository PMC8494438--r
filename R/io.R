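#' Group trajectory recording
#'
#' Container for the per-fish time series of one group in one circular arena:
#' positions (in arena-centred coordinates) and body orientations (radians,
#' direction-of-motion convention, wrapped to (-pi, pi]).
#'
#' @param positions numeric array with dim `c(n_frames, n_fish, 2)` (x, y).
#' @param orientations numeric matrix `n_frames x n_fish`, radians; `NA`
#'   allowed where the heading is undefined.
#' @param frame_rate frames per second (experimental recordings are ~39 fps,
#'   simulator exports 40 fps).
#' @param arena_diameter arena diameter in the same length units as positions
#'   (cm for experimental data, px for simulations).
#' @param group_id character label.
#' @param t optional frame times in seconds; defaults to `(0:(n-1))/frame_rate`.
#' @return an object of class `group_recording`.
#' @export
group_recording <- function(positions, orientations, frame_rate, arena_diameter,
                            group_id = "g1", t = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 2L)
    stopf("positions must be an [n_frames, n_fish, 2] array")
  n_frames <- dim(positions)[1]
  n_fish <- dim(positions)[2]
  if (n_frames < 1L) stopf("recording has no frames")
  orientations <- as.matrix(orientations)
  if (!all(dim(orientations) == c(n_frames, n_fish)))
    stopf("orientations must be an [n_frames, n_fish] matrix matching positions")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stopf("frame_rate must be > 0")
  if (!is.numeric(arena_diameter) || arena_diameter <= 0)
    stopf("arena_diameter must be > 0")
  r <- sqrt(positions[, , 1]^2 + positions[, , 2]^2)
  if (any(r > arena_diameter / 2 + 1e-6 * arena_diameter, na.rm = TRUE))
    stopf("positions lie outside the arena (radius %g)", arena_diameter / 2)
  if (is.null(t)) t <- (seq_len(n_frames) - 1) / frame_rate
  structure(
    list(group_id = as.character(group_id), frame_rate = frame_rate,
         arena_diameter = arena_diameter, t = t,
         positions = positions, orientations = wrap_angle(orientations)),
    class = "group_recording")
}

#' @export
print.group_recording <- function(x, ...) {
  cat(sprintf("<group_recording '%s': %d fish, %d frames @ %.3g fps, arena %g>\n",
              x$group_id, dim(x$positions)[2], dim(x$positions)[1],
              x$frame_rate, x$arena_diameter))
  invisible(x)
}

n_fish <- function(rec) dim(rec$positions)[2]
n_frames <- function(rec) dim(rec$positions)[1]

trajectory_columns <- c("group_id", "fish_id", "frame", "t_s", "x", "y", "heading_rad")

#' Write a group recording to a long-form trajectory CSV
#'
#' The dialect is one metadata comment line (`# frame_rate=... arena_diameter=...`),
#' one header line, then one row per frame per fish with columns
#' `group_id, fish_id, frame, t_s, x, y, heading_rad`.
#'
#' @param rec a [group_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_recording <- function(rec, path) {
  stopifnot(inherits(rec, "group_recording"))
  nf <- n_frames(rec); k <- n_fish(rec)
  if (nf < 1L || k < 1L) stopf("refusing to write an empty recording")
  df <- data.frame(
    group_id = rec$group_id,
    fish_id = rep(sprintf("f%02d", seq_len(k)), each = nf),
    frame = rep(seq_len(nf) - 1L, times = k),
    t_s = rep(rec$t, times = k),
    x = as.vector(rec$positions[, , 1]),
    y = as.vector(rec$positions[, , 2]),
    heading_rad = as.vector(rec$orientations))
  df <- df[order(df$frame, df$fish_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%.17g arena_diameter=%.17g",
                     rec$frame_rate, rec$arena_diameter), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a group recording from a trajectory CSV
#'
#' @param path file written by [write_group_recording()] (or any file in the
#'   same dialect). The file must contain a single group.
#' @return a [group_recording()]; orientations are wrapped to (-pi, pi].
#' @export
read_group_recording <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  meta <- c(frame_rate = NA_real_, arena_diameter = NA_real_)
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("[a-z_]+=[-0-9.eE+]+", first))[[1]]
    for (kv in m) {
      kvs <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (kvs[1] %in% names(meta)) meta[kvs[1]] <- as.numeric(kvs[2])
    }
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(trajectory_columns, names(df))
  if (length(missing))
    stopf("trajectory file lacks column(s): %s", paste(missing, collapse = ", "))
  if (length(unique(df$group_id)) != 1L)
    stopf("file contains %d groups; expected one group per file",
          length(unique(df$group_id)))
  fish <- sort(unique(df$fish_id))
  frames <- sort(unique(df$frame))
  if (any(diff(frames) <= 0) || !all(df$frame %in% frames))
    stopf("non-monotonic frame index")
  nf <- length(frames); k <- length(fish)
  if (nrow(df) != nf * k) stopf("unequal frame counts across fish")
  df <- df[order(match(df$fish_id, fish), df$frame), ]
  pos <- array(NA_real_, c(nf, k, 2))
  pos[, , 1] <- matrix(df$x, nf, k)
  pos[, , 2] <- matrix(df$y, nf, k)
  ori <- matrix(df$heading_rad, nf, k)
  t <- df$t_s[seq_len(nf)]
  fr <- meta[["frame_rate"]]
  if (is.na(fr)) fr <- if (nf > 1) 1 / stats::median(diff(t)) else 1
  ad <- meta[["arena_diameter"]]
  if (is.na(ad)) ad <- 2 * max(sqrt(df$x^2 + df$y^2), 1e-12)
  group_recording(pos, ori, frame_rate = fr, arena_diameter = ad,
                  group_id = df$group_id[1], t = t)
}

bout_columns <- c("fish_id", "t_s", "dheading_deg", "coherence_pct", "stim_dir")

#' Read / write bout tables
#'
#' Bout tables are event lists from the coherent-dot optomotor assay (or from
#' its drift-diffusion simulation): one row per swim bout with columns
#' `fish_id, t_s, dheading_deg, coherence_pct, stim_dir`. Heading changes are in
#' degrees with right turns positive; `stim_dir` is +1 (rightward), -1
#' (leftward).
#'
#' @param bouts a data frame of class `bout_table`.
#' @param path file path.
#' @return `read_bout_table` returns a `bout_table`; `write_bout_table` returns
#'   `path` invisibly.
#' @export
write_bout_table <- function(bouts, path) {
  stopifnot(is.data.frame(bouts), all(bout_columns %in% names(bouts)))
  write.csv(bouts[, bout_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bout_table
#' @export
read_bout_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(bout_columns, names(df))
  if (length(missing))
    stopf("bout file lacks column(s): %s", paste(missing, collapse = ", "))
  bad <- !df$coherence_pct %in% c(0, 25, 50, 100)
  if (any(bad)) stopf("coherence values outside {0,25,50,100}")
  ord <- order(df$fish_id, df$t_s)
  df <- df[ord, ]
  dup <- unlist(tapply(df$t_s, df$fish_id, function(t) c(FALSE, diff(t) <= 0)))
  if (any(dup)) stopf("bout times not strictly increasing within fish")
  class(df) <- c("bout_table", "data.frame")
  df
}

default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(output_dir = "."),
    metrics = list(turn_threshold_deg = 10, n_rays = 1000L, span_deg = 165,
                   bin_width_deg = 5),
    ddm = list(dt = 0.01, tau = 0.65, sigma = 8, threshold = 0.5,
               p_below = 0.005, p_above = 0.011),
    fitting = list(pop_size = 800L, generations = 80L, n_fish_eval = 12L,
                   metric = "mse"),
    collective = list(arena_diameter_px = 1024, fishsize_px = 20, dt = 0.01,
                      duration_s = 600, w_clutter = 1, w_motion = 1,
                      n_fish = 5L, frame_rate = 40))
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and fills documented defaults for any absent
#' block or key. Unknown keys trigger a warning; values whose type conflicts
#' with the default raise an error.
#'
#' @param path YAML file. A minimal file may contain just `seed: 1`.
#' @return a named list with blocks `seed`, `paths`, `metrics`, `ddm`,
#'   `fitting`, `collective`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  conf <- default_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  merge_block <- function(def, usr, prefix) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      warning(sprintf("unknown config key(s) ignored: %s",
                      paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
    for (k in intersect(names(usr), names(def))) {
      if (is.list(def[[k]])) {
        if (!is.list(usr[[k]]))
          stopf("config key '%s%s' must be a block", prefix, k)
        def[[k]] <- merge_block(def[[k]], usr[[k]], paste0(prefix, k, "."))
      } else {
        if (is.numeric(def[[k]]) && !is.numeric(usr[[k]]))
          stopf("config key '%s%s' must be numeric", prefix, k)
        if (is.character(def[[k]]) && !is.character(usr[[k]]))
          stopf("config key '%s%s' must be a string", prefix, k)
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  conf <- merge_block(conf, user, "")
  conf$seed <- as.integer(conf$seed)
  conf
}
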