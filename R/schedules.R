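# Stimulus schedules for the six tasks: block-randomized magnitude
# sequences plus per-trial nuisance draws (start positions, onset delays).

#' Build an equally spaced set of stimulus magnitudes
#'
#' The reproduction tasks use 11 equally spaced magnitudes: lengths from
#' 6 to 14 cm in 0.8 cm steps (space) and intervals from 1.270 to 1.8 s
#' (time). The mean of each set equals the corresponding discrimination
#' standard (10 cm, 1.535 s).
#'
#' @param min_mag smallest magnitude (cm or s).
#' @param max_mag largest magnitude; must be `>= min_mag`.
#' @param n_levels number of levels; if 1, `min_mag` must equal `max_mag`.
#' @return numeric vector of `n_levels` equally spaced magnitudes,
#'   inclusive of both ends.
#' @examples
#' build_levels(6, 14, 11)      # space: step 0.8 cm, mean 10 cm
#' build_levels(1.27, 1.8, 11)  # time: mean 1.535 s
#' @export
build_levels <- function(min_mag, max_mag, n_levels) {
  stop_if_not_scalar_number(min_mag, "min_mag")
  stop_if_not_scalar_number(max_mag, "max_mag")
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 1 ||
      n_levels != as.integer(n_levels)) {
    stop("`n_levels` must be a positive integer", call. = FALSE)
  }
  if (min_mag > max_mag) stop("`min_mag` must not exceed `max_mag`", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (n_levels == 1L) {
    if (min_mag != max_mag) {
      stop("with a single level, `min_mag` must equal `max_mag`", call. = FALSE)
    }
    return(min_mag)
  }
  seq(min_mag, max_mag, length.out = n_levels)
}

#' Default stimulus levels and standards
#'
#' `default_space_levels()` returns the 11 lengths (6–14 cm, 0.8 cm step);
#' `default_time_levels()` the 11 intervals (1.270–1.8 s). The
#' discrimination standards (10 cm, 1.535 s) equal the means of these sets.
#'
#' @return numeric vector of 11 magnitudes.
#' @export
default_space_levels <- function() build_levels(6, 14, 11)

#' @rdname default_space_levels
#' @export
default_time_levels <- function() build_levels(1.27, 1.8, 11)

#' @rdname default_space_levels
#' @export
space_standard <- function() 10

#' @rdname default_space_levels
#' @export
time_standard <- function() 1.535

#' Build a block-randomized reproduction schedule
#'
#' Each of `n_sets` contiguous blocks is an independent seeded permutation
#' of `levels` ("randomized within each set of stimuli"), so every level
#' appears exactly `n_sets` times. The default design is 6 sets of 11
#' levels, 66 trials.
#'
#' @param levels numeric vector of stimulus magnitudes (non-empty).
#' @param n_sets number of blocks (each a permutation of `levels`).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param condition `"space"` or `"time"`; fixes the units (cm or s).
#' @return a `stimulus_schedule` object: a list with `condition`, `task`,
#'   `levels`, `units`, `seed`, a `trials` data frame
#'   (`trial_index` 0-based, `set_index` 0-based, `magnitude`), a
#'   `nuisance` column placeholder (`NA` until [draw_nuisance()]), and
#'   presentation metadata.
#' @export
build_reproduction_schedule <- function(levels, n_sets, seed,
                                        condition = c("space", "time")) {
  condition <- match.arg(condition)
  if (length(levels) == 0L || !is.numeric(levels)) {
    stop("`levels` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 1) {
    stop("`n_sets` must be a positive integer", call. = FALSE)
  }
  n_sets <- as.integer(n_sets)
  order <- with_seed(seed, {
    unlist(lapply(seq_len(n_sets), function(i) sample(length(levels))))
  })
  mags <- levels[order]
  trials <- data.frame(
    trial_index = seq_along(mags) - 1L,
    set_index = rep(seq_len(n_sets) - 1L, each = length(levels)),
    magnitude = mags
  )
  new_stimulus_schedule(
    condition = condition, task = "reproduction", levels = levels,
    trials = trials, units = if (condition == "space") "cm" else "s",
    seed = as.integer(seed),
    # stimulus presentation durations; metadata only, no computational role
    meta = list(dot_duration_s = if (condition == "space") 0.4 else 0.2)
  )
}

new_stimulus_schedule <- function(condition, task, levels, trials, units,
                                  seed, meta = list()) {
  trials$nuisance <- if (is.null(trials$nuisance)) NA_real_ else trials$nuisance
  structure(
    list(condition = condition, task = task, levels = levels,
         trials = trials, units = units, seed = seed, meta = meta),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %s %s: %d trials over %d levels [%s], seed %d\n",
              x$condition, x$task, nrow(x$trials), length(x$levels),
              x$units, x$seed))
  invisible(x)
}

# Uniform nuisance ranges printed in the task descriptions, keyed by
# condition/task. Space reproduction: first-dot start position 0.2-1.7 cm
# from the screen border; time reproduction: first-dot onset delay 1-2 s;
# time discrimination: onset delay 1-1.8 s.
nuisance_range <- function(condition, task) {
  key <- paste(condition, task, sep = "/")
  switch(key,
    "space/reproduction" = c(0.2, 1.7),
    "time/reproduction" = c(1, 2),
    "time/discrimination" = c(1, 1.8),
    stop(sprintf("no nuisance range is defined for task '%s'", key),
         call. = FALSE)
  )
}

#' Fill a schedule's per-trial nuisance parameters
#'
#' Draws one uniform value per trial in the task's printed range (space
#' reproduction start position 0.2–1.7 cm; time reproduction onset delay
#' 1–2 s; time discrimination onset delay 1–1.8 s). Nuisance values are
#' recorded for completeness but never alter the stimulus magnitudes.
#'
#' @param schedule a `stimulus_schedule` with trials.
#' @param seed integer seed.
#' @param range optional length-2 override of the uniform range (equal
#'   bounds give a constant nuisance).
#' @return the schedule with its `nuisance` column filled.
#' @export
draw_nuisance <- function(schedule, seed, range = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (nrow(schedule$trials) == 0L) stop("schedule has no trials", call. = FALSE)
  if (is.null(range)) range <- nuisance_range(schedule$condition, schedule$task)
  stopifnot(length(range) == 2L, range[1] <= range[2])
  schedule$trials$nuisance <- with_seed(seed, {
    stats::runif(nrow(schedule$trials), range[1], range[2])
  })
  schedule
}

#' Write or read a stimulus schedule as annotated CSV
#'
#' The file starts with `#`-prefixed metadata lines (condition, task,
#' units, seed) followed by the trial table
#' (`trial_index,set_index,magnitude,nuisance`). `read_schedule()` inverts
#' `write_schedule()` losslessly.
#'
#' @param schedule a `stimulus_schedule`.
#' @param path file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `stimulus_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condition: %s", schedule$condition),
    sprintf("# task: %s", schedule$task),
    sprintf("# units: %s", schedule$units),
    sprintf("# seed: %d", schedule$seed),
    sprintf("# levels: %s", paste(format(schedule$levels, digits = 17),
                                  collapse = " "))
  ), con)
  utils::write.table(schedule$trials, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(sprintf("^# %s:", name), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("missing header field '%s'", name),
                              call. = FALSE)
    sub(sprintf("^# %s: ?", name), "", m)
  }
  trials <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  new_stimulus_schedule(
    condition = get_field("condition"), task = get_field("task"),
    levels = as.numeric(strsplit(get_field("levels"), " +")[[1]]),
    trials = trials, units = get_field("units"),
    seed = as.integer(get_field("seed"))
  )
}
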