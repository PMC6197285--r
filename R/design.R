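#' Configure a dyadic 2IFC contrast-discrimination experiment
#'
#' Describes the trial structure of a two-interval forced-choice (2IFC)
#' contrast-discrimination task performed by a dyad: a number of sessions,
#' each split into blocks of trials. On every trial one of `n_locations`
#' patches in one of the two displays (the target) has its contrast raised
#' above `baseline_contrast` by one of the `increments`; the observer reports
#' which display contained the target. Increments are counterbalanced so that
#' each appears an equal number of times, which requires the trial count to be
#' divisible by the number of increments.
#'
#' The default configuration is two sessions of 8 blocks x 16 trials
#' (256 trials), baseline contrast 0.15 and increments 0.075, 0.15, 0.20,
#' 0.30, with six possible target locations.
#'
#' On disagreement trials the dyad enters a joint decision, and members take
#' turns entering it: the mouse holder enters it on odd trials, the keyboard
#' holder on even trials. `mouse_member_session1` says which member starts
#' with the mouse; when `swap_devices_between_sessions` is `TRUE` the devices
#' (and hence the entry turns) swap at every session boundary.
#'
#' @param n_sessions Number of experimental sessions.
#' @param blocks_per_session Blocks per session.
#' @param trials_per_block Trials per block.
#' @param baseline_contrast Baseline Michelson-like contrast of the non-target
#'   patches, in `[0, 1]`.
#' @param increments Positive contrast increments added to the target patch;
#'   `baseline_contrast + max(increments)` must not exceed 1.
#' @param n_locations Number of candidate target locations per display.
#' @param seed Integer seed controlling the pseudo-random parts of the design
#'   (increment order, target interval and location).
#' @param mouse_member_session1 Which member (1 or 2) holds the mouse in
#'   session 1.
#' @param swap_devices_between_sessions Swap response devices between
#'   consecutive sessions?
#'
#' @return An object of class `experiment_config`.
#' @seealso [make_design()]
#' @export
#' @examples
#' cfg <- experiment_config(seed = 42)
#' cfg$blocks_per_session * cfg$trials_per_block   # trials per session
experiment_config <- function(n_sessions = 2L,
                              blocks_per_session = 8L,
                              trials_per_block = 16L,
                              baseline_contrast = 0.15,
                              increments = c(0.075, 0.15, 0.20, 0.30),
                              n_locations = 6L,
                              seed = 1L,
                              mouse_member_session1 = 2L,
                              swap_devices_between_sessions = TRUE) {
  n_sessions <- as.integer(n_sessions)
  blocks_per_session <- as.integer(blocks_per_session)
  trials_per_block <- as.integer(trials_per_block)
  n_locations <- as.integer(n_locations)
  seed <- as.integer(seed)
  if (any(c(n_sessions, blocks_per_session, trials_per_block, n_locations) < 1L)) {
    stop("configuration error: counts must be positive integers")
  }
  if (!is.numeric(baseline_contrast) || baseline_contrast < 0 || baseline_contrast > 1) {
    stop("configuration error: baseline_contrast must lie in [0, 1]")
  }
  increments <- as.numeric(increments)
  if (length(increments) < 1L || any(increments <= 0) || anyDuplicated(increments)) {
    stop("configuration error: increments must be distinct positive values")
  }
  if (baseline_contrast + max(increments) > 1) {
    stop("configuration error: baseline_contrast + max(increments) exceeds 1")
  }
  total <- n_sessions * blocks_per_session * trials_per_block
  if (total %% length(increments) != 0L) {
    stop(sprintf(
      "configuration error: total trial count %d is not divisible by the number of increments %d",
      total, length(increments)
    ))
  }
  if (!mouse_member_session1 %in% c(1L, 2L)) {
    stop("configuration error: mouse_member_session1 must be 1 or 2")
  }
  structure(
    list(
      n_sessions = n_sessions,
      blocks_per_session = blocks_per_session,
      trials_per_block = trials_per_block,
      baseline_contrast = baseline_contrast,
      increments = increments,
      n_locations = n_locations,
      seed = seed,
      mouse_member_session1 = as.integer(mouse_member_session1),
      swap_devices_between_sessions = isTRUE(swap_devices_between_sessions)
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  total <- x$n_sessions * x$blocks_per_session * x$trials_per_block
  cat(sprintf(
    "2IFC experiment: %d session(s) x %d block(s) x %d trial(s) = %d trials\n",
    x$n_sessions, x$blocks_per_session, x$trials_per_block, total
  ))
  cat(sprintf(
    "baseline contrast %.3f; increments: %s; %d locations; seed %d\n",
    x$baseline_contrast, paste(format(x$increments), collapse = ", "),
    x$n_locations, x$seed
  ))
  invisible(x)
}

# Member entering the joint decision on each trial: mouse on odd global trial
# numbers, keyboard on even, with devices optionally swapping every session.
joint_indicator_for <- function(config, session, trial) {
  mouse_holder <- config$mouse_member_session1
  if (config$swap_devices_between_sessions) {
    swap <- (session - 1L) %% 2L == 1L
    mouse_holder <- ifelse(swap, 3L - mouse_holder, mouse_holder)
  } else {
    mouse_holder <- rep(mouse_holder, length(session))
  }
  ifelse(trial %% 2L == 1L, mouse_holder, 3L - mouse_holder)
}

#' Generate the trial schedule of an experiment
#'
#' Expands an [experiment_config()] into one row per trial: increments exactly
#' counterbalanced (within each session when the session length is divisible
#' by the number of increments, otherwise across the whole experiment), target
#' interval and location drawn uniformly at random, and a deterministic
#' turn-taking assignment of who enters the joint decision. The schedule is a
#' pure function of the configuration, including its seed.
#'
#' The signed stimulus strength `delta_c` is the contrast difference between
#' the second and the first display at the target location: `+increment` when
#' the target is in interval 2 and `-increment` when it is in interval 1.
#'
#' @param config An [experiment_config()].
#' @return A data frame with columns `session`, `block`, `trial` (global,
#'   1-based), `target_interval` (1 or 2), `target_location`, `increment`,
#'   `delta_c` and `joint_indicator` (1 or 2).
#' @export
#' @examples
#' des <- make_design(experiment_config(seed = 7))
#' nrow(des)              # 256
#' table(des$increment)   # 64 each
make_design <- function(config) {
  if (!inherits(config, "experiment_config")) {
    stop("config must be an experiment_config object")
  }
  per_session <- config$blocks_per_session * config$trials_per_block
  total <- config$n_sessions * per_session
  n_inc <- length(config$increments)

  set.seed(config$seed)
  if (per_session %% n_inc == 0L) {
    increment <- unlist(lapply(seq_len(config$n_sessions), function(s) {
      sample(rep(config$increments, per_session %/% n_inc))
    }))
  } else {
    increment <- sample(rep(config$increments, total %/% n_inc))
  }
  target_interval <- sample(c(1L, 2L), total, replace = TRUE)
  target_location <- sample.int(config$n_locations, total, replace = TRUE)

  trial <- seq_len(total)
  session <- ((trial - 1L) %/% per_session) + 1L
  block <- (((trial - 1L) %% per_session) %/% config$trials_per_block) + 1L

  data.frame(
    session = session,
    block = block,
    trial = trial,
    target_interval = target_interval,
    target_location = target_location,
    increment = increment,
    delta_c = ifelse(target_interval == 2L, increment, -increment),
    joint_indicator = joint_indicator_for(config, session, trial)
  )
}
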