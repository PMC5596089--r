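## Decision-making layer: maps decoded key ids to commands and sequences
## a drinking task end to end on fully synthetic inputs. The robot itself
## is simulated as instantaneous waypoint traversal with a configurable
## fixed duration; what is modeled faithfully is the information flow:
## decode -> segment -> locate -> transform -> deliver -> decode -> return.

#' Map a decoded key to a command
#'
#' Keys 1-3 command delivery of the corresponding container; key 4 is
#' "back" (return the held container).
#'
#' @param decision key id in 1..4.
#' @return one of `"cup1"`, `"cup2"`, `"cup3"`, `"back"`.
#' @export
map_decision <- function(decision) {
  cmds <- c("cup1", "cup2", "cup3", "back")
  if (!is.numeric(decision) || length(decision) != 1 ||
      is.na(decision) || !(decision %in% 1:4)) {
    stop_config("decision must be a key id in 1..4")
  }
  cmds[decision]
}

#' Fresh system state
#'
#' @return a `system_state` in mode `"idle"` with an empty event log.
#' @export
system_state <- function() {
  structure(list(mode = "idle", held_object = NA_integer_,
                 log = list(), clock = 0),
            class = "system_state")
}

log_event <- function(state, event, ...) {
  state$log[[length(state$log) + 1L]] <- c(list(t = state$clock,
                                                event = event), list(...))
  state
}

#' Apply a command to the system state
#'
#' Guards: delivery is valid only from `idle` and only for a located
#' object; `back` is valid only while `holding`. Invalid transitions are
#' rejected (state unchanged, reason logged), not errors: the decoder may
#' legitimately emit a command that the current mode forbids.
#'
#' @param state a `system_state`.
#' @param command a command string from [map_decision()].
#' @param world list with `objects` (list of robot-frame 3-vectors, possibly
#'   with `NULL` holes for unlocated objects) and `mouth` (3-vector).
#' @param motion_s simulated duration of one robot motion, seconds.
#' @return the updated `system_state`; field `rejected` flags a refused
#'   transition.
#' @export
transition <- function(state, command, world, motion_s = 20) {
  state$rejected <- FALSE
  if (command == "back") {
    if (state$mode != "holding") {
      state$rejected <- TRUE
      return(log_event(state, "rejected", command = command,
                       reason = "back is only valid while holding"))
    }
    state$clock <- state$clock + motion_s
    state <- log_event(state, "returned", object = state$held_object)
    state$mode <- "idle"
    state$held_object <- NA_integer_
    return(state)
  }
  i <- match(command, c("cup1", "cup2", "cup3"))
  if (is.na(i)) {
    state$rejected <- TRUE
    return(log_event(state, "rejected", command = command,
                     reason = "unknown command"))
  }
  if (state$mode != "idle") {
    state$rejected <- TRUE
    return(log_event(state, "rejected", command = command,
                     reason = "deliver is only valid from idle"))
  }
  pos <- if (i <= length(world$objects)) world$objects[[i]] else NULL
  if (is.null(pos)) {
    state$rejected <- TRUE
    return(log_event(state, "rejected", command = command,
                     reason = "object not located"))
  }
  state$clock <- state$clock + motion_s
  state <- log_event(state, "delivered", object = i,
                     position = round(pos, 4), mouth = world$mouth)
  state$mode <- "holding"
  state$held_object <- i
  state
}

#' End-to-end drinking-task simulation
#'
#' For each task: synthesize a test EEG trial pair whose intended keys are
#' (chosen cup, back), decode both with the self-adaptive decoder, segment
#' and locate the commanded container in a synthetic scene, transform its
#' centroid camera -> board -> robot, and drive the state machine through
#' deliver and return. A task succeeds when both decodes are correct and
#' both transitions are accepted.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{eeg}{a [synth_session_spec()] for the test trials (its
#'       `n_trials` is overridden to `2 * n_tasks`).}
#'     \item{timing}{a [session_timing()].}
#'     \item{model}{a trained `blda_model`.}
#'     \item{theta0}{stopping threshold.}
#'     \item{scene}{a [scene_spec()] with at least 3 objects.}
#'     \item{cam_to_board, board_to_robot}{[rigid_transform()]s.}
#'     \item{mouth}{robot-frame mouth position (config-supplied; mouth
#'       tracking hardware is out of scope).}
#'     \item{n_tasks}{number of tasks.}
#'     \item{recognizer}{optional trained `cnn_model`; when absent, objects
#'       are indexed by scene order (sorted by centroid x).}
#'     \item{motion_s}{simulated robot motion duration, seconds.}
#'   }
#' @param seed integer seed for the synthetic EEG and task commands.
#' @return list with `tasks` (per-task data.frame), `accuracy`, `state`
#'   (final `system_state` with the full event log).
#' @export
run_e2e <- function(config, seed = NULL) {
  timing <- config$timing %||% session_timing()
  n_tasks <- config$n_tasks %||% 10
  theta0 <- config$theta0 %||% 0.5
  motion_s <- config$motion_s %||% 20

  # perception once per run: the scene is static on the table
  sc <- synth_scene(config$scene)
  ps <- extract_planes(sc$cloud)
  hulls <- object_hulls(ps, sc$cloud)
  objs <- segment_objects(sc$cloud, ps, hulls)
  cam_centroids <- lapply(objs$objects, locate_object, cloud = sc$cloud)
  to_robot <- compose_transforms(config$board_to_robot, config$cam_to_board)
  robot_pos <- lapply(cam_centroids, function(p) apply_transform(to_robot, p))
  ord <- order(vapply(robot_pos, `[`, numeric(1), 1))
  world <- list(objects = robot_pos[ord], mouth = config$mouth %||% c(0.3, 0, 0.4))

  seed_cmd <- if (is.null(seed)) NULL else seed + 1L
  cmds <- with_seed(seed_cmd, sample.int(3, n_tasks, replace = TRUE))
  # one synthetic online session: trials alternate (cup_i, back)
  spec <- config$eeg
  spec$n_trials <- 2L * n_tasks
  spec$rounds_per_trial <- timing$m_max
  spec$seed <- if (is.null(seed)) NULL else seed + 2L
  # trials alternate (chosen cup, back): two commands per task
  rec <- synthesize_recording(spec, timing,
                              targets = as.integer(rbind(cmds, 4L)))
  sim <- simulate_online(rec, config$model, theta0, timing)

  state <- system_state()
  rows <- vector("list", n_tasks)
  for (k in seq_len(n_tasks)) {
    d1 <- sim$trials$decision[2 * k - 1]
    d2 <- sim$trials$decision[2 * k]
    state <- log_event(state, "decode", task = k, decision = d1,
                       rounds = sim$trials$M[2 * k - 1])
    state$clock <- state$clock + sim$trials$selection_s[2 * k - 1]
    state <- transition(state, map_decision(d1), world, motion_s)
    deliver_ok <- !state$rejected
    state <- log_event(state, "decode", task = k, decision = d2,
                       rounds = sim$trials$M[2 * k])
    state$clock <- state$clock + sim$trials$selection_s[2 * k]
    state <- transition(state, map_decision(d2), world, motion_s)
    back_ok <- !state$rejected
    if (state$mode == "holding") {
      # task failed mid-way; put the container back so the next task can run
      state <- transition(state, "back", world, motion_s)
    }
    success <- d1 == cmds[k] && d2 == 4L && deliver_ok && back_ok
    stage <- if (!deliver_ok) "delivery" else if (!back_ok) "return"
             else if (d1 != cmds[k]) "decode-1" else if (d2 != 4L) "decode-2"
             else "ok"
    rows[[k]] <- data.frame(task = k, command = cmds[k], decision1 = d1,
                            decision2 = d2, M1 = sim$trials$M[2 * k - 1],
                            M2 = sim$trials$M[2 * k], success = success,
                            failed_stage = stage)
  }
  tasks <- do.call(rbind, rows)
  list(tasks = tasks, accuracy = mean(tasks$success), state = state,
       decode = sim, world = world)
}
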