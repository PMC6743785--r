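#' Construct a gestural score
#'
#' A gestural score is the timed activation schedule of constriction goals
#' ("gestures") for an utterance. Each gesture drives one task variable
#' toward a target with critically damped (or explicitly damped) second-order
#' point-attractor dynamics while its activation interval `[onset, offset)`
#' contains the current time. Activation is a step function; overlapping
#' gestures on the same task variable are rejected.
#'
#' @param gestures A data frame with one row per gesture and columns `task`
#'   (one of [task_inventory()]), `target` (task units: cm or rad), `mass`
#'   (> 0), `stiffness` (> 0), `damping` (numeric >= 0, or the string
#'   `"critical"` which resolves to `2*sqrt(mass*stiffness)`), `onset` and
#'   `offset` (seconds, `0 <= onset < offset`). A zero-row data frame gives
#'   a valid empty score (the simulation holds the neutral posture under it).
#' @param duration Total score duration in seconds; must cover every offset.
#'
#' @return An object of class `sfc_score`: a list with elements `gestures`
#'   (a tibble with `damping` resolved to a number and the original
#'   specification kept in `damping_spec`) and `duration`.
#' @examples
#' gs <- gestural_score(
#'   data.frame(task = "TBCD", target = 0.3, mass = 1, stiffness = 40,
#'              damping = "critical", onset = 0, offset = 0.35),
#'   duration = 0.5
#' )
#' active_set(gs, 0.1)$mask
#' @export
gestural_score <- function(gestures, duration) {
  required <- c("task", "target", "mass", "stiffness", "damping", "onset", "offset")
  if (!is.data.frame(gestures)) {
    abort("`gestures` must be a data frame (one row per gesture).")
  }
  if (nrow(gestures) > 0) {
    missing_cols <- setdiff(required, names(gestures))
    if (length(missing_cols) > 0) {
      abort(paste0("gestural score is missing field(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  } else {
    gestures <- data.frame(task = character(), target = numeric(),
                           mass = numeric(), stiffness = numeric(),
                           damping = numeric(), onset = numeric(),
                           offset = numeric())
  }
  g <- tibble::as_tibble(gestures[required])
  g$task <- as.character(g$task)
  damping_spec <- as.character(g$damping)
  for (col in c("target", "mass", "stiffness", "onset", "offset")) {
    val <- suppressWarnings(as.numeric(g[[col]]))
    if (anyNA(val)) {
      abort(paste0("gestural score field `", col, "` is not numeric (gesture ",
                   paste(which(is.na(val)), collapse = ", "), ")"))
    }
    g[[col]] <- val
  }
  is_critical <- damping_spec == "critical"
  b <- suppressWarnings(as.numeric(damping_spec))
  if (anyNA(b[!is_critical])) {
    bad <- which(!is_critical & is.na(b))
    abort(paste0("gestural score field `damping` must be numeric or \"critical\" (gesture ",
                 paste(bad, collapse = ", "), ")"))
  }
  b[is_critical] <- 2 * sqrt(g$mass[is_critical] * g$stiffness[is_critical])
  g$damping <- b
  g$damping_spec <- damping_spec

  score <- structure(list(gestures = g, duration = as.numeric(duration)),
                     class = "sfc_score")
  validate_score(score)
  score
}

validate_score <- function(score) {
  g <- score$gestures
  dur <- score$duration
  if (!is.finite(dur) || dur < 0) abort("score `duration` must be a non-negative number")
  if (nrow(g) == 0) return(invisible(score))

  bad_task <- !(g$task %in% task_inventory())
  if (any(bad_task)) {
    abort(paste0("unknown task variable(s): ",
                 paste(unique(g$task[bad_task]), collapse = ", "),
                 " (gesture ", paste(which(bad_task), collapse = ", "), ")"))
  }
  if (any(!is.finite(g$mass) | g$mass <= 0)) {
    abort(paste0("gesture mass must be > 0 (gesture ",
                 paste(which(!(g$mass > 0)), collapse = ", "), ")"))
  }
  if (any(!is.finite(g$stiffness) | g$stiffness <= 0)) {
    abort(paste0("gesture stiffness must be > 0 (gesture ",
                 paste(which(!(g$stiffness > 0)), collapse = ", "), ")"))
  }
  if (any(!is.finite(g$damping) | g$damping < 0)) {
    abort(paste0("gesture damping must be >= 0 (gesture ",
                 paste(which(!(g$damping >= 0)), collapse = ", "), ")"))
  }
  if (any(!is.finite(g$target))) {
    abort("gesture targets must be finite")
  }
  bad_interval <- !(g$onset >= 0 & g$offset > g$onset)
  if (any(bad_interval)) {
    abort(paste0("gesture activation must satisfy 0 <= onset < offset (gesture ",
                 paste(which(bad_interval), collapse = ", "), ")"))
  }
  if (dur < max(g$offset)) {
    abort("score `duration` must be >= the largest gesture offset")
  }
  # at most one active gesture per task variable under [onset, offset)
  for (tv in unique(g$task)) {
    gi <- g[g$task == tv, ]
    if (nrow(gi) < 2) next
    gi <- gi[order(gi$onset), ]
    overlap <- gi$onset[-1] < gi$offset[-nrow(gi)]
    if (any(overlap)) {
      abort(paste0("overlapping gestures on task ", tv,
                   ": activation intervals on one task variable must be disjoint"))
    }
  }
  invisible(score)
}

#' @export
print.sfc_score <- function(x, ...) {
  cat("<sfc_score> ", nrow(x$gestures), " gesture(s), duration ",
      x$duration, " s\n", sep = "")
  if (nrow(x$gestures) > 0) print(x$gestures, ...)
  invisible(x)
}

#' Read and write gestural scores as JSON
#'
#' The on-disk score format is a JSON document
#' `{"duration": s, "gestures": [{"task": "TBCD", "target": 0.2, "mass": 1,
#' "stiffness": 40, "damping": "critical", "onset": 0, "offset": 0.35},
#' ...]}`. `parse_score()` accepts a file path or a JSON string and
#' validates all score invariants; `write_score()` serializes a score so
#' that parsing it back yields an equal score (the `"critical"` damping
#' sentinel is preserved).
#'
#' @param text Path to a JSON file, or a literal JSON string.
#' @param score An `sfc_score` object.
#' @param path Output file path; if `NULL`, the JSON text is returned.
#' @return `parse_score()` returns an `sfc_score`; `write_score()` returns
#'   the JSON text invisibly (and writes `path` if given).
#' @export
parse_score <- function(text) {
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = TRUE),
    error = function(e) abort(paste0("malformed score document: ", conditionMessage(e)))
  )
  if (!is.list(doc) || is.null(doc$duration)) {
    abort("malformed score document: missing top-level field `duration`")
  }
  gestures <- doc$gestures
  if (is.null(gestures) || (is.data.frame(gestures) && nrow(gestures) == 0) ||
      (is.list(gestures) && length(gestures) == 0)) {
    gestures <- data.frame()
  }
  gestural_score(gestures, duration = doc$duration)
}

#' @rdname parse_score
#' @export
write_score <- function(score, path = NULL) {
  stopifnot(inherits(score, "sfc_score"))
  g <- score$gestures
  out <- list(
    duration = score$duration,
    gestures = lapply(seq_len(nrow(g)), function(i) {
      damping <- if (g$damping_spec[i] == "critical") "critical" else g$damping[i]
      list(task = g$task[i], target = g$target[i], mass = g$mass[i],
           stiffness = g$stiffness[i], damping = damping,
           onset = g$onset[i], offset = g$offset[i])
    })
  )
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Active gestures and their dynamical parameters at a time point
#'
#' Evaluates the step-function activation of a score at time `t` under the
#' half-open convention: a gesture is active when `onset <= t < offset`.
#' Inactive task variables carry inert placeholder parameters (target at the
#' neutral task posture, unit mass, zero stiffness and damping); the task
#' controller issues a zero command for them, and restoration of
#' uncontrolled degrees of freedom is handled by the articulatory-space
#' null-space attractor instead.
#'
#' @param score An `sfc_score`.
#' @param t Time in seconds, within `[0, duration]`.
#' @return A list with named length-7 components (ordered per
#'   [task_inventory()]): `mask` (logical, active tasks), `x0` (targets),
#'   `m`, `b`, `k` (mass, damping, stiffness).
#' @export
active_set <- function(score, t) {
  stopifnot(inherits(score, "sfc_score"))
  if (!is.finite(t) || t < 0 || t > score$duration) {
    abort(paste0("t = ", t, " outside the score interval [0, ", score$duration, "]"))
  }
  tasks <- task_inventory()
  x_neutral <- forward_kinematics(neutral_posture())
  mask <- setNames(rep(FALSE, length(tasks)), tasks)
  x0 <- x_neutral
  m <- setNames(rep(1, length(tasks)), tasks)
  b <- setNames(rep(0, length(tasks)), tasks)
  k <- setNames(rep(0, length(tasks)), tasks)
  g <- score$gestures
  if (nrow(g) > 0) {
    act <- which(g$onset <= t & t < g$offset)
    for (i in act) {
      tv <- g$task[i]
      mask[tv] <- TRUE
      x0[tv] <- g$target[i]
      m[tv] <- g$mass[i]
      b[tv] <- g$damping[i]
      k[tv] <- g$stiffness[i]
    }
  }
  list(mask = mask, x0 = x0, m = m, b = b, k = k)
}
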