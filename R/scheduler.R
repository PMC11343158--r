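# The patch-walking coordination algorithm: cell queue management,
# nearest-cell assignment, stage/camera arbitration, clean-and-reuse on
# failure, pair formation, and the release-first-whole-cell walk rule.
#
# The scheduler is a deterministic state machine driven by completion events
# (`advance()`); it owns no clock and draws no random numbers, so the same
# event sequence always yields the same log. The Monte Carlo simulator
# supplies event times and outcomes; tests can script them by hand.
#
# Two pipettes ("a" and "b") are supported — the apparatus this workflow was
# designed for. Every patch attempt needs exclusive use of the microscope
# stage and camera during neuron hunting; sealing, break-in and holding
# proceed in parallel.

#' Scheduler configuration
#'
#' @param strategy `"patchwalk"` (clean and advance one pipette at a time,
#'   keeping the other's recording alive) or `"traditional"` (retract both
#'   pipettes after each paired screen).
#' @param hold_limit_min Maximum time a cell is held in whole-cell
#'   configuration while waiting (min); default 45.
#' @param min_tip_separation_um Optional collision radius: a candidate cell
#'   closer than this to the other pipette's held cell is skipped. Default 0
#'   (off).
#' @return A `sched_config` list.
#' @export
scheduler_config <- function(strategy = c("patchwalk", "traditional"),
                             hold_limit_min = 45,
                             min_tip_separation_um = 0) {
  strategy <- match.arg(strategy)
  if (hold_limit_min <= 0) stop_domain("`hold_limit_min` must be positive")
  structure(
    list(strategy = strategy, hold_limit_min = hold_limit_min,
         min_tip_separation_um = min_tip_separation_um),
    class = "sched_config"
  )
}

#' Select the next cell for a pipette
#'
#' When a pipette becomes available it is assigned the queued cell with the
#' shortest 3D Euclidean distance to its home position; ties are broken by
#' lowest cell id. Returns `NA` when the queue is exhausted (the pipette
#' retires). Cells within `min_separation_um` of `avoid` (the other
#' pipette's held cell, when a collision radius is configured) are skipped.
#'
#' @param home Numeric xyz position (um) of the pipette's home.
#' @param cells Cell-map data frame with columns `id`, `x_um`, `y_um`,
#'   `z_um` and a `status` column; only `"queued"` cells are candidates
#'   (absent `status`, all rows are candidates).
#' @param avoid Optional xyz position to keep clear of.
#' @param min_separation_um Collision radius used with `avoid`; default 0.
#' @return Cell id (integer) or `NA_integer_` if no candidate remains.
#' @export
select_next_cell <- function(home, cells, avoid = NULL, min_separation_um = 0) {
  cand <- if ("status" %in% names(cells)) cells[cells$status == "queued", ] else cells
  if (!is.null(avoid) && min_separation_um > 0 && nrow(cand) > 0) {
    d_avoid <- sqrt((cand$x_um - avoid[1])^2 + (cand$y_um - avoid[2])^2 +
                      (cand$z_um - avoid[3])^2)
    cand <- cand[d_avoid >= min_separation_um, ]
  }
  if (nrow(cand) == 0) return(NA_integer_)
  d <- sqrt((cand$x_um - home[1])^2 + (cand$y_um - home[2])^2 +
              (cand$z_um - home[3])^2)
  best <- cand$id[order(d, cand$id)][1]
  as.integer(best)
}

#' Initialize scheduler state
#'
#' @param cells Cell map (columns `id`, `x_um`, `y_um`, `z_um`), e.g. from
#'   [generate_cell_map()] or [read_cell_map()].
#' @param homes Named list of pipette home positions (`a`, `b`); default
#'   [default_home_positions()].
#' @param config A [scheduler_config()].
#' @return A `sched_state` list; feed it to [advance()].
#' @export
scheduler_init <- function(cells, homes = default_home_positions(),
                           config = scheduler_config()) {
  stopifnot(all(c("id", "x_um", "y_um", "z_um") %in% names(cells)))
  if (length(homes) != 2L || !all(c("a", "b") %in% names(homes))) {
    stop_domain("exactly two pipettes, named 'a' and 'b', are supported")
  }
  cells <- cells[order(cells$id), c("id", "x_um", "y_um", "z_um")]
  cells$status <- "queued"
  pip <- function(id, home) {
    list(id = id, home = as.numeric(home[1:3]), stage = "idle",
         held_cell = NA_integer_, whole_cell_since = NA_real_,
         pending_cell = NA_integer_, retired = FALSE)
  }
  structure(
    list(
      time = 0,
      cells = cells,
      pipettes = list(a = pip("a", homes$a), b = pip("b", homes$b)),
      stage_owner = NA_character_,
      stage_wait = character(0),
      pairs = empty_pairs(),
      open_pair = NA_integer_,
      screening = FALSE,
      events = empty_events(),
      config = config,
      done = FALSE
    ),
    class = "sched_state"
  )
}

empty_events <- function() {
  data.frame(t = numeric(0), pipette = character(0), cell = integer(0),
             kind = character(0), cell2 = integer(0), connected = logical(0))
}

empty_pairs <- function() {
  data.frame(pair_id = integer(0), cell_a = integer(0), cell_b = integer(0),
             start = numeric(0), end = numeric(0), distance_um = numeric(0),
             probe_ab = logical(0), probe_ba = logical(0))
}

#' Construct a scheduler event
#'
#' Events report completions to [advance()]: `"start"` (begin the run),
#' `"hunt_done"` (neuron hunting finished; `found`), `"patch_result"`
#' (seal/break-in finished; `success`), `"screen_done"` (connectivity test
#' finished; `connected` is a length-2 logical for the a-cell->b-cell and
#' b-cell->a-cell directions, `NA` for untested), `"clean_done"`, and
#' `"hold_expired"`.
#'
#' @param kind Event kind (see Description).
#' @param t Event time (min).
#' @param pipette Pipette id `"a"` or `"b"` where applicable.
#' @param found,success Logical outcomes for hunt/patch events.
#' @param connected Length-2 logical for `screen_done`.
#' @return A `sched_event` list.
#' @export
sched_event <- function(kind, t, pipette = NULL, found = NULL, success = NULL,
                        connected = NULL) {
  structure(list(kind = kind, t = t, pipette = pipette, found = found,
                 success = success, connected = connected),
            class = "sched_event")
}

# --- internal transition helpers; each returns list(state, actions) --------

log_event <- function(state, t, kind, pipette = NA_character_,
                      cell = NA_integer_, cell2 = NA_integer_,
                      connected = NA) {
  state$events <- rbind(state$events, data.frame(
    t = t, pipette = pipette, cell = as.integer(cell), kind = kind,
    cell2 = as.integer(cell2), connected = connected
  ))
  state
}

other_pipette <- function(pid) if (pid == "a") "b" else "a"

cell_pos <- function(state, id) {
  r <- state$cells[state$cells$id == id, ]
  c(r$x_um, r$y_um, r$z_um)
}

set_cell_status <- function(state, id, status) {
  state$cells$status[state$cells$id == id] <- status
  state
}

# assign the nearest queued cell and request the stage; retire on exhaustion
request_attempt <- function(state, pid, t) {
  actions <- list()
  pip <- state$pipettes[[pid]]
  oth <- state$pipettes[[other_pipette(pid)]]
  avoid <- NULL
  if (state$config$min_tip_separation_um > 0 && !is.na(oth$held_cell)) {
    avoid <- cell_pos(state, oth$held_cell)
  }
  cid <- select_next_cell(pip$home, state$cells, avoid,
                          state$config$min_tip_separation_um)
  if (is.na(cid)) {
    pip$retired <- TRUE
    pip$stage <- "retracted"
    state$pipettes[[pid]] <- pip
    state <- log_event(state, t, "retire", pid)
    actions <- c(actions, list(list(kind = "retire", pipette = pid, t = t)))
    res <- check_stranded(state, t)
    state <- res$state
    actions <- c(actions, res$actions)
    res <- check_termination(state, t)
    return(list(state = res$state, actions = c(actions, res$actions)))
  }
  state <- set_cell_status(state, cid, "assigned")
  pip$pending_cell <- cid
  state$pipettes[[pid]] <- pip
  state <- log_event(state, t, "assign", pid, cid)
  grant_or_defer(state, pid, t, actions)
}

# stage/camera arbitration: at most one pipette hunts at a time
grant_or_defer <- function(state, pid, t, actions = list()) {
  pip <- state$pipettes[[pid]]
  if (is.na(state$stage_owner)) {
    state$stage_owner <- pid
    pip$stage <- "hunting"
    state$pipettes[[pid]] <- pip
    state <- log_event(state, t, "hunt_start", pid, pip$pending_cell)
    actions <- c(actions, list(list(kind = "hunt", pipette = pid,
                                    cell = pip$pending_cell, t = t)))
  } else {
    state$stage_wait <- c(state$stage_wait, pid)
    pip$stage <- "waiting_stage"
    state$pipettes[[pid]] <- pip
    state <- log_event(state, t, "hunt_deferred", pid, pip$pending_cell)
  }
  list(state = state, actions = actions)
}

release_stage <- function(state, pid, t) {
  actions <- list()
  if (identical(state$stage_owner, pid)) state$stage_owner <- NA_character_
  if (is.na(state$stage_owner) && length(state$stage_wait) > 0) {
    nxt <- state$stage_wait[1]
    state$stage_wait <- state$stage_wait[-1]
    res <- grant_or_defer(state, nxt, t)
    state <- res$state
    actions <- res$actions
  }
  list(state = state, actions = actions)
}

fail_attempt <- function(state, pid, t) {
  pip <- state$pipettes[[pid]]
  state <- set_cell_status(state, pip$pending_cell, "failed")
  state <- log_event(state, t, "fail", pid, pip$pending_cell)
  pip$pending_cell <- NA_integer_
  pip$stage <- "cleaning"
  state$pipettes[[pid]] <- pip
  state <- log_event(state, t, "clean_start", pid)
  list(state = state,
       actions = list(list(kind = "clean", pipette = pid, t = t)))
}

release_cell <- function(state, pid, t, terminal_status = "released") {
  pip <- state$pipettes[[pid]]
  if (!is.na(pip$held_cell)) {
    state <- set_cell_status(state, pip$held_cell, terminal_status)
    state <- log_event(state, t, "release", pid, pip$held_cell)
    # close any pair still open on this cell
    if (!is.na(state$open_pair)) state$open_pair <- NA_integer_
    op <- which(is.na(state$pairs$end) &
                  (state$pairs$cell_a == pip$held_cell |
                     state$pairs$cell_b == pip$held_cell))
    if (length(op)) state$pairs$end[op] <- t
    pip$held_cell <- NA_integer_
    pip$whole_cell_since <- NA_real_
    state$pipettes[[pid]] <- pip
  }
  state
}

# a pipette holding a cell whose partner has retired can never pair again
check_stranded <- function(state, t) {
  actions <- list()
  for (pid in c("a", "b")) {
    pip <- state$pipettes[[pid]]
    oth <- state$pipettes[[other_pipette(pid)]]
    if (pip$stage == "whole_cell" && oth$retired && !state$screening) {
      state <- release_cell(state, pid, t)
      pip <- state$pipettes[[pid]]
      pip$retired <- TRUE
      pip$stage <- "retracted"
      state$pipettes[[pid]] <- pip
      state <- log_event(state, t, "retire", pid)
      actions <- c(actions, list(list(kind = "retire", pipette = pid, t = t)))
    }
  }
  list(state = state, actions = actions)
}

check_termination <- function(state, t) {
  actions <- list()
  if (!state$done && all(vapply(state$pipettes, `[[`, TRUE, "retired"))) {
    state$done <- TRUE
    state <- log_event(state, t, "end")
    actions <- list(list(kind = "done", t = t))
  }
  list(state = state, actions = actions)
}

send_to_clean <- function(state, pid, t) {
  pip <- state$pipettes[[pid]]
  pip$stage <- "cleaning"
  state$pipettes[[pid]] <- pip
  state <- log_event(state, t, "clean_start", pid)
  list(state = state,
       actions = list(list(kind = "clean", pipette = pid, t = t)))
}

#' Advance the scheduler by one event
#'
#' Encodes the patch-walking control flow: on a failed attempt the pipette
#' is cleaned and assigned the next closest queued cell; a pipette that
#' reaches whole-cell holds while the other proceeds; when both hold, a
#' connectivity test is requested and a paired recording is logged; after
#' the test the pipette whose whole-cell recording started earliest is
#' released to clean and walk on (patch-walking) or both are retracted
#' (traditional). The stage and camera are granted to at most one hunting
#' pipette; a simultaneous request is deferred until the stage frees.
#'
#' @param state A `sched_state` from [scheduler_init()].
#' @param event A [sched_event()].
#' @return `list(state = <new state>, actions = <list of requested
#'   actions>)`. Action kinds: `"hunt"`, `"patch"`, `"screen"`, `"clean"`,
#'   `"hold"` (schedule a hold-limit check), `"retire"`, `"done"`.
#' @export
advance <- function(state, event) {
  stopifnot(inherits(state, "sched_state"), inherits(event, "sched_event"))
  t <- event$t
  state$time <- max(state$time, t)
  pid <- event$pipette
  if (!is.null(pid)) {
    if (!pid %in% c("a", "b")) stop_domain("unknown pipette: ", pid)
    if (state$pipettes[[pid]]$retired && event$kind != "hold_expired") {
      stop_domain("protocol error: event for retired pipette ", pid)
    }
  }
  actions <- list()

  if (event$kind == "start") {
    for (p in c("a", "b")) {
      res <- request_attempt(state, p, t)
      state <- res$state
      actions <- c(actions, res$actions)
    }
  } else if (event$kind == "hunt_done") {
    res <- release_stage(state, pid, t)
    state <- res$state
    actions <- c(actions, res$actions)
    state <- log_event(state, t, "hunt_done", pid,
                       state$pipettes[[pid]]$pending_cell)
    if (isTRUE(event$found)) {
      pip <- state$pipettes[[pid]]
      pip$stage <- "patching"
      state$pipettes[[pid]] <- pip
      actions <- c(actions, list(list(kind = "patch", pipette = pid,
                                      cell = pip$pending_cell, t = t)))
    } else {
      res <- fail_attempt(state, pid, t)
      state <- res$state
      actions <- c(actions, res$actions)
    }
  } else if (event$kind == "patch_result") {
    if (isTRUE(event$success)) {
      pip <- state$pipettes[[pid]]
      cid <- pip$pending_cell
      state <- set_cell_status(state, cid, "whole_cell")
      pip$held_cell <- cid
      pip$pending_cell <- NA_integer_
      pip$whole_cell_since <- t
      pip$stage <- "whole_cell"
      state$pipettes[[pid]] <- pip
      state <- log_event(state, t, "whole_cell", pid, cid)
      actions <- c(actions, list(list(kind = "hold", pipette = pid,
                                      until = t + state$config$hold_limit_min)))
      oth <- state$pipettes[[other_pipette(pid)]]
      if (oth$stage == "whole_cell") {
        # both pipettes hold: form a paired recording and screen it
        ca <- state$pipettes$a$held_cell
        cb <- state$pipettes$b$held_cell
        dist <- dist3(cell_pos(state, ca), cell_pos(state, cb))
        state$pairs <- rbind(state$pairs, data.frame(
          pair_id = nrow(state$pairs) + 1L, cell_a = ca, cell_b = cb,
          start = t, end = NA_real_, distance_um = dist,
          probe_ab = NA, probe_ba = NA
        ))
        state$open_pair <- nrow(state$pairs)
        state$screening <- TRUE
        state <- log_event(state, t, "pair_start", NA, ca, cb)
        actions <- c(actions, list(list(
          kind = "screen", cell_a = ca, cell_b = cb, distance_um = dist, t = t
        )))
      } else if (oth$retired) {
        # no partner will ever hold again; record the cell and wind down
        state <- release_cell(state, pid, t)
        pip <- state$pipettes[[pid]]
        pip$retired <- TRUE
        pip$stage <- "retracted"
        state$pipettes[[pid]] <- pip
        state <- log_event(state, t, "retire", pid)
        actions <- c(actions, list(list(kind = "retire", pipette = pid, t = t)))
        res <- check_termination(state, t)
        state <- res$state
        actions <- c(actions, res$actions)
      }
    } else {
      res <- fail_attempt(state, pid, t)
      state <- res$state
      actions <- c(actions, res$actions)
    }
  } else if (event$kind == "screen_done") {
    if (is.na(state$open_pair)) stop_domain("screen_done without an open pair")
    k <- state$open_pair
    conn <- event$connected
    if (is.null(conn)) conn <- c(NA, NA)
    state$pairs$probe_ab[k] <- conn[1]
    state$pairs$probe_ba[k] <- conn[2]
    ca <- state$pairs$cell_a[k]
    cb <- state$pairs$cell_b[k]
    state <- log_event(state, t, "probe", "a", ca, cb, conn[1])
    state <- log_event(state, t, "probe", "b", cb, ca, conn[2])
    state$screening <- FALSE
    if (state$config$strategy == "patchwalk") {
      # release the pipette that reached whole cell first; it walks on
      since_a <- state$pipettes$a$whole_cell_since
      since_b <- state$pipettes$b$whole_cell_since
      rel <- if (since_a <= since_b) "a" else "b"
      state$pairs$end[k] <- t
      state$open_pair <- NA_integer_
      state <- release_cell(state, rel, t)
      res <- send_to_clean(state, rel, t)
      state <- res$state
      actions <- c(actions, res$actions)
    } else {
      state$pairs$end[k] <- t
      state$open_pair <- NA_integer_
      for (p in c("a", "b")) {
        state <- release_cell(state, p, t)
        res <- send_to_clean(state, p, t)
        state <- res$state
        actions <- c(actions, res$actions)
      }
    }
  } else if (event$kind == "clean_done") {
    pip <- state$pipettes[[pid]]
    pip$stage <- "idle"
    state$pipettes[[pid]] <- pip
    state <- log_event(state, t, "clean_done", pid)
    res <- request_attempt(state, pid, t)
    state <- res$state
    actions <- c(actions, res$actions)
  } else if (event$kind == "hold_expired") {
    pip <- state$pipettes[[pid]]
    # stale unless the pipette still holds and the limit has truly elapsed
    if (!pip$retired && pip$stage == "whole_cell" && !state$screening &&
        !is.na(pip$whole_cell_since) &&
        (t - pip$whole_cell_since) >= state$config$hold_limit_min - 1e-9) {
      state <- log_event(state, t, "hold_expired", pid, pip$held_cell)
      state <- release_cell(state, pid, t)
      res <- send_to_clean(state, pid, t)
      state <- res$state
      actions <- c(actions, res$actions)
    }
  } else {
    stop_domain("unknown event kind: ", event$kind)
  }

  list(state = state, actions = actions)
}

#' Reconstruct paired recordings from an event log
#'
#' A paired recording is a maximal interval during which two distinct cells
#' are simultaneously held in whole-cell configuration. Holding intervals
#' are rebuilt per pipette from `whole_cell` and `release` events; their
#' pairwise overlaps of positive duration across the two pipettes are the
#' paired recordings. Each pair contributes two directed probed connections;
#' probe outcomes logged during the interval are attached (directions with
#' no probe event remain untested).
#'
#' @param log A `patchwalk_log` from [simulate_experiment()], or a raw event
#'   data frame with columns `t`, `pipette`, `cell`, `kind` (optionally
#'   `cell2`, `connected`).
#' @param cells Optional cell map used to attach intersomatic distances.
#' @return A data frame of pairs (`cell_a`, `cell_b`, `start`, `end`,
#'   `distance_um`, `probe_ab`, `probe_ba`) with attribute
#'   `probed_connections` `= 2 *` number of pairs.
#' @export
pairs_from_log <- function(log, cells = NULL) {
  events <- if (inherits(log, "patchwalk_log")) log$events else log
  if (is.null(cells) && inherits(log, "patchwalk_log")) cells <- log$cells
  stopifnot(all(c("t", "pipette", "cell", "kind") %in% names(events)))
  events <- events[order(events$t), ]
  t_end <- if (nrow(events)) max(events$t) else 0
  holds <- function(pid) {
    ev <- events[events$pipette %in% pid &
                   events$kind %in% c("whole_cell", "release"), ]
    out <- data.frame(cell = integer(0), start = numeric(0), end = numeric(0))
    open_cell <- NA_integer_
    open_t <- NA_real_
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "whole_cell") {
        if (!is.na(open_cell)) {
          stop_domain("log integrity error: pipette ", pid,
                      " enters whole cell while already holding")
        }
        open_cell <- ev$cell[i]
        open_t <- ev$t[i]
      } else {
        if (is.na(open_cell) || open_cell != ev$cell[i]) {
          stop_domain("log integrity error: pipette ", pid,
                      " releases a cell it does not hold")
        }
        out <- rbind(out, data.frame(cell = open_cell, start = open_t,
                                     end = ev$t[i]))
        open_cell <- NA_integer_
      }
    }
    if (!is.na(open_cell)) {
      out <- rbind(out, data.frame(cell = open_cell, start = open_t,
                                   end = t_end))
    }
    out
  }
  ha <- holds("a")
  hb <- holds("b")
  pairs <- empty_pairs()
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) {
      s <- max(ha$start[i], hb$start[j])
      e <- min(ha$end[i], hb$end[j])
      if (e > s && ha$cell[i] != hb$cell[j]) {
        dist <- NA_real_
        if (!is.null(cells)) {
          pa <- cells[cells$id == ha$cell[i], ]
          pb <- cells[cells$id == hb$cell[j], ]
          if (nrow(pa) && nrow(pb)) {
            dist <- dist3(c(pa$x_um, pa$y_um, pa$z_um),
                          c(pb$x_um, pb$y_um, pb$z_um))
          }
        }
        probe <- function(pre, post) {
          if (!all(c("cell2", "connected") %in% names(events))) return(NA)
          hit <- events$kind == "probe" & events$cell %in% pre &
            events$cell2 %in% post & events$t >= s & events$t <= e
          if (any(hit)) events$connected[which(hit)[1]] else NA
        }
        pairs <- rbind(pairs, data.frame(
          pair_id = nrow(pairs) + 1L, cell_a = ha$cell[i], cell_b = hb$cell[j],
          start = s, end = e, distance_um = dist,
          probe_ab = probe(ha$cell[i], hb$cell[j]),
          probe_ba = probe(hb$cell[j], ha$cell[i])
        ))
      }
    }
  }
  attr(pairs, "probed_connections") <- 2L * nrow(pairs)
  pairs
}
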