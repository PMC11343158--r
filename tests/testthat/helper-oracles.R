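# Independent counting oracles and a deterministic scheduler driver used
# across test files.

# Enumerate the probes of an ideal patch-walk: hold p cells, probe all
# ordered pairs among the initial p, then for each new cell release the
# oldest hold and probe the newcomer against the p - 1 held cells in both
# directions. Returns the count of directed probed connections.
walk_count_oracle <- function(n, p) {
  held <- seq_len(p)
  cnt <- length(held) * (length(held) - 1)
  if (n > p) {
    for (j in seq.int(p + 1, n)) {
      held <- c(held[-1], j)
      cnt <- cnt + 2 * (p - 1)
    }
  }
  cnt
}

# Enumerate traditional probing: consecutive groups of p cells, all ordered
# pairs within each group (the last group may be smaller).
traditional_count_oracle <- function(n, p) {
  groups <- split(seq_len(n), ceiling(seq_len(n) / p))
  sum(vapply(groups, function(g) length(g) * (length(g) - 1), numeric(1)))
}

# Drive the scheduler state machine with fixed unit durations and scripted
# outcomes; no randomness. success_fn(pipette, cell) decides each patch
# attempt; screen_fn(cell_a, cell_b) returns the two directed outcomes.
run_deterministic <- function(cells,
                              success_fn = function(pipette, cell) TRUE,
                              strategy = "patchwalk",
                              hold_limit_min = 45,
                              screen_fn = function(ca, cb) c(FALSE, FALSE),
                              homes = default_home_positions()) {
  st <- scheduler_init(cells, homes,
                       scheduler_config(strategy, hold_limit_min))
  queue <- list()
  push <- function(ev) queue[[length(queue) + 1L]] <<- ev
  handle <- function(actions) {
    for (act in actions) {
      if (act$kind == "hunt") {
        push(sched_event("hunt_done", act$t + 1, act$pipette, found = TRUE))
      } else if (act$kind == "patch") {
        push(sched_event("patch_result", act$t + 1, act$pipette,
                         success = success_fn(act$pipette, act$cell)))
      } else if (act$kind == "screen") {
        push(sched_event("screen_done", act$t + 1,
                         connected = screen_fn(act$cell_a, act$cell_b)))
      } else if (act$kind == "clean") {
        push(sched_event("clean_done", act$t + 1, act$pipette))
      } else if (act$kind == "hold") {
        push(sched_event("hold_expired", act$until, act$pipette))
      }
    }
  }
  r <- advance(st, sched_event("start", 0))
  st <- r$state
  handle(r$actions)
  iter <- 0L
  while (length(queue) > 0 && !st$done) {
    iter <- iter + 1L
    if (iter > 10000L) stop("scripted run failed to terminate")
    ts <- vapply(queue, `[[`, numeric(1), "t")
    i <- which.min(ts)
    ev <- queue[[i]]
    queue[[i]] <- NULL
    if (ev$kind == "hold_expired" && st$pipettes[[ev$pipette]]$retired) next
    r <- advance(st, ev)
    st <- r$state
    handle(r$actions)
  }
  st
}

# A line of n cells along x: pipette a (home x = 0) walks from the left,
# pipette b (home x = 200) from the right.
line_cells <- function(n, spacing = 180 / max(n - 1, 1)) {
  data.frame(id = seq_len(n), x_um = 10 + spacing * (seq_len(n) - 1),
             y_um = 100, z_um = 50)
}

# Build a raw event log with k co-held pair intervals (and no other events).
pair_interval_log <- function(k, connected = rep(NA, k)) {
  rows <- lapply(seq_len(k), function(i) {
    t0 <- 10 * i
    ca <- 2L * i - 1L
    cb <- 2L * i
    df <- data.frame(
      t = t0 + c(0, 1, 2, 3),
      pipette = c("a", "b", "a", "b"),
      cell = c(ca, cb, ca, cb),
      kind = c("whole_cell", "whole_cell", "release", "release"),
      cell2 = NA_integer_, connected = NA
    )
    probes <- data.frame(
      t = t0 + 1.5, pipette = c("a", "b"), cell = c(ca, cb),
      kind = "probe", cell2 = c(cb, ca),
      connected = c(connected[i], FALSE)
    )
    rbind(df, probes)
  })
  do.call(rbind, rows)
}
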