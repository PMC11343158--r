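# Seeded Monte Carlo discrete-event simulation of full patch-walking or
# traditional multi-patch experiments. The simulator owns the clock and all
# randomness; scheduling decisions are delegated to the deterministic
# scheduler state machine, so a (config, seed) pair fully determines the run.

#' Simulation configuration
#'
#' Stage durations are drawn from gamma distributions parameterized by mean
#' and SD in minutes (a point mass when SD = 0). Defaults place the emergent
#' time to achieve a paired recording at roughly ten minutes, the operating
#' regime of a two-pipette cortical slice experiment.
#'
#' @param n_cells Number of cells in the map; default 9 (one slice's worth).
#' @param n_pipettes Number of pipettes; only 2 is supported.
#' @param strategy `"patchwalk"` or `"traditional"`.
#' @param success_prob Whole-cell success probability per patch attempt;
#'   default 0.522.
#' @param stage_durations Named list of `c(mean, sd)` minutes for `hunt`,
#'   `seal`, `break_in`, `clean`, `screen`.
#' @param hold_limit_min Maximum whole-cell hold time; default 45 min.
#' @param model Connectivity model used to draw directed connections from
#'   intersomatic distance; default [default_connectivity_model()].
#' @param min_tip_separation_um Optional collision radius (see
#'   [scheduler_config()]); default 0.
#' @param cells Optional cell map; if `NULL` one is generated per run from
#'   the seed.
#' @param field_um,depth_band_um,min_separation_um Cell-map geometry passed
#'   to [generate_cell_map()] when `cells` is `NULL`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 9L, n_pipettes = 2L,
                       strategy = c("patchwalk", "traditional"),
                       success_prob = 0.522,
                       stage_durations = list(
                         hunt = c(2, 1), seal = c(3, 2),
                         break_in = c(0.5, 0.25), clean = c(1.5, 0.5),
                         screen = c(2, 0.5)
                       ),
                       hold_limit_min = 45,
                       model = default_connectivity_model(),
                       min_tip_separation_um = 0,
                       cells = NULL,
                       field_um = c(200, 200), depth_band_um = c(20, 100),
                       min_separation_um = 15) {
  strategy <- match.arg(strategy)
  if (check_count(n_pipettes, "n_pipettes", min = 2L) != 2L) {
    stop_domain("only a two-pipette apparatus is supported by the simulator")
  }
  success_prob <- check_prob(success_prob, "success_prob")
  for (nm in c("hunt", "seal", "break_in", "clean", "screen")) {
    d <- stage_durations[[nm]]
    if (is.null(d) || length(d) != 2 || d[1] <= 0 || d[2] < 0) {
      stop_domain("stage_durations$", nm, " must be c(mean > 0, sd >= 0)")
    }
  }
  structure(
    list(n_cells = check_count(n_cells, "n_cells", min = 2L),
         n_pipettes = 2L, strategy = strategy, success_prob = success_prob,
         stage_durations = stage_durations, hold_limit_min = hold_limit_min,
         model = model, min_tip_separation_um = min_tip_separation_um,
         cells = cells, field_um = field_um, depth_band_um = depth_band_um,
         min_separation_um = min_separation_um),
    class = "sim_config"
  )
}

draw_duration <- function(spec) {
  m <- spec[1]
  s <- spec[2]
  if (s == 0) return(m)
  shape <- (m / s)^2
  stats::rgamma(1, shape = shape, rate = shape / m)
}

#' Simulate one experiment
#'
#' Runs an event-driven experiment: patch attempt outcomes are
#' Bernoulli(`success_prob`), stage durations come from the configured gamma
#' distributions, scheduling follows the patch-walking (or traditional)
#' rules, and each directed probe of a paired recording is drawn
#' Bernoulli(`connection_probability(distance)`). Fully reproducible under
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return A `patchwalk_log`: list with `events` (data frame), `cells`,
#'   `pairs`, `config`, `seed`, `total_time_min`.
#' @export
simulate_experiment <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) stop_domain("`seed` is mandatory")
  cells <- config$cells
  if (is.null(cells)) {
    cells <- generate_cell_map(
      n_cells = config$n_cells, field_um = config$field_um,
      depth_band_um = config$depth_band_um,
      min_separation_um = config$min_separation_um, seed = seed
    )
  }
  set.seed(seed)
  sched <- scheduler_init(
    cells, default_home_positions(config$field_um),
    scheduler_config(config$strategy, config$hold_limit_min,
                     config$min_tip_separation_um)
  )

  queue <- list()   # pending events: sched_event objects
  push <- function(ev) queue[[length(queue) + 1L]] <<- ev
  pop <- function() {
    ts <- vapply(queue, `[[`, numeric(1), "t")
    i <- which.min(ts)  # FIFO among ties: which.min takes the first
    ev <- queue[[i]]
    queue[[i]] <<- NULL
    ev
  }

  dur <- config$stage_durations
  handle_actions <- function(actions) {
    for (act in actions) {
      if (act$kind == "hunt") {
        push(sched_event("hunt_done", act$t + draw_duration(dur$hunt),
                         pipette = act$pipette, found = TRUE))
      } else if (act$kind == "patch") {
        success <- stats::runif(1) < config$success_prob
        d <- draw_duration(dur$seal) + draw_duration(dur$break_in)
        push(sched_event("patch_result", act$t + d, pipette = act$pipette,
                         success = success))
      } else if (act$kind == "screen") {
        q <- connection_probability(act$distance_um, config$model)
        conn <- stats::runif(2) < q
        push(sched_event("screen_done", act$t + draw_duration(dur$screen),
                         connected = conn))
      } else if (act$kind == "clean") {
        push(sched_event("clean_done", act$t + draw_duration(dur$clean),
                         pipette = act$pipette))
      } else if (act$kind == "hold") {
        push(sched_event("hold_expired", act$until, pipette = act$pipette))
      }
      # "retire" and "done" need no scheduled follow-up
    }
  }

  res <- advance(sched, sched_event("start", 0))
  sched <- res$state
  handle_actions(res$actions)
  iter <- 0L
  while (length(queue) > 0 && !sched$done) {
    iter <- iter + 1L
    if (iter > 100000L) stop("simulation failed to terminate")
    ev <- pop()
    if (ev$kind == "hold_expired" && sched$pipettes[[ev$pipette]]$retired) next
    res <- advance(sched, ev)
    sched <- res$state
    handle_actions(res$actions)
  }

  structure(
    list(events = sched$events, cells = cells, pairs = sched$pairs,
         config = config, seed = seed, total_time_min = sched$time),
    class = "patchwalk_log"
  )
}

#' @export
print.patchwalk_log <- function(x, ...) {
  s <- summarize_log(x)
  cat(sprintf(
    "Patch-clamp experiment log (%s, %d cells, seed %d)\n", x$config$strategy,
    nrow(x$cells), x$seed
  ))
  cat(sprintf(
    "  attempts %d | whole cells %d (%.1f%%) | pairs %d | probed %d | found %d | %.1f min\n",
    s$attempts, s$whole_cells, s$success_rate_pct, s$pairs,
    s$probed_connections, s$found_connections, s$total_time_min
  ))
  invisible(x)
}

#' Summarize an experiment log
#'
#' Tallies patch attempts (whole cells + failures), whole-cell successes,
#' the success rate as a percentage to one decimal, paired recordings,
#' probed connections (twice the pairs), found connections, and run time.
#' Also returns per-pair timing inputs (`time_to_pair_min`) as an attribute
#' for histogramming.
#'
#' @param log A `patchwalk_log`, or a raw event data frame (pairs are then
#'   reconstructed with [pairs_from_log()]).
#' @return A one-row data frame with columns `attempts`, `whole_cells`,
#'   `success_rate_pct`, `pairs`, `probed_connections`,
#'   `found_connections`, `total_time_min`.
#' @export
summarize_log <- function(log) {
  events <- if (inherits(log, "patchwalk_log")) log$events else log
  stopifnot(all(c("t", "pipette", "cell", "kind") %in% names(events)))
  pairs <- if (inherits(log, "patchwalk_log")) log$pairs else pairs_from_log(events)
  wc <- sum(events$kind == "whole_cell")
  fl <- sum(events$kind == "fail")
  attempts <- wc + fl
  found <- if ("connected" %in% names(events)) {
    sum(events$connected[events$kind == "probe"], na.rm = TRUE)
  } else 0L
  out <- data.frame(
    attempts = attempts, whole_cells = wc,
    success_rate_pct = if (attempts > 0) round(100 * wc / attempts, 1) else 0,
    pairs = nrow(pairs), probed_connections = 2L * nrow(pairs),
    found_connections = as.integer(found),
    total_time_min = if (nrow(events)) max(events$t) else 0
  )
  if (nrow(pairs)) {
    starts <- sort(pairs$start)
    attr(out, "time_to_pair_min") <- c(starts[1], diff(starts))
  }
  out
}

#' Compare strategies over Monte Carlo replicates
#'
#' Runs paired-seed replicates of the patch-walking and traditional
#' strategies on identical cell maps and reports per-replicate tallies,
#' means, and the empirical improvement in probed connections. With
#' `success_prob = 1` and deterministic durations the improvement equals the
#' closed-form `improvement(n, p)` from the yield model.
#'
#' @param config A [sim_config()]; its `strategy` field is overridden.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Base integer seed; replicate `i` uses `seed + i`.
#' @return A `strategy_summary` list: `replicates` (data frame with one row
#'   per replicate and strategy), `means` (per-strategy means), and
#'   `improvement_fraction` (mean patch-walking probes over mean traditional
#'   probes, minus one).
#' @export
compare_strategies <- function(config, n_reps = 20L, seed = 1L) {
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  rows <- list()
  for (i in seq_len(n_reps)) {
    for (strat in c("traditional", "patchwalk")) {
      cfg <- config
      cfg$strategy <- strat
      log <- simulate_experiment(cfg, seed = seed + i)
      s <- summarize_log(log)
      s$strategy <- strat
      s$replicate <- i
      rows[[length(rows) + 1L]] <- s
    }
  }
  reps <- do.call(rbind, rows)
  num <- c("attempts", "whole_cells", "pairs", "probed_connections",
           "found_connections", "total_time_min")
  means <- aggregate(reps[num], by = list(strategy = reps$strategy), FUN = mean)
  mp <- means$probed_connections[means$strategy == "patchwalk"]
  mt <- means$probed_connections[means$strategy == "traditional"]
  structure(
    list(replicates = reps, means = means,
         improvement_fraction = if (mt > 0) mp / mt - 1 else NA_real_),
    class = "strategy_summary"
  )
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat("Strategy comparison over", max(x$replicates$replicate), "replicates\n")
  print(x$means, row.names = FALSE)
  cat(sprintf("Improvement (probed connections): %.1f%%\n",
              100 * x$improvement_fraction))
  invisible(x)
}
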