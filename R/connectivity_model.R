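# Distance-dependent synaptic connection probability and binomial yield
# statistics over probed connections.

#' Exponential distance-decay connectivity model
#'
#' Connection probability between two cortical neurons falls off with
#' intersomatic distance. This constructor builds the two-parameter
#' exponential form `P(d) = a * exp(-d / lambda)`: `a` is the probability at
#' zero distance and `lambda` the decay length in micrometres. The model
#' object is pluggable — any object with a `predict` method mapping distance
#' (um) to probability can stand in wherever a connectivity model is taken.
#'
#' @param amplitude Probability at zero distance, in (0, 1].
#' @param length_scale_um Decay constant lambda in micrometres (> 0).
#' @return An object of class `decay_model`.
#' @seealso [calibrate_decay_model()], [connection_probability()]
#' @export
exp_decay_model <- function(amplitude, length_scale_um) {
  amplitude <- check_prob(amplitude, "amplitude")
  if (amplitude <= 0) stop_domain("`amplitude` must be in (0, 1]")
  if (!is.numeric(length_scale_um) || length(length_scale_um) != 1L ||
      is.na(length_scale_um) || length_scale_um <= 0) {
    stop_domain("`length_scale_um` must be a positive number")
  }
  structure(
    list(amplitude = amplitude, length_scale_um = as.numeric(length_scale_um)),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "Exponential distance-decay connectivity model\n  P(d) = %.4f * exp(-d / %.2f um)\n",
    x$amplitude, x$length_scale_um
  ))
  invisible(x)
}

#' @export
predict.decay_model <- function(object, distance_um, ...) {
  if (any(distance_um < 0, na.rm = TRUE)) {
    stop_domain("`distance_um` must be non-negative")
  }
  p <- object$amplitude * exp(-distance_um / object$length_scale_um)
  pmin(pmax(p, 0), 1)
}

#' Calibrate an exponential decay model through two anchor points
#'
#' Two (distance, probability) anchors identify the exponential model
#' exactly: `lambda = (d2 - d1) / log(p1 / p2)` and
#' `a = p1 * exp(d1 / lambda)`.
#'
#' @param d_um Numeric length-2 vector of anchor distances (um).
#' @param p Numeric length-2 vector of anchor probabilities.
#' @return A `decay_model` passing exactly through both anchors.
#' @export
calibrate_decay_model <- function(d_um, p) {
  stopifnot(length(d_um) == 2L, length(p) == 2L)
  if (any(p <= 0) || any(p > 1)) stop_domain("anchor probabilities must be in (0, 1]")
  if (d_um[1] == d_um[2] || p[1] == p[2]) {
    stop_domain("anchors must differ in both distance and probability")
  }
  lambda <- (d_um[2] - d_um[1]) / log(p[1] / p[2])
  if (lambda <= 0) stop_domain("anchors imply a non-decreasing model")
  exp_decay_model(p[1] * exp(d_um[1] / lambda), lambda)
}

#' Default cortical connectivity model
#'
#' The exponential decay calibrated to two published operating points for
#' local cortical circuits: 16.9% connection probability at 91.6 um
#' intersomatic distance and 10% at 200 um. The solved parameters are
#' a = 0.263 at zero distance and lambda = 206.6 um.
#'
#' @return A calibrated `decay_model`.
#' @export
default_connectivity_model <- function() {
  calibrate_decay_model(d_um = c(91.6, 200), p = c(0.169, 0.10))
}

#' Connection probability at an intersomatic distance
#'
#' @param distance_um Intersomatic distance(s) in micrometres (>= 0).
#' @param model A connectivity model; defaults to
#'   [default_connectivity_model()].
#' @return Probability in \[0, 1\], vectorized over `distance_um`.
#' @examples
#' connection_probability(91.6)  # 0.169
#' connection_probability(200)   # 0.100
#' @export
connection_probability <- function(distance_um, model = default_connectivity_model()) {
  stats::predict(model, distance_um)
}

#' Binomial probability of finding at least k connections
#'
#' Exact upper tail `P(X >= k)` for `X ~ Binomial(m, q)`: the chance of
#' finding at least `k` synaptic connections among `m` independent probed
#' connections each succeeding with probability `q`. Computed from the exact
#' binomial distribution, not a normal approximation.
#'
#' @param m Number of independent probes (>= 0).
#' @param q Per-probe connection probability.
#' @param k Threshold count of found connections.
#' @return `P(X >= k)`; 1 for `k <= 0`, 0 for `k > m`.
#' @examples
#' prob_at_least_k(29, 0.169, 3)  # 0.889..., prints as 89%
#' prob_at_least_k(6, 0.169, 1)   # 0.671: >=1 connection in 3 pairs probed
#'                                # bidirectionally
#' @export
prob_at_least_k <- function(m, q, k) {
  m <- check_count(m, "m", min = 0L)
  q <- check_prob(q, "q")
  k <- check_count(k, "k", min = 0L)
  if (k == 0L) return(1)
  if (k > m) return(0)
  stats::pbinom(k - 1L, size = m, prob = q, lower.tail = FALSE)
}

#' Expected number of found connections
#'
#' @inheritParams prob_at_least_k
#' @return `m * q`.
#' @export
expected_connections <- function(m, q) {
  m <- check_count(m, "m", min = 0L)
  q <- check_prob(q, "q")
  m * q
}
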