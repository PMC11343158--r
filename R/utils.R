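# internal argument checks -----------------------------------------------

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_domain(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_domain(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

# Euclidean distance between two xyz points (um)
dist3 <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}
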