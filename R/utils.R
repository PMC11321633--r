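# Internal helpers shared across modules.

# Canonical timepoint labels for the multi-timepoint metastasis design:
# parental culture plus four post-inoculation collection times.
TIMEPOINTS_SC <- c("parental", "6h", "48h", "2mo", "4mo")

# Colony-count collection times (lung sections).
TIMEPOINTS_COLONY <- c("2h", "6h", "24h", "48h", "1wk", "2mo", "4mo")

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "mictrack_config_error")
}

check_fraction <- function(x, field, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0 | x > 1) else (is.na(x) | x < 0 | x > 1)
  if (!is.numeric(x) || any(bad)) {
    stop_config(field, "must lie in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok) stop_config(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

# Deterministic substream seed derived from a top-level seed and a stream
# name, so that e.g. adding genes never perturbs cell-level assignments.
# Kept below 2^31 - 1 to stay a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629L)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Mean of a negative binomial with given size (dispersion) whose zero mass
# equals p0: solves (size / (size + mu))^size = p0 in closed form.
nb_mean_for_zero_prob <- function(p0, size) {
  if (any(p0 <= 0 | p0 >= 1)) {
    stop_config("dropout zero-probability", "must lie strictly in (0, 1)")
  }
  size * (p0^(-1 / size) - 1)
}
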