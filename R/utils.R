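# Internal helpers shared across modules.

# Input errors (bad user data / arguments) are signalled with a dedicated
# condition class so the CLI can map them to exit code 1 and everything else
# to exit code 2.
stop_input <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c("cropsuit_input_error", "cropsuit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_input_error <- function(e) inherits(e, "cropsuit_input_error")

# Round half away from zero. base::round() ties to even, which is the wrong
# convention for reporting ("10.5%" should print as 11, not 10).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Population (denominator n) standard deviation; keeps rsr^2 + me == 1 exact.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derived from a master seed and a stable label, so
# each generator consumes its own stream and adding a generator does not
# perturb the others. Result always in [1, 2^31 - 2].
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# The five canonical criterion names, in canonical order.
CRITERIA <- c("temperature", "rainfall", "solar_radiation", "soil_ph", "drainage_class")

# Mean Earth radius (km) used for spherical cell areas.
EARTH_RADIUS_KM <- 6371.0072
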