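# Shared fixtures and independent scalar oracles. The oracles re-state the
# published piecewise formula directly (if/else chain, scalar) and never
# call the vectorized implementation they check.

FINAL <- read_profile("breadfruit_final")
ECOCROP <- read_profile("breadfruit_ecocrop")

# Environmental values inside every optimal range of the final profile.
optimal_values <- function() {
  list(temperature = 25, rainfall = 2000, solar_radiation = 100,
       soil_ph = 5.8, drainage_class = 5)
}

# Scalar trapezoid oracle: direct transcription of the piecewise formula.
oracle_membership <- function(p, set) {
  a <- set$abs_min; b <- set$opt_min; c_ <- set$opt_max; d <- set$abs_max
  if (is.na(p)) return(NA_real_)
  if (p >= b && p < c_) return(100)
  if (c_ == d && p == c_) return(100)
  if (p < a || p >= d) return(0)
  if (p < b) return((p - a) / (b - a) * 100)
  (1 - (p - c_) / (d - c_)) * 100
}

oracle_score <- function(values, profile, excluded = character()) {
  use <- setdiff(names(profile$criteria), excluded)
  scores <- vapply(use, function(nm) {
    oracle_membership(values[[nm]], profile$criteria[[nm]]$set)
  }, numeric(1))
  if (anyNA(scores)) NA_real_ else min(scores)
}

# Draw random criterion values spanning beyond the absolute range.
random_values <- function(profile, na_prob = 0) {
  vals <- lapply(profile$criteria, function(cr) {
    span <- cr$set$abs_max - cr$set$abs_min
    if (runif(1) < na_prob) NA_real_
    else runif(1, cr$set$abs_min - 0.2 * span, cr$set$abs_max + 0.2 * span)
  })
  names(vals) <- names(profile$criteria)
  vals
}

# Small aligned stack from named matrices (all same dim).
tiny_stack <- function(mats, dx = 50, crs_kind = "projected") {
  nr <- nrow(mats[[1]])
  layers <- lapply(names(mats), function(nm) {
    grid_layer(mats[[nm]], xmin = 0, ymax = nr * dx, dx = dx,
               crs_kind = crs_kind, criterion = nm)
  })
  names(layers) <- names(mats)
  layer_stack(layers)
}

# Stack where every pixel takes the given per-criterion constants.
constant_stack <- function(values, nr = 2, nc = 2, dx = 50) {
  tiny_stack(lapply(values, function(v) matrix(v, nr, nc)), dx = dx)
}

# Random stack spanning each criterion's absolute range and beyond.
random_stack <- function(profile, nr = 20, nc = 20, na_prob = 0) {
  mats <- lapply(profile$criteria, function(cr) {
    span <- cr$set$abs_max - cr$set$abs_min
    m <- matrix(runif(nr * nc, cr$set$abs_min - 0.2 * span,
                      cr$set$abs_max + 0.2 * span), nr, nc)
    if (na_prob > 0) m[runif(nr * nc) < na_prob] <- NA
    m
  })
  names(mats) <- names(profile$criteria)
  tiny_stack(mats)
}

# Table 3 printed per-bin areas (million km^2), used as fixture inputs.
TABLE3_BINS <- list(
  current = c("<1" = 2.59, "1-10" = 2.11, "11-20" = 1.97, "21-30" = 1.83,
              "31-40" = 2.03, "41-50" = 3.27, "51-60" = 1.64, "61-70" = 1.42,
              "71-80" = 1.63, "81-90" = 4.25, "91-100" = 12.50),
  rcp45 = c("<1" = 3.53, "1-10" = 4.68, "11-20" = 3.62, "21-30" = 2.90,
            "31-40" = 2.50, "41-50" = 3.74, "51-60" = 1.90, "61-70" = 1.96,
            "71-80" = 2.12, "81-90" = 5.25, "91-100" = 12.94),
  rcp85 = c("<1" = 9.35, "1-10" = 10.38, "11-20" = 6.20, "21-30" = 5.28,
            "31-40" = 4.62, "41-50" = 5.17, "51-60" = 3.16, "61-70" = 2.93,
            "71-80" = 4.17, "81-90" = 6.22, "91-100" = 13.59)
)

# Table 3 printed group/total rows.
TABLE3_PRINTED <- list(
  total = c(current = 32.66, rcp45 = 41.62, rcp85 = 61.71),
  low = c(current = 8.51, rcp45 = 14.73, rcp85 = 31.21),
  moderate = c(current = 8.36, rcp45 = 10.11, rcp85 = 15.88),
  high = c(current = 18.38, rcp45 = 20.31, rcp85 = 23.97)
)
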