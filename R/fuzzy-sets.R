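#' Trapezoidal fuzzy suitability set
#'
#' A fuzzy set maps an environmental measurement to a 0-100 suitability
#' score through a trapezoidal membership function: 0 outside the absolute
#' range, 100 inside the optimal range, and linear ramps between the
#' absolute and optimal bounds.
#'
#' @param abs_min,opt_min,opt_max,abs_max Numeric thresholds in criterion
#'   units, satisfying `abs_min <= opt_min <= opt_max <= abs_max`. Equal
#'   neighbours are allowed (degenerate ramps).
#' @return An object of class `fuzzy_set`.
#' @examples
#' fs <- fuzzy_set(750, 1500, 4000, 8000) # rainfall, mm/yr
#' membership(1125, fs) # 50
#' @export
fuzzy_set <- function(abs_min, opt_min, opt_max, abs_max) {
  s <- structure(
    list(abs_min = abs_min, opt_min = opt_min,
         opt_max = opt_max, abs_max = abs_max),
    class = "fuzzy_set"
  )
  v <- validate_fuzzy_set(s)
  if (!isTRUE(v$ok)) stop_input("invalid fuzzy set: %s", v$violation)
  s
}

#' Validate a fuzzy set's threshold ordering
#'
#' @param s A `fuzzy_set` or a list/vector with the four thresholds.
#' @return A list with `ok` (logical) and, when not ok, `violation`, a
#'   message naming the violated ordering.
#' @export
validate_fuzzy_set <- function(s) {
  if (is.numeric(s) && length(s) == 4) {
    s <- list(abs_min = s[[1]], opt_min = s[[2]], opt_max = s[[3]], abs_max = s[[4]])
  }
  need <- c("abs_min", "opt_min", "opt_max", "abs_max")
  if (!all(need %in% names(s))) {
    stop_input("fuzzy set must provide fields %s", paste(need, collapse = ", "))
  }
  v <- unlist(s[need], use.names = FALSE)
  if (!is.numeric(v)) stop_input("fuzzy set thresholds must be numeric")
  if (any(!is.finite(v))) {
    return(list(ok = FALSE, violation = "all four thresholds must be finite"))
  }
  if (s$abs_min > s$opt_min) {
    return(list(ok = FALSE, violation = "abs_min > opt_min"))
  }
  if (s$opt_min > s$opt_max) {
    return(list(ok = FALSE, violation = "opt_min > opt_max"))
  }
  if (s$opt_max > s$abs_max) {
    return(list(ok = FALSE, violation = "opt_max > abs_max"))
  }
  list(ok = TRUE)
}

#' @export
print.fuzzy_set <- function(x, ...) {
  cat(sprintf("<fuzzy_set> abs [%g, %g], opt [%g, %g]\n",
              x$abs_min, x$abs_max, x$opt_min, x$opt_max))
  invisible(x)
}

#' Trapezoidal membership score
#'
#' Evaluates the piecewise-linear suitability response of a criterion value:
#' \deqn{SUIT(p) = 0} for `p < abs_min` or `p >= abs_max`, 100 on
#' `[opt_min, opt_max)`, and linear ramps `(p - abs_min)/(opt_min -
#' abs_min) * 100` and `(1 - (p - opt_max)/(abs_max - opt_max)) * 100` on
#' the shoulders.
#'
#' Boundary conventions: `p == abs_max` scores 0 (both adjacent branches
#' agree there); a degenerate ramp (`abs_min == opt_min` or `opt_max ==
#' abs_max`) scores 100 at the shared bound, the optimal branch taking
#' precedence, so e.g. a set (4, 4, 6, 6) scores 100 on the whole of
#' `[4, 6]`. `NA` values (nodata) propagate to `NA`; non-finite values
#' are an error.
#'
#' @param p Numeric vector or matrix of criterion values.
#' @param set A `fuzzy_set`.
#' @return Suitability scores in `[0, 100]`, same shape as `p`.
#' @export
membership <- function(p, set) {
  v <- validate_fuzzy_set(set)
  if (!isTRUE(v$ok)) stop_input("invalid fuzzy set: %s", v$violation)
  if (!is.numeric(p)) stop_input("criterion values must be numeric")
  if (any(is.nan(p) | is.infinite(p), na.rm = TRUE)) {
    stop_input("criterion values must be finite or NA (nodata)")
  }
  a <- set$abs_min; b <- set$opt_min; c_ <- set$opt_max; d <- set$abs_max

  out <- rep(0, length(p))
  plateau <- !is.na(p) & p >= b & p < c_
  if (c_ == d) plateau <- plateau | (!is.na(p) & p == c_) # degenerate upper ramp
  up <- !is.na(p) & p >= a & p < b
  down <- !is.na(p) & p >= c_ & p < d & !plateau
  out[up] <- (p[up] - a) / (b - a) * 100
  out[plateau] <- 100
  out[down] <- (1 - (p[down] - c_) / (d - c_)) * 100
  out[is.na(p)] <- NA_real_
  if (!is.null(dim(p))) dim(out) <- dim(p)
  out
}

#' Law-of-the-minimum combination
#'
#' Overall suitability is the score of the single most limiting criterion:
#' the minimum of the per-criterion scores. `NA` (nodata) in any input
#' propagates to `NA` — a record with an unknown criterion cannot be scored.
#'
#' @param scores Numeric vector of per-criterion scores in `[0, 100]`.
#' @return A single score in `[0, 100]`, or `NA`.
#' @export
combine_min <- function(scores) {
  scores <- unlist(scores, use.names = FALSE)
  if (length(scores) == 0) stop_input("combine_min: empty score collection")
  if (!is.numeric(scores)) stop_input("combine_min: scores must be numeric")
  if (any(scores < 0 | scores > 100, na.rm = TRUE)) {
    stop_input("combine_min: scores outside [0, 100]")
  }
  if (anyNA(scores)) return(NA_real_)
  min(scores)
}

#' Score one record of environmental values against a crop profile
#'
#' Applies [membership()] to each non-excluded criterion of `profile` and
#' combines with [combine_min()].
#'
#' @param values Named list or vector mapping criterion names to values.
#' @param profile A [crop_profile()].
#' @param excluded Character vector of criterion names to leave out (e.g.
#'   `"rainfall"` for an irrigated site).
#' @return A suitability score in `[0, 100]`, or `NA` if any used value is
#'   `NA`.
#' @export
score_record <- function(values, profile, excluded = character()) {
  profile <- as_crop_profile(profile)
  use <- setdiff(names(profile$criteria), excluded)
  if (length(use) == 0) stop_input("score_record: all criteria excluded")
  scores <- vapply(use, function(nm) {
    if (!nm %in% names(values)) {
      stop_input("score_record: missing value for criterion '%s'", nm)
    }
    membership(values[[nm]], profile$criteria[[nm]]$set)
  }, numeric(1))
  combine_min(scores)
}
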