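#' Criterion mask for a producer site
#'
#' Irrigated sites are not limited by rainfall, and sites with soil
#' amendments are not limited by native soil pH, so those criteria are
#' excluded from the modeled score the site is compared against.
#'
#' @param irrigated,amended Logical (or 0/1) flags. A data.frame row or
#'   list with `$irrigated` / `$amended` may be given as the first
#'   argument instead.
#' @return Character vector of criterion names to exclude (possibly empty).
#' @export
mask_for_site <- function(irrigated, amended) {
  if (missing(amended) && (is.list(irrigated) || is.data.frame(irrigated))) {
    site <- irrigated
    irrigated <- site$irrigated
    amended <- site$amended
  }
  excl <- character()
  if (isTRUE(as.logical(irrigated))) excl <- c(excl, "rainfall")
  if (isTRUE(as.logical(amended))) excl <- c(excl, "soil_ph")
  excl
}

site_required_cols <- c("id", "measured_productivity", "irrigated", "amended")

validate_sites <- function(sites) {
  if (!is.data.frame(sites)) stop_input("sites must be a data.frame")
  missing <- setdiff(site_required_cols, names(sites))
  if (length(missing)) {
    stop_input("sites table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  mp <- sites$measured_productivity
  if (any(!is.finite(mp)) || any(mp < 0 | mp > 100)) {
    stop_input("measured_productivity must be finite and in [0, 100]")
  }
  invisible(sites)
}

# Environmental values for one site row: direct columns take precedence,
# otherwise nearest-cell sampling from the stack at (lon, lat).
site_env_values <- function(site, needed, stack = NULL) {
  vals <- list()
  for (nm in needed) {
    v <- if (nm %in% names(site)) site[[nm]] else NA_real_
    if (is.na(v) && !is.null(stack) && all(c("lon", "lat") %in% names(site))) {
      if (nm %in% names(stack$layers)) {
        v <- sample_layer(stack$layers[[nm]], site$lon, site$lat)
      }
    }
    if (is.na(v)) {
      stop_input("site '%s': no value for criterion '%s'", site$id, nm)
    }
    vals[[nm]] <- v
  }
  vals
}

#' Score producer sites against a crop profile
#'
#' For each site, the simulated suitability `S` is [score_record()] under
#' the site's own criterion mask ([mask_for_site()]); the measured
#' productivity `M` is taken as given. Environmental values may be site
#' columns (named as the criteria) or sampled from `stack` at the site's
#' `lon`/`lat` by nearest-cell lookup; direct values take precedence.
#'
#' @param sites Producer-site data.frame (see [read_sites_csv()] for the
#'   column contract).
#' @param profile A [crop_profile()], label, or path.
#' @param stack Optional aligned [layer_stack()] for coordinate sampling.
#' @return A data.frame with columns `id`, `measured`, `simulated`,
#'   `irrigated`, `amended`, `excluded` (semicolon-joined mask), in input
#'   order.
#' @export
simulate_sites <- function(sites, profile, stack = NULL) {
  validate_sites(sites)
  profile <- as_crop_profile(profile)
  n <- nrow(sites)
  sim <- numeric(n)
  excl_lab <- character(n)
  for (k in seq_len(n)) {
    site <- sites[k, , drop = FALSE]
    excl <- mask_for_site(site$irrigated, site$amended)
    needed <- setdiff(names(profile$criteria), excl)
    vals <- site_env_values(site, needed, stack)
    sim[k] <- score_record(vals, profile, excluded = excl)
    excl_lab[k] <- paste(excl, collapse = ";")
  }
  data.frame(id = as.character(sites$id),
             measured = as.numeric(sites$measured_productivity),
             simulated = sim,
             irrigated = as.logical(sites$irrigated),
             amended = as.logical(sites$amended),
             excluded = excl_lab,
             stringsAsFactors = FALSE)
}

check_pair <- function(m, s, min_n = 2) {
  if (length(m) != length(s)) stop_input("M and S must have equal length")
  if (length(m) < min_n) stop_input("need at least %d paired values", min_n)
  if (anyNA(m) || anyNA(s)) stop_input("M and S must not contain NA")
  invisible(NULL)
}

#' Root mean square error
#' @param m,s Measured and simulated vectors of equal length (n >= 2).
#' @export
rmse <- function(m, s) {
  check_pair(m, s)
  sqrt(mean((m - s)^2))
}

#' Nash-Sutcliffe model efficiency
#'
#' `ME = 1 - sum((M - S)^2) / sum((M - mean(M))^2)`. 1 is a perfect fit;
#' 0 means the observed mean predicts as well as the model; unbounded
#' below.
#' @inheritParams rmse
#' @export
nash_sutcliffe_me <- function(m, s) {
  check_pair(m, s)
  if (sd_pop(m) == 0) stop_input("ME undefined: measured values are constant")
  1 - sum((m - s)^2) / sum((m - mean(m))^2)
}

#' RMSE / observed-standard-deviation ratio
#'
#' `RSR = RMSE / sd(M)` with population (denominator n) standard
#' deviation, so the identity `RSR^2 + ME = 1` holds exactly. Lower is
#' better; < 0.7 is the usual satisfactory-model bar.
#' @inheritParams rmse
#' @export
rsr <- function(m, s) {
  check_pair(m, s)
  sdm <- sd_pop(m)
  if (sdm == 0) stop_input("RSR undefined: measured values are constant")
  rmse(m, s) / sdm
}

#' Willmott's index of agreement
#'
#' `IA = 1 - sum((S - M)^2) / sum((|S - mean(M)| + |M - mean(M)|)^2)`,
#' bounded in [0, 1]; 1 is a perfect fit.
#' @inheritParams rmse
#' @export
willmott_ia <- function(m, s) {
  check_pair(m, s)
  mbar <- mean(m)
  denom <- sum((abs(s - mbar) + abs(m - mbar))^2)
  if (denom == 0) stop_input("IA undefined: zero potential error")
  1 - sum((s - m)^2) / denom
}

#' Ordinary least squares of measured on simulated
#'
#' @inheritParams rmse
#' @return List with `r2`, `slope`, `intercept`, `p_value` (slope t-test).
#' @export
linear_fit_r2 <- function(m, s) {
  check_pair(m, s, min_n = 3)
  if (sd_pop(s) == 0) stop_input("regression undefined: simulated values are constant")
  fit <- stats::lm(m ~ s)
  # exact fits (zero-noise validation) are legitimate; silence summary.lm's
  # "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(r2 = unname(sm$r.squared),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(p))
}

cv_pct <- function(x) 100 * sd_pop(x) / mean(x)

accuracy_row <- function(label, m, s) {
  fit <- tryCatch(linear_fit_r2(m, s),
                  error = function(e) list(r2 = NA_real_, slope = NA_real_,
                                           intercept = NA_real_, p_value = NA_real_))
  data.frame(group = label, n = length(m),
             rmse = rmse(m, s), sd_measured = sd_pop(m),
             me = nash_sutcliffe_me(m, s), ia = willmott_ia(m, s),
             rsr = rsr(m, s),
             r2 = fit$r2, slope = fit$slope, intercept = fit$intercept,
             p_value = fit$p_value,
             stringsAsFactors = FALSE)
}

#' Grouped validation report
#'
#' Summarizes sites by (irrigated, amended) group — count, mean and CV of
#' measured and simulated productivity, and the criteria excluded for the
#' group — plus a pooled row; and computes accuracy statistics (RMSE, sd,
#' ME, IA, RSR, OLS r2/slope/intercept/p) for the "natural" group (neither
#' flag, all criteria used) and for all sites pooled, each site scored
#' under its own mask.
#'
#' @inheritParams simulate_sites
#' @return List of class `validation_report` with data.frames `groups` and
#'   `accuracy`.
#' @export
validation_report <- function(sites, profile, stack = NULL) {
  sim <- simulate_sites(sites, profile, stack)
  if (nrow(sim) < 2) stop_input("validation needs at least 2 sites")

  combos <- expand.grid(irrigated = c(FALSE, TRUE), amended = c(FALSE, TRUE))
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    irr <- combos$irrigated[k]; amd <- combos$amended[k]
    sel <- sim$irrigated == irr & sim$amended == amd
    if (!any(sel)) next # empty group omitted, not an error
    excl <- mask_for_site(irr, amd)
    rows[[length(rows) + 1]] <- data.frame(
      irrigated = irr, amended = amd, n = sum(sel),
      mean_measured = mean(sim$measured[sel]),
      cv_measured = cv_pct(sim$measured[sel]),
      mean_simulated = mean(sim$simulated[sel]),
      cv_simulated = cv_pct(sim$simulated[sel]),
      excluded = paste(excl, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    irrigated = NA, amended = NA, n = nrow(sim),
    mean_measured = mean(sim$measured), cv_measured = cv_pct(sim$measured),
    mean_simulated = mean(sim$simulated), cv_simulated = cv_pct(sim$simulated),
    excluded = "per-site", stringsAsFactors = FALSE)
  groups <- do.call(rbind, rows)

  acc <- list()
  nat <- !sim$irrigated & !sim$amended
  if (sum(nat) >= 2) {
    acc[[length(acc) + 1]] <- accuracy_row("natural", sim$measured[nat], sim$simulated[nat])
  }
  acc[[length(acc) + 1]] <- accuracy_row("all", sim$measured, sim$simulated)
  structure(list(groups = groups, accuracy = do.call(rbind, acc), sites = sim),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation site groups:\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat("\nModel accuracy:\n")
  print(x$accuracy, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a validation report as CSV (two blocks)
#'
#' The group-summary block and the accuracy block are written to the same
#' file, separated by a blank line.
#' @param report A [validation_report()].
#' @param path Output CSV path.
#' @export
write_validation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(report$groups, con, row.names = FALSE)
  writeLines("", con)
  utils::write.csv(report$accuracy, con, row.names = FALSE)
  invisible(path)
}

#' Read / write producer-site tables
#'
#' CSV columns: `id`, optional `lon`/`lat`, the criterion columns
#' `temperature`, `rainfall`, `solar_radiation`, `soil_ph`,
#' `drainage_class` (optional when coordinates plus a stack are used),
#' `measured_productivity` (0-100), `irrigated` (0/1), `amended` (0/1).
#' @param path CSV path.
#' @export
read_sites_csv <- function(path) {
  if (!file.exists(path)) stop_input("sites file not found: %s", path)
  sites <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sites(sites)
  sites$irrigated <- as.logical(sites$irrigated)
  sites$amended <- as.logical(sites$amended)
  sites
}

#' @rdname read_sites_csv
#' @param sites Producer-site data.frame.
#' @export
write_sites_csv <- function(sites, path) {
  validate_sites(sites)
  out <- sites
  out$irrigated <- as.integer(as.logical(out$irrigated))
  out$amended <- as.integer(as.logical(out$amended))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
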