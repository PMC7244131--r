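#' Configuration for the synthetic-data generators
#'
#' The defaults state a Hawai'i-like world: steep orthogonal gradients in
#' mean annual temperature (10-24 degC across rows) and annual rainfall
#' (200-10,000 mm/yr across columns) on a 200x200 projected grid of 50 m
#' cells; solar radiation inversely tracking rainfall (wetter = cloudier);
#' patchy smoothed-noise soil pH and drainage-class fields; 57 producer
#' sites whose measured productivity is the true suitability under the
#' site's irrigation/amendment mask plus Gaussian noise (sd 5, clipped to
#' [0, 100]); and a 17-member climate ensemble perturbing temperature by
#' an additive offset and rainfall by a multiplier per member.
#'
#' @param nrow,ncol Grid shape.
#' @param crs_kind `"projected"` (metres) or `"geographic"` (degrees).
#' @param cell_size Cell size (m or degrees).
#' @param seed Master seed; every generator derives a labelled sub-seed
#'   from it, so results are fully deterministic and generators do not
#'   perturb each other's streams.
#' @param temp_range,rain_range,solar_range Gradient end points (degC,
#'   mm/yr, W/m^2).
#' @param solar_noise_sd Gaussian noise on the solar field (W/m^2).
#' @param ph_mean,ph_sd,ph_patch_scale Soil-pH field: mean, sd, and
#'   smoothing window (cells) of the patchy field.
#' @param drainage_mean,drainage_sd,drainage_patch_scale Drainage-class
#'   field before rounding to classes 1-7.
#' @param n_sites Number of producer sites.
#' @param site_noise_sd Gaussian noise sd on measured productivity
#'   (suitability units).
#' @param irrigation_prob,amendment_prob Per-site flag probabilities.
#' @param ensemble_size Number of climate-model members.
#' @param temp_offset_mean,temp_offset_sd Per-member temperature offset
#'   distribution (degC).
#' @param rain_mult_mean,rain_mult_sd Per-member rainfall multiplier
#'   distribution.
#' @export
synth_config <- function(nrow = 200, ncol = 200,
                         crs_kind = c("projected", "geographic"),
                         cell_size = 50, seed = 1L,
                         temp_range = c(10, 24), rain_range = c(200, 10000),
                         solar_range = c(60, 190), solar_noise_sd = 3,
                         ph_mean = 6, ph_sd = 0.8, ph_patch_scale = 15,
                         drainage_mean = 4.5, drainage_sd = 1.2,
                         drainage_patch_scale = 11,
                         n_sites = 57, site_noise_sd = 5,
                         irrigation_prob = 0.46, amendment_prob = 0.26,
                         ensemble_size = 17,
                         temp_offset_mean = 2, temp_offset_sd = 0.8,
                         rain_mult_mean = 1.05, rain_mult_sd = 0.08) {
  crs_kind <- match.arg(crs_kind)
  cfg <- list(nrow = nrow, ncol = ncol, crs_kind = crs_kind,
              cell_size = cell_size, seed = seed,
              temp_range = temp_range, rain_range = rain_range,
              solar_range = solar_range, solar_noise_sd = solar_noise_sd,
              ph_mean = ph_mean, ph_sd = ph_sd, ph_patch_scale = ph_patch_scale,
              drainage_mean = drainage_mean, drainage_sd = drainage_sd,
              drainage_patch_scale = drainage_patch_scale,
              n_sites = n_sites, site_noise_sd = site_noise_sd,
              irrigation_prob = irrigation_prob, amendment_prob = amendment_prob,
              ensemble_size = ensemble_size,
              temp_offset_mean = temp_offset_mean, temp_offset_sd = temp_offset_sd,
              rain_mult_mean = rain_mult_mean, rain_mult_sd = rain_mult_sd)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$nrow < 2 || cfg$ncol < 2) stop_input("grid must be at least 2x2")
  sds <- c(cfg$solar_noise_sd, cfg$ph_sd, cfg$drainage_sd,
           cfg$site_noise_sd, cfg$temp_offset_sd, cfg$rain_mult_sd)
  if (any(sds < 0)) stop_input("standard deviations must be >= 0")
  probs <- c(cfg$irrigation_prob, cfg$amendment_prob)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must be in [0, 1]")
  if (cfg$ensemble_size < 1) stop_input("ensemble size must be >= 1")
  if (cfg$cell_size <= 0) stop_input("cell size must be positive")
  invisible(cfg)
}

#' Read a synthetic-data config from JSON
#'
#' Keys are the [synth_config()] arguments; absent keys take the defaults.
#' @param path JSON file path.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) stop_input("unknown config key(s): %s", paste(extra, collapse = ", "))
  do.call(synth_config, obj)
}

# Patchy field: white noise smoothed with a separable box kernel of width
# `scale` cells (edge-padded), standardized to mean 0 / sd 1.
smooth_field <- function(nr, nc, scale) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  w <- max(1L, as.integer(scale))
  if (w > 1) {
    k <- rep(1 / w, w)
    pad <- w %/% 2
    run <- function(x) {
      xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
      s <- stats::filter(xp, k, sides = 2)
      s[(pad + 1):(pad + length(x))]
    }
    m <- apply(m, 2, run)
    m <- t(apply(m, 1, run))
  }
  (m - mean(m)) / stats::sd(m)
}

#' Generate a synthetic environmental layer stack
#'
#' Temperature varies linearly along rows (cool north edge to warm south
#' edge), rainfall along columns (dry west to wet east) — orthogonal
#' gradients. Solar radiation decreases linearly with rainfall plus small
#' noise (clipped to the configured range); soil pH and drainage class are
#' seeded patchy fields, drainage quantized to classes 1-7.
#'
#' @param cfg A [synth_config()].
#' @return An aligned [layer_stack()] with the five criterion layers.
#' @export
gen_environment <- function(cfg) {
  validate_synth_config(cfg)
  nr <- cfg$nrow; nc <- cfg$ncol
  with_seed(sub_seed(cfg$seed, "environment"), {
    temp <- matrix(seq(cfg$temp_range[1], cfg$temp_range[2], length.out = nr),
                   nr, nc, byrow = FALSE)
    rain <- matrix(seq(cfg$rain_range[1], cfg$rain_range[2], length.out = nc),
                   nr, nc, byrow = TRUE)
    rfrac <- (rain - cfg$rain_range[1]) / diff(cfg$rain_range)
    solar <- cfg$solar_range[2] - rfrac * diff(cfg$solar_range) +
      matrix(stats::rnorm(nr * nc, 0, cfg$solar_noise_sd), nr, nc)
    solar <- pmin(pmax(solar, cfg$solar_range[1]), cfg$solar_range[2])
    ph <- cfg$ph_mean + cfg$ph_sd * smooth_field(nr, nc, cfg$ph_patch_scale)
    ph <- pmin(pmax(ph, 3), 9.5)
    drain <- round_half_up(cfg$drainage_mean +
                             cfg$drainage_sd * smooth_field(nr, nc, cfg$drainage_patch_scale))
    drain <- pmin(pmax(drain, 1), 7)
    mk <- function(v, criterion, units) {
      grid_layer(v, xmin = 0, ymax = nr * cfg$cell_size,
                 dx = cfg$cell_size, dy = cfg$cell_size,
                 crs_kind = cfg$crs_kind, criterion = criterion, units = units)
    }
    layer_stack(list(
      temperature = mk(temp, "temperature", "degC"),
      rainfall = mk(rain, "rainfall", "mm/yr"),
      solar_radiation = mk(solar, "solar_radiation", "W/m2"),
      soil_ph = mk(ph, "soil_ph", "pH"),
      drainage_class = mk(drain, "drainage_class", "class 1-7")
    ))
  })
}

#' Generate a perturbed climate-model ensemble
#'
#' Each member copies the baseline and applies one additive temperature
#' offset and one multiplicative rainfall factor, drawn per member from
#' the configured distributions (multipliers truncated at 0).
#'
#' @param baseline Aligned [layer_stack()] from [gen_environment()].
#' @param cfg A [synth_config()].
#' @param scenario_label Ensemble label; also salts the sub-seed, so the
#'   RCP4.5 and RCP8.5 ensembles differ.
#' @return A [scenario_ensemble()].
#' @export
gen_gcm_ensemble <- function(baseline, cfg, scenario_label = "RCP4.5") {
  validate_synth_config(cfg)
  require_aligned(baseline)
  with_seed(sub_seed(cfg$seed, paste0("ensemble:", scenario_label)), {
    k <- cfg$ensemble_size
    offsets <- stats::rnorm(k, cfg$temp_offset_mean, cfg$temp_offset_sd)
    mults <- pmax(stats::rnorm(k, cfg$rain_mult_mean, cfg$rain_mult_sd), 0)
    members <- lapply(seq_len(k), function(i) {
      tl <- baseline$layers$temperature
      rl <- baseline$layers$rainfall
      tl$values <- tl$values + offsets[i]
      rl$values <- rl$values * mults[i]
      layer_stack(list(temperature = tl, rainfall = rl))
    })
    scenario_ensemble(scenario_label, members, baseline)
  })
}

#' Generate noisy producer validation sites
#'
#' Sites are placed at seeded random valid pixels of the stack.
#' Irrigation and amendment flags are independent Bernoulli draws; the
#' measured productivity is the true suitability under the site's own
#' criterion mask plus Gaussian noise, clipped to [0, 100]. Irrigated
#' sites in arid pixels therefore still measure high productivity.
#'
#' @param stack Aligned [layer_stack()] with all five criteria.
#' @param profile A [crop_profile()], label, or path.
#' @param cfg A [synth_config()].
#' @return A producer-site data.frame (see [read_sites_csv()]).
#' @export
gen_sites <- function(stack, profile, cfg) {
  validate_synth_config(cfg)
  require_aligned(stack)
  profile <- as_crop_profile(profile)
  vals <- lapply(stack$layers, function(l) l$values)
  valid <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  idx_pool <- which(valid)
  if (length(idx_pool) == 0) stop_input("no valid pixels to place sites on")
  ref <- stack$layers[[1]]
  with_seed(sub_seed(cfg$seed, "sites"), {
    n <- cfg$n_sites
    idx <- sample(idx_pool, n, replace = length(idx_pool) < n)
    rc <- arrayInd(idx, dim(ref$values))
    irrigated <- stats::runif(n) < cfg$irrigation_prob
    amended <- stats::runif(n) < cfg$amendment_prob
    env <- lapply(vals, function(v) v[idx])
    true_s <- vapply(seq_len(n), function(k) {
      score_record(lapply(env, `[[`, k), profile,
                   excluded = mask_for_site(irrigated[k], amended[k]))
    }, numeric(1))
    measured <- pmin(pmax(true_s + stats::rnorm(n, 0, cfg$site_noise_sd), 0), 100)
    data.frame(
      id = sprintf("site_%03d", seq_len(n)),
      lon = ref$xmin + (rc[, 2] - 0.5) * ref$dx,
      lat = ref$ymax - (rc[, 1] - 0.5) * ref$dy,
      temperature = env$temperature, rainfall = env$rainfall,
      solar_radiation = env$solar_radiation, soil_ph = env$soil_ph,
      drainage_class = env$drainage_class,
      measured_productivity = measured,
      irrigated = irrigated, amended = amended,
      true_suitability = true_s,
      stringsAsFactors = FALSE
    )
  })
}

#' Derive a categorical reference map from a suitability surface
#'
#' Maps scores to classes 0 (below `thresholds[1]`), 1 (between), 2
#' (`>= thresholds[2]`), optionally flipping a seeded fraction of labels
#' to a random other class to emulate disagreement between models.
#'
#' @param suit A suitability `grid_layer`.
#' @param thresholds Increasing pair of class cut points (default `c(1, 70)`).
#' @param noise_rate Fraction of valid pixels whose class is re-drawn.
#' @param seed Seed for the label noise.
#' @return A `grid_layer` of classes `{0, 1, 2}`.
#' @export
gen_reference_classes <- function(suit, thresholds = c(1, 70),
                                  noise_rate = 0, seed = 1L) {
  if (!inherits(suit, "grid_layer")) stop_input("not a grid_layer")
  if (length(thresholds) != 2 || !(thresholds[1] < thresholds[2])) {
    stop_input("thresholds must be strictly increasing")
  }
  if (noise_rate < 0 || noise_rate > 1) stop_input("noise_rate must be in [0, 1]")
  v <- suit$values
  cls <- ifelse(is.na(v), NA_real_,
                ifelse(v < thresholds[1], 0, ifelse(v < thresholds[2], 1, 2)))
  dim(cls) <- dim(v)
  if (noise_rate > 0) {
    with_seed(sub_seed(seed, "reference-noise"), {
      valid <- which(!is.na(cls))
      flip <- valid[stats::runif(length(valid)) < noise_rate]
      cls[flip] <- vapply(cls[flip], function(cl) {
        sample(setdiff(c(0, 1, 2), cl), 1)
      }, numeric(1))
    })
  }
  grid_layer(cls, xmin = suit$xmin, ymax = suit$ymax, dx = suit$dx, dy = suit$dy,
             crs_kind = suit$crs_kind, nodata = suit$nodata,
             criterion = "reference_class", units = "class 0/1/2")
}
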