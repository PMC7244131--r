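#' Future-climate scenario ensemble
#'
#' One emissions scenario's worth of climate-model members. Each member
#' stack must provide `temperature` and `rainfall`; the remaining criteria
#' (solar radiation, soil pH, drainage class) are taken from `baseline` at
#' evaluation time, since only climate is projected.
#'
#' @param scenario_label e.g. `"RCP4.5"` or `"RCP8.5"`.
#' @param members List of [layer_stack()]s, one per climate model.
#' @param baseline Aligned [layer_stack()] with all five criteria.
#' @export
scenario_ensemble <- function(scenario_label, members, baseline) {
  if (length(members) == 0) stop_input("ensemble has zero members")
  require_aligned(baseline)
  ref <- baseline$layers[[1]]
  for (k in seq_along(members)) {
    mem <- members[[k]]
    if (!inherits(mem, "layer_stack")) stop_input("member %d is not a layer_stack", k)
    miss <- setdiff(c("temperature", "rainfall"), names(mem$layers))
    if (length(miss)) {
      stop_input("member %d lacks layer(s): %s", k, paste(miss, collapse = ", "))
    }
    for (nm in names(mem$layers)) {
      l <- mem$layers[[nm]]
      if (!identical(dim(l$values), dim(ref$values)) || !same_transform(l, ref) ||
          !identical(l$crs_kind, ref$crs_kind)) {
        stop_input("member %d layer '%s' is not aligned with the baseline", k, nm)
      }
    }
  }
  structure(list(scenario_label = scenario_label, members = members,
                 baseline = baseline),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf("<scenario_ensemble> %s, %d member(s)\n",
              x$scenario_label, length(x$members)))
  invisible(x)
}

#' Ensemble-mean future suitability
#'
#' For each member, a full stack is assembled from the member's
#' temperature and rainfall plus the baseline's remaining layers, scored
#' with [suitability_map()], and the per-member suitability surfaces are
#' averaged pixel-wise (mean of suitabilities, not of climates). A pixel
#' is valid only where every member and the baseline are valid.
#'
#' @param ens A [scenario_ensemble()].
#' @param profile A [crop_profile()], label, or path.
#' @param excluded Criteria excluded from scoring (rarely used here).
#' @return A suitability `grid_layer`.
#' @export
ensemble_suitability <- function(ens, profile, excluded = character()) {
  if (!inherits(ens, "scenario_ensemble")) stop_input("not a scenario_ensemble")
  profile <- as_crop_profile(profile)
  base_layers <- ens$baseline$layers
  acc <- NULL
  for (mem in ens$members) {
    layers <- base_layers
    layers[names(mem$layers)] <- mem$layers
    m <- suitability_map(layer_stack(layers), profile, excluded)
    acc <- if (is.null(acc)) m$values else acc + m$values # NA propagates
  }
  ref <- base_layers[[1]]
  grid_layer(acc / length(ens$members),
             xmin = ref$xmin, ymax = ref$ymax, dx = ref$dx, dy = ref$dy,
             crs_kind = ref$crs_kind, nodata = ref$nodata,
             criterion = "suitability", units = "score 0-100")
}

#' Suitability change between a future and a baseline surface
#'
#' Computes the pixel-wise difference `future - baseline` and the
#' unchanged / minimally-changed breakdown over pixels valid in both
#' surfaces. "Unchanged" means `|delta| < 0.5` (indistinguishable at the
#' integer reporting precision); "minimally changed" means
#' `0.5 <= |delta| <= 10`.
#'
#' @param future,baseline Aligned suitability `grid_layer`s.
#' @return A list of class `change_summary`: `delta` (grid_layer),
#'   `n_valid`, `fraction_unchanged`, `fraction_minimal`,
#'   `area_unchanged`, `area_minimal`, `area_valid` (km^2).
#' @export
change_map <- function(future, baseline) {
  if (!inherits(future, "grid_layer") || !inherits(baseline, "grid_layer")) {
    stop_input("change_map needs two grid_layers")
  }
  if (!identical(dim(future$values), dim(baseline$values)) ||
      !same_transform(future, baseline) ||
      !identical(future$crs_kind, baseline$crs_kind)) {
    stop_input("future and baseline layers are not aligned")
  }
  delta <- future$values - baseline$values
  valid <- !is.na(delta)
  if (!any(valid)) stop_input("no pixels valid in both layers")
  areas <- cell_areas(baseline)
  a_valid <- sum(areas[valid])
  unchanged <- valid & abs(delta) < 0.5
  minimal <- valid & abs(delta) >= 0.5 & abs(delta) <= 10
  dl <- grid_layer(delta, xmin = baseline$xmin, ymax = baseline$ymax,
                   dx = baseline$dx, dy = baseline$dy,
                   crs_kind = baseline$crs_kind, nodata = baseline$nodata,
                   criterion = "suitability_change", units = "score delta")
  structure(list(
    delta = dl, n_valid = sum(valid),
    fraction_unchanged = sum(areas[unchanged]) / a_valid,
    fraction_minimal = sum(areas[minimal]) / a_valid,
    area_unchanged = sum(areas[unchanged]),
    area_minimal = sum(areas[minimal]),
    area_valid = a_valid
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary> %d valid px; unchanged %.1f%%, minimal %.1f%% (of %.4g km^2)\n",
              x$n_valid, 100 * x$fraction_unchanged, 100 * x$fraction_minimal,
              x$area_valid))
  invisible(x)
}

BIN_LABELS <- c("<1", "1-10", "11-20", "21-30", "31-40", "41-50",
                "51-60", "61-70", "71-80", "81-90", "91-100")
GROUP_LABELS <- c("<1 to 30", "31 to 70", "71 to 100")

#' Suitability area table
#'
#' Areas (million km^2) per suitability bin, plus the three summary
#' groups and the total. Binning rounds a score to the nearest integer and
#' uses the closed integer ranges `{0}`, `[1,10]`, `[11,20]`, ...,
#' `[91,100]` — the only partition of `[0, 100]` consistent with labels
#' "<1", "1-10", "11-20". The `<1 to 30` group includes the `<1` bin;
#' the reported total excludes it (scores under 0.5 count as no
#' cultivable area).
#'
#' @param bins Named numeric vector of length 11 (names as in the bin
#'   labels, in order) of areas in million km^2.
#' @return Object of class `area_table` with `bins`, `groups`, `total`.
#' @export
area_table <- function(bins) {
  bins <- unlist(bins)
  if (length(bins) != 11) stop_input("area_table needs 11 bin areas")
  if (is.null(names(bins)) || !all(nzchar(names(bins)))) names(bins) <- BIN_LABELS
  if (!identical(names(bins), BIN_LABELS)) {
    stop_input("bin names must be: %s", paste(BIN_LABELS, collapse = ", "))
  }
  if (any(!is.finite(bins)) || any(bins < 0)) stop_input("bin areas must be finite and >= 0")
  groups <- c(sum(bins[1:4]), sum(bins[5:8]), sum(bins[9:11]))
  names(groups) <- GROUP_LABELS
  structure(list(bins = bins, groups = groups,
                 total = sum(bins) - bins[["<1"]]),
            class = "area_table")
}

#' @export
print.area_table <- function(x, ...) {
  cat("<area_table> (million km^2)\n")
  cat(sprintf("  total (excl. <1): %.4g\n", x$total))
  for (nm in names(x$bins)) cat(sprintf("  bin %-8s %.4g\n", nm, x$bins[[nm]]))
  for (nm in names(x$groups)) cat(sprintf("  group %-10s %.4g\n", nm, x$groups[[nm]]))
  invisible(x)
}

# Bin index (1..11) for each score; NA passes through.
score_bin_index <- function(score) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    stop_input("suitability scores outside [0, 100]")
  }
  r <- round_half_up(score)
  idx <- ifelse(r == 0, 1L, 2L + (r - 1L) %/% 10L)
  idx
}

#' Bin a suitability surface into an area table
#'
#' @param suit A suitability `grid_layer`.
#' @return An [area_table()] in million km^2.
#' @export
bin_areas <- function(suit) {
  if (!inherits(suit, "grid_layer")) stop_input("not a grid_layer")
  areas <- cell_areas(suit)
  idx <- score_bin_index(suit$values)
  valid <- !is.na(idx)
  if (!any(valid)) stop_input("no valid pixels to bin")
  sums <- vapply(1:11, function(b) sum(areas[valid & idx == b]), numeric(1))
  names(sums) <- BIN_LABELS
  area_table(sums / 1e6) # km^2 -> million km^2
}

#' Percent change between two area tables
#'
#' `100 * (future - baseline) / baseline` for the total (excluding the <1
#' bin), the moderate group (31-70) and the high group (71-100).
#'
#' @param table_future,table_baseline [area_table()]s from aligned analyses.
#' @return A data.frame with columns `quantity`, `baseline`, `future`,
#'   `change_pct` (unrounded) and `change_pct_rounded` (nearest whole
#'   percent, the reporting convention). A zero baseline yields `NA` with
#'   a warning rather than an error.
#' @export
percent_change <- function(table_future, table_baseline) {
  if (!inherits(table_future, "area_table") || !inherits(table_baseline, "area_table")) {
    stop_input("percent_change needs two area_tables")
  }
  base <- c(total = unname(table_baseline$total),
            moderate = unname(table_baseline$groups[["31 to 70"]]),
            high = unname(table_baseline$groups[["71 to 100"]]))
  fut <- c(total = unname(table_future$total),
           moderate = unname(table_future$groups[["31 to 70"]]),
           high = unname(table_future$groups[["71 to 100"]]))
  pct <- ifelse(base == 0, NA_real_, 100 * (fut - base) / base)
  if (anyNA(pct)) warning("zero baseline area: percent change undefined for some quantities")
  data.frame(quantity = names(base), baseline = unname(base), future = unname(fut),
             change_pct = unname(pct),
             change_pct_rounded = unname(round_half_up(pct)),
             stringsAsFactors = FALSE)
}

#' Area-weighted mean suitability
#'
#' @param suit A suitability `grid_layer`.
#' @return Mean score over valid pixels, weighted by cell area.
#' @export
mean_suitability <- function(suit) {
  if (!inherits(suit, "grid_layer")) stop_input("not a grid_layer")
  valid <- !is.na(suit$values)
  if (!any(valid)) stop_input("no valid pixels")
  areas <- cell_areas(suit)
  sum(suit$values[valid] * areas[valid]) / sum(areas[valid])
}

#' Cross-tabulate a categorical reference model against a suitability map
#'
#' The reference layer holds classes 0 (unsuitable), 1 (suitable), 2
#' (best). For each class the table reports total area, area per
#' suitability bin, the area fraction scoring >= 90, and the
#' area-weighted mean suitability, over pixels valid in both layers.
#'
#' @param reference `grid_layer` with values in `{0, 1, 2}` or nodata.
#' @param suit Aligned suitability `grid_layer`.
#' @return A data.frame with one row per class present: `class`,
#'   `total_area_mkm2`, one `bin_*` column per bin (million km^2),
#'   `frac_ge90`, `mean_suitability`.
#' @export
crosstab_categorical <- function(reference, suit) {
  if (!inherits(reference, "grid_layer") || !inherits(suit, "grid_layer")) {
    stop_input("crosstab needs two grid_layers")
  }
  if (!identical(dim(reference$values), dim(suit$values)) ||
      !same_transform(reference, suit) ||
      !identical(reference$crs_kind, suit$crs_kind)) {
    stop_input("reference and suitability layers are not aligned")
  }
  cls <- reference$values
  bad <- !is.na(cls) & !cls %in% c(0, 1, 2)
  if (any(bad)) stop_input("reference classes must be 0, 1 or 2")
  idx <- score_bin_index(suit$values)
  areas <- cell_areas(suit)
  valid <- !is.na(cls) & !is.na(suit$values)
  rows <- list()
  for (cl in sort(unique(cls[valid]))) {
    sel <- valid & cls == cl
    a_tot <- sum(areas[sel])
    bins <- vapply(1:11, function(b) sum(areas[sel & idx == b]), numeric(1)) / 1e6
    row <- data.frame(class = cl, total_area_mkm2 = a_tot / 1e6,
                      frac_ge90 = sum(areas[sel & suit$values >= 90]) / a_tot,
                      mean_suitability = sum(suit$values[sel] * areas[sel]) / a_tot,
                      stringsAsFactors = FALSE)
    for (b in 1:11) row[[paste0("bin_", gsub("[^0-9]+", "_", BIN_LABELS[b]))]] <- bins[b]
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Write an area table as CSV
#'
#' Long format: columns `kind` (bin/group/total), `label`, `area_mkm2`.
#' @param tab An [area_table()].
#' @param path Output CSV path.
#' @export
write_area_table <- function(tab, path) {
  if (!inherits(tab, "area_table")) stop_input("not an area_table")
  df <- rbind(
    data.frame(kind = "total", label = "total", area_mkm2 = unname(tab$total)),
    data.frame(kind = "bin", label = names(tab$bins), area_mkm2 = unname(tab$bins)),
    data.frame(kind = "group", label = names(tab$groups), area_mkm2 = unname(tab$groups))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an area table written by [write_area_table()]
#' @param path CSV path.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) stop_input("area table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bins <- df$area_mkm2[df$kind == "bin"]
  names(bins) <- df$label[df$kind == "bin"]
  area_table(bins[BIN_LABELS])
}
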