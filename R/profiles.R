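#' Single-criterion profile
#'
#' Binds a canonical criterion name and its units to a [fuzzy_set()].
#'
#' @param name One of `temperature`, `rainfall`, `solar_radiation`,
#'   `soil_ph`, `drainage_class`.
#' @param units Free-text units label (e.g. `"degC"`, `"mm/yr"`).
#' @param set A `fuzzy_set`.
#' @export
criterion_profile <- function(name, units, set) {
  name <- match.arg(name, CRITERIA)
  v <- validate_fuzzy_set(set)
  if (!isTRUE(v$ok)) stop_input("criterion '%s': %s", name, v$violation)
  if (!inherits(set, "fuzzy_set")) {
    set <- fuzzy_set(set$abs_min, set$opt_min, set$opt_max, set$abs_max)
  }
  structure(list(name = name, units = as.character(units), set = set),
            class = "criterion_profile")
}

#' Crop parameter profile
#'
#' A labelled, ordered set of per-criterion fuzzy sets. Two profiles ship
#' with the package (see [read_profile()]): `breadfruit_final`, the
#' field-refined breadfruit parameters, and `breadfruit_ecocrop`, the
#' original EcoCrop-database parameters.
#'
#' @param label Profile label.
#' @param criteria List of [criterion_profile()] objects with unique names.
#' @export
crop_profile <- function(label, criteria) {
  if (length(criteria) < 1) stop_input("crop profile needs at least one criterion")
  nms <- vapply(criteria, function(cr) cr$name, character(1))
  if (anyDuplicated(nms)) stop_input("duplicate criterion names in profile '%s'", label)
  names(criteria) <- nms
  structure(list(label = as.character(label), criteria = criteria),
            class = "crop_profile")
}

#' @export
print.crop_profile <- function(x, ...) {
  cat(sprintf("<crop_profile> %s\n", x$label))
  for (cr in x$criteria) {
    cat(sprintf("  %-16s (%s): abs [%g, %g], opt [%g, %g]\n", cr$name, cr$units,
                cr$set$abs_min, cr$set$abs_max, cr$set$opt_min, cr$set$opt_max))
  }
  invisible(x)
}

# Resolve a profile given as object, built-in label, or file path.
as_crop_profile <- function(profile) {
  if (inherits(profile, "crop_profile")) return(profile)
  if (is.character(profile) && length(profile) == 1) return(read_profile(profile))
  stop_input("cannot interpret 'profile'; give a crop_profile, built-in label, or file path")
}

builtin_profile_path <- function(label) {
  system.file("extdata", "profiles", paste0(label, ".json"),
              package = "cropsuit", mustWork = FALSE)
}

#' List the built-in crop profiles
#' @return Character vector of built-in profile labels.
#' @export
builtin_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "cropsuit")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

#' Read a crop profile from JSON (or by built-in label)
#'
#' The serialization is a flat JSON object: a `label` plus, per criterion,
#' `{abs_min, opt_min, opt_max, abs_max, units}`.
#'
#' @param path A file path, or the label of a packaged profile
#'   (`"breadfruit_final"`, `"breadfruit_ecocrop"`).
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    bp <- builtin_profile_path(path)
    if (nzchar(bp) && file.exists(bp)) path <- bp
    else stop_input("profile '%s' is neither a file nor a built-in label", path)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$label) || is.null(obj$criteria)) {
    stop_input("profile file '%s' must have 'label' and 'criteria'", path)
  }
  criteria <- lapply(names(obj$criteria), function(nm) {
    cr <- obj$criteria[[nm]]
    criterion_profile(nm, cr$units %||% "",
                      fuzzy_set(cr$abs_min, cr$opt_min, cr$opt_max, cr$abs_max))
  })
  crop_profile(obj$label, criteria)
}

#' Write a crop profile to JSON
#' @param profile A [crop_profile()].
#' @param path Output file path.
#' @export
write_profile <- function(profile, path) {
  profile <- as_crop_profile(profile)
  criteria <- lapply(profile$criteria, function(cr) {
    list(abs_min = cr$set$abs_min, opt_min = cr$set$opt_min,
         opt_max = cr$set$opt_max, abs_max = cr$set$abs_max,
         units = cr$units)
  })
  jsonlite::write_json(list(label = profile$label, criteria = criteria),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
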