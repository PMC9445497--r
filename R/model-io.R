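SAIBR_SCHEMA_VERSION <- 1L

#' Save a calibration model to a versioned JSON file
#'
#' All coefficients are written at full double precision, so a save/load
#' round trip reproduces them bit-exactly.
#'
#' @param model A fitted `saibr_model` (see [fit_two_channel()]).
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "saibr_model"))
  doc <- list(
    schema_version = SAIBR_SCHEMA_VERSION,
    mode = model$mode,
    c = model$c,
    s = model$s,
    gaussian_radius = model$gaussian_radius,
    n_pixels = model$n_pixels,
    r_squared = model$r_squared,
    sample_ids = model$sample_ids,
    method = model$method)
  if (model$mode == "two_channel") {
    doc$m <- model$m
  } else {
    doc$m1 <- model$m1
    doc$m2 <- model$m2
  }
  # digits = I(17): significant digits sufficient for exact double round trip
  jsonlite::write_json(doc[!vapply(doc, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' @param path Path to a JSON document written by [save_model()].
#' @return A `saibr_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    saibr_abort(sprintf("model file `%s` does not exist", path), class = "io")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) {
    saibr_abort("model file has no schema_version field", class = "schema")
  }
  if (doc$schema_version > SAIBR_SCHEMA_VERSION) {
    saibr_abort(
      sprintf("model schema version %s is newer than supported version %d",
              doc$schema_version, SAIBR_SCHEMA_VERSION),
      class = "version")
  }
  if (is.null(doc$mode) || !doc$mode %in% c("two_channel", "three_channel")) {
    saibr_abort("model file has missing or invalid `mode`", class = "schema")
  }
  required <- if (doc$mode == "two_channel") c("m", "c") else c("m1", "m2", "c")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    saibr_abort(sprintf("model file lacks required field(s): %s",
                        paste(missing, collapse = ", ")), class = "schema")
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  new_saibr_model(
    mode = doc$mode,
    m = num(doc$m), m1 = num(doc$m1), m2 = num(doc$m2), c = num(doc$c),
    s = num(doc$s),
    gaussian_radius = num(doc$gaussian_radius) %||% 2,
    n_pixels = as.integer(doc$n_pixels %||% NA_integer_),
    r_squared = num(doc$r_squared) %||% NA_real_,
    sample_ids = doc$sample_ids,
    method = doc$method %||% "pixel")
}
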