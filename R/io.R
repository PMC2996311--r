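#' Read bout durations from a plain-text or CSV file
#'
#' Accepts either one positive number per line or a CSV with a `duration`
#' column (an optional `component` column is carried along as an attribute).
#' Values below 1 epoch are rejected with an error naming the truncation
#' convention, and malformed lines are reported with their line number.
#'
#' @param path file to read.
#' @return a [bout_sample()].
#' @export
#' @examples
#' f <- tempfile(); writeLines(c("1.5", "2", "7.25"), f)
#' read_durations(f)
read_durations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first) || grepl("duration", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    if (!"duration" %in% names(df))
      stop("CSV input must have a `duration` column")
    x <- df$duration
    if (any(is.na(x)))
      stop("parse error: non-numeric duration at data row ",
           which(is.na(x))[1L])
    s <- bout_sample(x, provenance = list(family = "file", path = path))
    if ("component" %in% names(df)) attr(s, "component") <- df$component
    return(s)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  x <- suppressWarnings(as.numeric(lines))
  if (any(is.na(x))) {
    bad <- which(is.na(x))[1L]
    stop(sprintf("parse error at line %d: %s", bad, lines[bad]))
  }
  bout_sample(x, provenance = list(family = "file", path = path))
}

#' Write bout durations to a plain-text file
#'
#' One duration per line at full precision (17 significant digits), so that a
#' write/read round trip reproduces the sample exactly.
#'
#' @param sample a [bout_sample()] or numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_durations <- function(sample, path) {
  writeLines(format(as.numeric(sample), digits = 17, scientific = FALSE,
                    trim = TRUE), path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Fixed-schema record `{family, params, converged, constraint_ok, seed}`
#' covering both model families and non-convergence outcomes, written at full
#' precision so models round-trip exactly through [read_model_json()].
#'
#' @param model a [power_law_model()], [exp_mixture_model()] or
#'   `boutlaw_nonconvergence` outcome.
#' @param path output path.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  rec <- if (inherits(model, "power_law_model")) {
    list(family = "powerlaw",
         params = list(alpha = model$alpha, x_min = model$x_min),
         converged = TRUE, constraint_ok = TRUE, seed = seed)
  } else if (inherits(model, "exp_mixture_model")) {
    list(family = paste0("exp", model$k),
         params = list(amplitudes = model$amplitudes, taus = model$taus,
                       offset = 0),
         converged = TRUE, constraint_ok = TRUE, seed = seed)
  } else if (inherits(model, "boutlaw_nonconvergence")) {
    list(family = NA, params = NULL, converged = FALSE,
         constraint_ok = !identical(model$reason, "constraint-violation"),
         reason = model$reason, seed = seed)
  } else stop("unsupported model class")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (isFALSE(rec$converged)) return(nonconvergence(rec$reason))
  if (identical(rec$family, "powerlaw")) {
    return(power_law_model(rec$params$alpha, rec$params$x_min))
  }
  if (grepl("^exp[123]$", rec$family)) {
    return(exp_mixture_model(rec$params$amplitudes, rec$params$taus))
  }
  stop("unrecognized model record in ", path)
}
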