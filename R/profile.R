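#' Lane intensity profiles
#'
#' An `intensity_profile` holds the densitometry of a single gel lane: an
#' ordered vector of electrophoretic distances (mm from the well) and the
#' staining intensity (arbitrary units, AU) measured at each distance.  It is
#' a `data.frame` with columns `distance_mm` and `intensity_au`, plus a lane
#' identifier and a free-form metadata list carried as attributes.
#'
#' @param distance_mm numeric, strictly increasing distances in mm from the
#'   well (0 = well, increasing toward the gel bottom).
#' @param intensity_au numeric intensities in AU, same length as
#'   `distance_mm`.  All values must be finite.
#' @param lane_id character label for the lane.
#' @param metadata named list of provenance information.
#'
#' @return An object of class `intensity_profile`.
#' @seealso [read_profile()], [subtract_background()], [smooth_profile()]
#' @export
intensity_profile <- function(distance_mm, intensity_au,
                              lane_id = NA_character_, metadata = list()) {
  distance_mm <- as.numeric(distance_mm)
  intensity_au <- as.numeric(intensity_au)
  if (length(distance_mm) != length(intensity_au)) {
    stop("`distance_mm` and `intensity_au` must have the same length",
         call. = FALSE)
  }
  if (length(distance_mm) < 1L) stop("empty profile", call. = FALSE)
  if (any(!is.finite(distance_mm)) || any(!is.finite(intensity_au))) {
    stop("distances and intensities must be finite", call. = FALSE)
  }
  if (any(diff(distance_mm) <= 0)) {
    stop("distances must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(distance_mm = distance_mm, intensity_au = intensity_au),
    lane_id = as.character(lane_id),
    metadata = metadata,
    class = c("intensity_profile", "data.frame")
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Lane intensity profile '%s': %d samples, %.2f-%.2f mm\n",
              lane_id(x), nrow(x), min(x$distance_mm), max(x$distance_mm)))
  cat(sprintf("  intensity range %.4g-%.4g AU\n",
              min(x$intensity_au), max(x$intensity_au)))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...,
                                   xlab = "distance from well (mm)",
                                   ylab = "intensity (AU)", type = "l") {
  graphics::plot(x$distance_mm, x$intensity_au, type = type,
                 xlab = xlab, ylab = ylab,
                 main = lane_id(x), ...)
  invisible(x)
}

#' Lane identifier of a profile or derived object
#' @param x an object carrying a `lane_id` attribute.
#' @return character scalar (possibly `NA`).
#' @export
lane_id <- function(x) attr(x, "lane_id") %||% NA_character_

# Rebuild a profile with new intensities, carrying attributes forward.
update_profile <- function(profile, intensity_au, extra_meta = list()) {
  meta <- attr(profile, "metadata") %||% list()
  meta[names(extra_meta)] <- extra_meta
  intensity_profile(profile$distance_mm, intensity_au,
                    lane_id = lane_id(profile), metadata = meta)
}

#' Read a lane profile from a two-column text file
#'
#' Reads densitometry exported as tab-, comma- or whitespace-separated text
#' with two numeric columns (distance in mm, intensity in AU).  Lines starting
#' with `#` are treated as comments.  Rows are sorted by distance; duplicate
#' distances and non-numeric rows are rejected with the offending line number.
#'
#' @param path path to the file.
#' @param lane_id label for the lane; defaults to the file name without
#'   extension.
#' @return An [intensity_profile()].
#' @export
read_profile <- function(path, lane_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  id_line <- grep("^#\\s*lane_id:", lines, value = TRUE)
  if (is.null(lane_id) && length(id_line)) {
    lane_id <- trimws(sub("^#\\s*lane_id:", "", id_line[1L]))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[idx]), "[\t,;]+|\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected two columns", idx[bad[1L]], path),
         call. = FALSE)
  }
  d <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  i <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(d) | !is.finite(i))
  if (length(bad)) {
    stop(sprintf("line %d of %s: non-numeric value", idx[bad[1L]], path),
         call. = FALSE)
  }
  dup <- which(duplicated(d))
  if (length(dup)) {
    stop(sprintf("line %d of %s: duplicated distance %g mm",
                 idx[dup[1L]], path, d[dup[1L]]), call. = FALSE)
  }
  ord <- order(d)
  intensity_profile(d[ord], i[ord],
                    lane_id = lane_id %||%
                      sub("\\.[^.]*$", "", basename(path)),
                    metadata = list(source = path))
}

#' Write a lane profile to a two-column TSV file
#'
#' The inverse of [read_profile()].  Scalar metadata entries are written as
#' `# key: value` comment lines so that configuration provenance travels with
#' the data.
#'
#' @param profile an [intensity_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  meta <- attr(profile, "metadata") %||% list()
  hdr <- c(sprintf("# lane_id: %s", lane_id(profile)))
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.atomic(v) && length(v) == 1L) {
      hdr <- c(hdr, sprintf("# %s: %s", nm, format(v, digits = 15)))
    }
  }
  body <- sprintf("%.6g\t%.8g", profile$distance_mm, profile$intensity_au)
  writeLines(c(hdr, "# distance_mm\tintensity_au", body), path)
  invisible(path)
}
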