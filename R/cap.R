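#' Cap layout specification
#'
#' Declares how the rows of a Polhemus digitization file are organised:
#' reference landmarks first, then sources, then detectors, one 3D point per
#' row. The unit flag covers digitizers left at their factory default of
#' inches; coordinates are converted to centimeters on read and kept in
#' centimeters internally.
#'
#' @param n_landmarks,n_sources,n_detectors Non-negative point counts.
#' @param unit `"cm"` (default) or `"in"`; inches are converted on read.
#' @param landmark_labels Labels for the landmark rows. Defaults to the
#'   conventional five-point set (nasion, inion, left/right pre-auricular,
#'   vertex), truncated to `n_landmarks`.
#' @return An object of class `cap_layout`.
#' @export
cap_layout <- function(n_landmarks, n_sources, n_detectors, unit = c("cm", "in"),
                       landmark_labels = NULL) {
  unit <- match.arg(unit)
  stopifnot(n_landmarks >= 0, n_sources >= 0, n_detectors >= 0,
            n_landmarks + n_sources + n_detectors > 0)
  if (is.null(landmark_labels)) {
    landmark_labels <- c("nz", "iz", "ar", "al", "cz")
    if (n_landmarks > length(landmark_labels)) {
      landmark_labels <- c(landmark_labels,
                           paste0("ref", seq_len(n_landmarks - length(landmark_labels)) + 5L))
    }
    landmark_labels <- landmark_labels[seq_len(n_landmarks)]
  }
  stopifnot(length(landmark_labels) == n_landmarks)
  structure(list(n_landmarks = n_landmarks, n_sources = n_sources,
                 n_detectors = n_detectors, unit = unit,
                 landmark_labels = landmark_labels),
            class = "cap_layout")
}

#' Construct a cap (one digitization)
#'
#' A cap is an ordered, labeled set of 3D points in centimeters: landmarks,
#' then sources, then detectors. This ordering is an invariant relied on by
#' every alignment routine (correspondence is positional, not searched).
#'
#' @param points Numeric n x 3 matrix of coordinates (cm).
#' @param roles Character vector: `"landmark"`, `"source"` or `"detector"`.
#' @param labels Character point labels (e.g. `"nz"`, `"s1"`, `"d3"`).
#' @param cap_id Identifier for this digitization.
#' @param cap_size_cm Head circumference the cap was built for.
#' @param replaced_mask Logical; `TRUE` where the stored value came from a
#'   template rather than the digitizer.
#' @return An object of class `cap`.
#' @export
new_cap <- function(points, roles, labels, cap_id = "cap", cap_size_cm = NA_real_,
                    replaced_mask = rep(FALSE, nrow(points))) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop_fnirsdot("cap points must be an n x 3 matrix", "cap_invalid")
  if (!all(is.finite(points)))
    stop_fnirsdot("cap points must all be finite", "cap_invalid")
  n <- nrow(points)
  roles <- as.character(roles)
  if (length(roles) != n || length(labels) != n || length(replaced_mask) != n)
    stop_fnirsdot("roles, labels and replaced_mask must match the point count",
                  "cap_invalid")
  if (!all(roles %in% c("landmark", "source", "detector")))
    stop_fnirsdot("roles must be landmark, source or detector", "cap_invalid")
  ord <- match(roles, c("landmark", "source", "detector"))
  if (is.unsorted(ord))
    stop_fnirsdot("points must be stored landmarks, then sources, then detectors",
                  "cap_invalid")
  dimnames(points) <- list(as.character(labels), c("x", "y", "z"))
  structure(list(cap_id = cap_id, cap_size_cm = cap_size_cm, points = points,
                 roles = roles, labels = as.character(labels),
                 replaced_mask = as.logical(replaced_mask)),
            class = "cap")
}

#' @export
print.cap <- function(x, ...) {
  cat(sprintf("<cap> %s (size %s cm): %d landmarks, %d sources, %d detectors",
              x$cap_id, format(x$cap_size_cm), sum(x$roles == "landmark"),
              sum(x$roles == "source"), sum(x$roles == "detector")), "\n")
  if (any(x$replaced_mask))
    cat(sprintf("  %d point(s) replaced from a template: %s\n",
                sum(x$replaced_mask),
                paste(x$labels[x$replaced_mask], collapse = ", ")))
  invisible(x)
}

default_labels <- function(layout) {
  c(layout$landmark_labels,
    if (layout$n_sources > 0) paste0("s", seq_len(layout$n_sources)),
    if (layout$n_detectors > 0) paste0("d", seq_len(layout$n_detectors)))
}

#' Read a Polhemus digitization file
#'
#' Reads an ASCII file with one 3D point per row (whitespace separated), the
#' rows ordered landmarks, sources, detectors as declared by `layout`.
#'
#' @param path File path.
#' @param layout A [cap_layout()] declaring point counts and unit.
#' @param cap_id,cap_size_cm Metadata attached to the returned cap.
#' @return A [new_cap()] object, coordinates in cm.
#' @export
read_polhemus <- function(path, layout, cap_id = basename(path),
                          cap_size_cm = NA_real_) {
  stopifnot(inherits(layout, "cap_layout"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_fnirsdot(sprintf("'%s' contains no data rows", path), "parse_error")
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
    if (length(v) != 3L || anyNA(v))
      stop_fnirsdot(sprintf("non-numeric or non-3D row in '%s': \"%s\"", path, l),
                    "parse_error")
    v
  })
  pts <- do.call(rbind, rows)
  total <- layout$n_landmarks + layout$n_sources + layout$n_detectors
  if (nrow(pts) != total)
    stop_fnirsdot(sprintf("'%s' has %d rows but the layout declares %d points",
                          path, nrow(pts), total), "layout_mismatch")
  if (layout$unit == "in") pts <- pts * 2.54
  roles <- rep(c("landmark", "source", "detector"),
               c(layout$n_landmarks, layout$n_sources, layout$n_detectors))
  new_cap(pts, roles, default_labels(layout), cap_id = cap_id,
          cap_size_cm = cap_size_cm)
}

#' Write a cap as a plain Polhemus-style file
#'
#' One `x y z` row per point in cm, in storage order. Inverse of
#' [read_polhemus()] for a matching layout.
#'
#' @param cap A cap.
#' @param path Output file path.
#' @export
write_polhemus <- function(cap, path) {
  stopifnot(inherits(cap, "cap"))
  write.table(format(cap$points, digits = 12, trim = TRUE, scientific = FALSE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export caps in the digpts.txt dialect
#'
#' Writes each cap in its own subfolder of `out_dir` as `digpts.txt`, one
#' `label: x y z` line per point (landmarks, then sources, then detectors),
#' with coordinates converted from centimeters to millimeters — the format
#' consumed by common fNIRS anatomy tools.
#'
#' @param caps A cap or list of caps.
#' @param out_dir Directory; one subfolder per cap is created.
#' @return Paths of the written files, invisibly.
#' @export
save_digpts <- function(caps, out_dir) {
  if (inherits(caps, "cap")) caps <- list(caps)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_fnirsdot(sprintf("cannot create '%s'", out_dir), "io_error")
  paths <- vapply(caps, function(cap) {
    stopifnot(inherits(cap, "cap"))
    if (any(!nzchar(cap$labels)))
      stop_fnirsdot("all points must be labeled to export digpts", "cap_invalid")
    d <- file.path(out_dir, cap$cap_id)
    if (!dir.exists(d) && !dir.create(d))
      stop_fnirsdot(sprintf("cannot create '%s'", d), "io_error")
    mm <- cap$points * 10
    num <- function(v) vapply(v, function(x)
      format(x, digits = 12, trim = TRUE, scientific = FALSE), character(1))
    lines <- sprintf("%s: %s %s %s", cap$labels,
                     num(mm[, 1]), num(mm[, 2]), num(mm[, 3]))
    f <- file.path(d, "digpts.txt")
    ok <- tryCatch({ writeLines(lines, f); TRUE }, error = function(e) FALSE)
    if (!ok) stop_fnirsdot(sprintf("cannot write '%s'", f), "io_error")
    f
  }, character(1))
  invisible(paths)
}

#' Read a digpts.txt file back into a cap
#'
#' @param path A `digpts.txt` file written by [save_digpts()] (mm, converted
#'   back to cm).
#' @param cap_id,cap_size_cm Metadata for the returned cap.
#' @export
read_digpts <- function(path, cap_id = basename(dirname(path)),
                        cap_size_cm = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fnirsdot("empty digpts file", "parse_error")
  m <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*$", lines))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad))
    stop_fnirsdot(sprintf("malformed digpts line: \"%s\"", lines[which(bad)[1]]),
                  "parse_error")
  labels <- vapply(m, `[[`, character(1), 2L)
  pts <- t(vapply(m, function(g) as.numeric(g[3:5]), numeric(3))) / 10
  roles <- ifelse(grepl("^s[0-9]+$", labels), "source",
                  ifelse(grepl("^d[0-9]+$", labels), "detector", "landmark"))
  new_cap(pts, roles, labels, cap_id = cap_id, cap_size_cm = cap_size_cm)
}
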