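# Individual-cap correction against a per-size template.
#
# All three methods separate true variance in cap placement (kept) from
# digitizer slips (replaced from the template). Threshold comparisons are
# strict: a point is dropped when its distance exceeds ("> ") the threshold.

# Shared core: iterate over a vector of thresholds, re-aligning on the
# currently retained points each pass, then replace dropped points with the
# template's points in the final aligned frame.
correct_against_template <- function(cap, template, thresholds,
                                     stop_when_within = NULL,
                                     max_prop_replaced = 1) {
  n <- nrow(cap$points)
  retained <- rep(TRUE, n)
  used <- numeric(0)
  last_dist <- rep(NA_real_, n)
  for (thr in thresholds) {
    if (sum(retained) < 3L)
      stop_fnirsdot("too few points retained to align (degenerate cap)",
                    "degenerate_cap")
    al <- kabsch_align(cap, template, point_subset = retained)
    last_dist <- al$distances
    if (!is.null(stop_when_within) && all(al$distances[retained] <= stop_when_within)) {
      used <- used
      break
    }
    drop <- retained & al$distances > thr
    if ((sum(!retained) + sum(drop)) / n > max_prop_replaced) break
    used <- c(used, thr)
    retained <- retained & !drop
  }
  if (!any(retained))
    stop_fnirsdot("all points dropped before the final pass (degenerate cap)",
                  "degenerate_cap")
  final <- kabsch_align(cap, template, point_subset = retained)
  pts <- final$aligned$points
  pts[!retained, ] <- template_points(template)[!retained, , drop = FALSE]
  corrected <- cap
  corrected$points <- pts
  dimnames(corrected$points) <- dimnames(cap$points)
  corrected$replaced_mask <- unname(!retained)
  report <- structure(list(thresholds_used = used,
                           distances_cm = final$distances,
                           replaced = unname(which(!retained)),
                           proportion_replaced = mean(!retained)),
                      class = "correction_report")
  list(cap = corrected, report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("<correction_report> passes at %s cm; %d/%d points replaced (%.1f%%)\n",
              paste(format(x$thresholds_used), collapse = ", "),
              length(x$replaced), length(x$distances_cm),
              100 * x$proportion_replaced))
  invisible(x)
}

#' Three-step alignment correction
#'
#' Aligns a cap to its template in three sequential passes with user-chosen
#' threshold distances `d1 >= d2 >= d3` (cm). Each pass aligns on the points
#' retained so far, drops points whose 3D distance to the template exceeds the
#' pass threshold, and re-aligns without them. After the third pass, dropped
#' points are replaced with the template's points in the final aligned frame,
#' so the corrected cap is co-registered with the template. Untouched points
#' keep their (aligned) measured coordinates. A practical goal when choosing
#' the distances is that no more than about a third of the points end up
#' replaced.
#'
#' @param cap Cap to correct.
#' @param template Template (or cap) with the same layout.
#' @param d1,d2,d3 Pass thresholds in cm, non-increasing. 12, 10 and 7 cm are
#'   reasonable for whole-head caps.
#' @return A list with `cap` (corrected, `replaced_mask` set) and `report`
#'   (a `correction_report`).
#' @export
threestep_alignment <- function(cap, template, d1 = 12, d2 = 10, d3 = 7) {
  stopifnot(d1 >= d2, d2 >= d3, d3 > 0)
  correct_against_template(cap, template, thresholds = c(d1, d2, d3))
}

#' Iterative alignment correction
#'
#' Like the three-step method but with an automatic threshold schedule: the
#' first pass uses a 3D distance of 20 cm and each subsequent pass reduces the
#' threshold by 1 cm, re-aligning each time. Iteration stops when replacing
#' the next batch of points would push the replaced proportion beyond
#' `max_prop_replaced`, or when all retained points already lie within 0.5 cm
#' of the template.
#'
#' @inheritParams threestep_alignment
#' @param max_prop_replaced Maximum tolerated proportion of replaced points,
#'   in (0, 1].
#' @export
iterative_alignment <- function(cap, template, max_prop_replaced = 1/3) {
  stopifnot(max_prop_replaced > 0, max_prop_replaced <= 1)
  correct_against_template(cap, template, thresholds = seq(20, 1, by = -1),
                           stop_when_within = 0.5,
                           max_prop_replaced = max_prop_replaced)
}

#' Head-wise correction
#'
#' Deals with entire caps rather than individual points: each cap is aligned
#' to the template and its mean per-point 3D distance computed. Caps whose
#' mean distance exceeds `threshold_cm` are replaced wholesale by the
#' template; the rest are kept, aligned but otherwise unmodified.
#'
#' @param caps List of caps.
#' @param template Template with the same layout.
#' @param threshold_cm Mean-distance criterion in cm.
#' @return A list, one element per cap: `cap` (aligned or template copy),
#'   `replaced` flag, and `mean_distance_cm`.
#' @export
headwise_alignment <- function(caps, template, threshold_cm) {
  stopifnot(threshold_cm > 0)
  lapply(caps, function(cap) {
    al <- kabsch_align(cap, template)
    md <- mean(al$distances)
    if (md > threshold_cm) {
      repl <- template_as_cap(template, cap_id = cap$cap_id)
      repl$replaced_mask <- rep(TRUE, nrow(repl$points))
      list(cap = repl, replaced = TRUE, mean_distance_cm = md)
    } else {
      list(cap = al$aligned, replaced = FALSE, mean_distance_cm = md)
    }
  })
}
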