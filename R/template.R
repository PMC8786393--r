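#' Build a consensus template from caps of one size
#'
#' Every cap is rigidly aligned (Kabsch) to every other cap. A pair "matches"
#' when, after alignment, no point lies further than `threshold_cm` from its
#' counterpart. The cap with the most matches becomes the reference (ties are
#' broken by the lowest mean 3D distance to its matches, then by cap_id); the
#' template is the pointwise 3D mean over the reference and its matching caps
#' after alignment to the reference. Well-digitized caps align mutually; a bad
#' digitization fails to match anything and is excluded from the mean.
#'
#' @param caps List of caps sharing one layout and cap size (at least 2).
#' @param threshold_cm Match criterion: maximum allowed per-point 3D distance
#'   after alignment. 10 cm is a workable value for whole-head infant caps.
#' @return An object of class `cap_template` (usable wherever a cap-like
#'   reference is accepted) with `n_contributing` and `threshold_cm` recorded.
#' @export
build_template <- function(caps, threshold_cm) {
  stopifnot(is.list(caps), length(caps) >= 2L, threshold_cm > 0)
  n <- length(caps)
  ids <- vapply(caps, function(cp) cp$cap_id, character(1))
  npts <- vapply(caps, function(cp) nrow(cp$points), integer(1))
  if (length(unique(npts)) != 1L)
    stop_fnirsdot("all caps must share one layout", "layout_mismatch")

  # max and mean post-alignment distance for every ordered pair
  maxd <- matrix(Inf, n, n)
  meand <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      al <- kabsch_align(caps[[j]], caps[[i]])
      maxd[i, j] <- max(al$distances)
      meand[i, j] <- mean(al$distances)
    }
  }
  match_mat <- maxd <= threshold_cm        # strict ">" means replacement/exclusion
  n_matches <- rowSums(match_mat)
  if (all(n_matches == 0L)) {
    msg <- paste0("no cap matches any other within ", threshold_cm,
                  " cm; pairwise max distances (cm):\n",
                  paste(utils::capture.output(print(round(maxd, 2))), collapse = "\n"))
    stop_fnirsdot(msg, "no_consensus")
  }
  mean_to_matches <- vapply(seq_len(n), function(i) {
    if (n_matches[i] == 0L) Inf else mean(meand[i, match_mat[i, ]])
  }, numeric(1))
  ord <- order(-n_matches, mean_to_matches, ids)
  ref <- ord[1L]

  members <- c(ref, which(match_mat[ref, ]))
  acc <- caps[[ref]]$points
  for (j in setdiff(members, ref))
    acc <- acc + kabsch_align(caps[[j]], caps[[ref]])$aligned$points
  pts <- acc / length(members)

  ref_cap <- caps[[ref]]
  structure(list(cap_id = paste0("template_", format(ref_cap$cap_size_cm)),
                 cap_size_cm = ref_cap$cap_size_cm, points = pts,
                 roles = ref_cap$roles, labels = ref_cap$labels,
                 replaced_mask = rep(FALSE, nrow(pts)),
                 n_contributing = length(members),
                 threshold_cm = threshold_cm,
                 reference_id = ref_cap$cap_id),
            class = c("cap_template", "cap"))
}

#' @export
print.cap_template <- function(x, ...) {
  cat(sprintf("<cap_template> size %s cm: %d points, mean of %d cap(s), threshold %g cm\n",
              format(x$cap_size_cm), nrow(x$points), x$n_contributing, x$threshold_cm))
  invisible(x)
}

#' Treat a template as an ordinary cap
#' @param template A `cap_template`.
#' @param cap_id Identifier for the resulting cap.
#' @export
template_as_cap <- function(template, cap_id = template$cap_id) {
  new_cap(template$points, template$roles, template$labels, cap_id = cap_id,
          cap_size_cm = template$cap_size_cm)
}
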