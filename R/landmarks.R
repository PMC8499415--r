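#' Find convex/concave transition segments in a curvature profile
#'
#' Locates sign changes of the signed curvature (boundary-flagged samples
#' excluded) and qualifies a transition only when the adjoining convex and
#' concave runs each span at least `min_run` mm and the concave run's
#' curvature extremum magnitude reaches `min_prominence` 1/mm. Both gate
#' defaults are configurable; the prominence default sits below the 5th
#' percentile of clinically observed CEJ curvature (0.32 1/mm) with margin.
#' Each qualifying adjacency is reported twice conceptually: a convex run
#' followed (coronal to apical) by a concave run is a corono-apical
#' convex-to-concave transition; a concave run followed by a convex run is,
#' read in the opposite scan direction, the apico-coronal convex-to-concave
#' transition used for the gingival margin.
#'
#' @param profile a `curvature_profile` from [signed_curvature()].
#' @param min_prominence minimal concave extremum magnitude (1/mm).
#' @param min_run minimal run span (mm) for both adjoining runs.
#' @return list of transition segments (possibly empty), ordered coronal to
#'   apical; each has `kind`, `scan_direction`, `s_start`, `s_end`,
#'   `concave_range` (index range into the profile), `extremum_idx`,
#'   `extremum_s`, `extremum_kappa`.
#' @export
find_transitions <- function(profile, min_prominence = 0.1, min_run = 0.05) {
  stopifnot(inherits(profile, "curvature_profile"))
  idx <- which(!profile$boundary)
  k <- profile$kappa[idx]
  s <- profile$curve$s[idx]
  sgn <- sign(k)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  span <- s[ends] - s[starts]
  segs <- list()
  for (i in seq_len(max(length(r$values) - 1L, 0L))) {
    v1 <- r$values[i]; v2 <- r$values[i + 1L]
    pair <- NULL
    if (v1 == 1 && v2 == -1) {
      pair <- list(scan = "corono_apical", convex = i, concave = i + 1L)
    } else if (v1 == -1 && v2 == 1) {
      pair <- list(scan = "apico_coronal", convex = i + 1L, concave = i)
    }
    if (is.null(pair)) next
    if (span[pair$convex] < min_run || span[pair$concave] < min_run) next
    ci <- starts[pair$concave]:ends[pair$concave]
    ex_local <- ci[which.min(k[ci])]       # ties -> smallest index (coronal)
    if (-k[ex_local] < min_prominence) next
    segs[[length(segs) + 1L]] <- list(
      kind = "convex_concave",
      scan_direction = pair$scan,
      s_start = s[starts[min(pair$convex, pair$concave)]],
      s_end = s[ends[max(pair$convex, pair$concave)]],
      concave_range = idx[c(ci[1L], ci[length(ci)])],
      extremum_idx = idx[ex_local],
      extremum_s = s[ex_local],
      extremum_kappa = k[ex_local])
  }
  if (length(segs) > 1L) {
    ord <- order(vapply(segs, `[[`, 1, "s_start"))
    segs <- segs[ord]
  }
  segs
}

landmark_error <- function(msg, kind, segments) {
  cand <- if (length(segments))
    vapply(segments, function(sg)
      sprintf("%s scan at s=[%.2f,%.2f], extremum %.3f 1/mm at s=%.2f",
              sg$scan_direction, sg$s_start, sg$s_end,
              sg$extremum_kappa, sg$extremum_s), "")
  else "no candidate segments"
  stop(structure(class = c("gingrec_landmark_error", "error", "condition"),
                 list(message = paste0(msg, " [", kind, "] candidates: ",
                                       paste(cand, collapse = "; ")),
                      call = sys.call(-1), kind = kind,
                      candidates = segments)))
}

make_landmark <- function(kind, profile, segment) {
  i <- segment$extremum_idx
  structure(list(kind = kind,
                 s = profile$curve$s[i],
                 point = profile$curve$points[i, ],
                 kappa = profile$kappa[i],
                 index = i,
                 segment = segment),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark %s> s = %.3f mm, (y, z) = (%.3f, %.3f), kappa = %.3f 1/mm\n",
              x$kind, x$s, x$point[1], x$point[2], x$kappa))
  invisible(x)
}

#' Detect the cemento-enamel junction (CEJ) landmark
#'
#' Scanning coronal to apical, the first qualifying convex-to-concave
#' transition is the CEJ segment; the landmark is the sample of minimal
#' (most negative) curvature within its concave run, ties broken toward the
#' most coronal sample.
#'
#' @param profile a `curvature_profile`.
#' @param segments transitions from [find_transitions()]; computed when NULL.
#' @param ... gate parameters passed to [find_transitions()].
#' @return a `landmark` of kind `"CEJ"`.
#' @export
detect_cej <- function(profile, segments = NULL, ...) {
  if (is.null(segments)) segments <- find_transitions(profile, ...)
  ca <- Filter(function(sg) sg$scan_direction == "corono_apical", segments)
  if (length(ca) == 0L)
    landmark_error("no qualifying convex-to-concave transition", "CEJ",
                   segments)
  make_landmark("CEJ", profile, ca[[1L]])
}

#' Detect the gingival margin (GM) landmark
#'
#' Scanning apical to coronal, the first qualifying convex-to-concave
#' transition (in that scan direction) is the GM segment; the landmark is its
#' minimal-curvature sample. When a CEJ landmark is supplied the GM must lie
#' apical to it (smaller z), otherwise an orientation error is raised.
#'
#' @param profile a `curvature_profile`.
#' @param segments transitions from [find_transitions()]; computed when NULL.
#' @param cej optional CEJ `landmark` for the orientation check.
#' @param ... gate parameters passed to [find_transitions()].
#' @return a `landmark` of kind `"GM"`.
#' @export
detect_gm <- function(profile, segments = NULL, cej = NULL, ...) {
  if (is.null(segments)) segments <- find_transitions(profile, ...)
  ac <- Filter(function(sg) sg$scan_direction == "apico_coronal", segments)
  if (length(ac) == 0L)
    landmark_error("no qualifying convex-to-concave transition", "GM",
                   segments)
  # first segment encountered when scanning from the apical end
  sg <- ac[[which.max(vapply(ac, `[[`, 1, "s_end"))]]
  lm <- make_landmark("GM", profile, sg)
  if (!is.null(cej) && lm$point[2] >= cej$point[2])
    stop(structure(class = c("gingrec_orientation_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "GM (z = %.3f) not apical to CEJ (z = %.3f)",
                     lm$point[2], cej$point[2]), call = sys.call())))
  lm
}

#' Detect both landmarks and build a detection report
#'
#' @param profile a `curvature_profile`.
#' @param site_id label for the report.
#' @param min_prominence,min_run gates, see [find_transitions()].
#' @return list with `cej`, `gm` landmarks and `report` (site, landmarks,
#'   all candidate segments, gate parameters) suitable for JSON export.
#' @export
detect_landmarks <- function(profile, site_id = "site",
                             min_prominence = 0.1, min_run = 0.05) {
  segments <- find_transitions(profile, min_prominence, min_run)
  cej <- detect_cej(profile, segments)
  gm <- detect_gm(profile, segments, cej = cej)
  report <- list(
    site_id = site_id,
    cej = landmark_as_list(cej),
    gm = landmark_as_list(gm),
    candidates = lapply(segments, function(sg)
      sg[c("kind", "scan_direction", "s_start", "s_end",
           "extremum_s", "extremum_kappa")]),
    gates = list(min_prominence = min_prominence, min_run = min_run),
    h = profile$curve$h)
  list(cej = cej, gm = gm, report = report)
}

landmark_as_list <- function(lm) {
  list(kind = lm$kind, s = lm$s, y = lm$point[1], z = lm$point[2],
       kappa = lm$kappa)
}

#' Write a detection report as JSON
#'
#' @param report the `report` element of [detect_landmarks()].
#' @param path output path.
#' @export
write_detection_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}
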