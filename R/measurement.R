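#' Recession depth between two measurement points
#'
#' In-plane Euclidean distance between the CEJ and GM points (landmarks or
#' raw 2D picks), the digital-ruler reading between two selected points.
#' Full precision is kept internally; rounding to 0.01 mm belongs to display
#' and CSV export only.
#'
#' @param cej,gm a `landmark` or numeric (y, z) pair in mm.
#' @return distance in mm.
#' @export
recession_depth <- function(cej, gm) {
  p <- landmark_point(cej)
  q <- landmark_point(gm)
  sqrt(sum((p - q)^2))
}

landmark_point <- function(x) {
  if (inherits(x, "landmark")) return(as.numeric(x$point))
  x <- as.numeric(x)
  if (length(x) != 2L) stop("a measurement point must be a (y, z) pair")
  x
}

#' Signed arc-length deviation of a manual pick from the automated landmark
#'
#' The manual point is snapped to the nearest curve sample; its along-curve
#' (arc-length) distance to the reference landmark is returned, signed so
#' that picks coronal to the reference are positive and apical picks
#' negative. Points farther than 0.5 mm from the curve raise an off-curve
#' error; snapping distances above 0.05 mm are recorded in the result.
#'
#' @param manual numeric (y, z) pick in mm, or a single arc-length s value
#'   given as `c(s = ...)`.
#' @param reference the automated `landmark`.
#' @param curve the `sampled_curve` both points live on.
#' @return list of class `deviation_record`: `deviation` (mm, + coronal),
#'   `s_manual`, `snap_distance`, `snapped` flag, `reference_kappa`.
#' @export
arc_length_deviation <- function(manual, reference, curve) {
  stopifnot(inherits(reference, "landmark"),
            inherits(curve, "sampled_curve"))
  if (!is.null(names(manual)) && identical(names(manual), "s")) {
    s_manual <- as.numeric(manual)
    if (s_manual < 0 || s_manual > max(curve$s))
      stop("off-curve error: s outside the curve")
    snap <- 0
  } else {
    p <- as.numeric(manual)
    if (length(p) != 2L) stop("manual pick must be a (y, z) pair")
    d2 <- (curve$points[, 1] - p[1])^2 + (curve$points[, 2] - p[2])^2
    i <- which.min(d2)
    snap <- sqrt(d2[i])
    if (snap > 0.5)
      stop(sprintf(
        "off-curve error: manual point %.3f mm from the curve (max 0.5)",
        snap))
    s_manual <- curve$s[i]
  }
  structure(list(deviation = reference$s - s_manual,
                 s_manual = s_manual,
                 snap_distance = snap,
                 snapped = snap > 0.05,
                 reference_kappa = reference$kappa),
            class = "deviation_record")
}

#' Batch measurement over many sites
#'
#' Runs landmark detection on every supplied curvature profile, computes the
#' automated recession depth per site, and — when a manual-pick table is
#' given — the signed arc-length deviation of every pick plus manual depth
#' records for complete CEJ/GM pick pairs. Sites where detection fails are
#' carried through with their failure reason, never dropped.
#'
#' @param sections named list of `curvature_profile` objects (names are site
#'   ids) or a list of `list(site_id=, profile=)` entries.
#' @param picks optional data.frame with columns `site_id`, `examiner`,
#'   `round`, `landmark` ("CEJ"/"GM") and either `s` or `y`,`z`.
#' @param min_prominence,min_run detection gates, see [find_transitions()].
#' @return list with data.frames `measurements` (site_id, method, round,
#'   cej_s, gm_s, cej_y, cej_z, gm_y, gm_z, depth_mm, status) and
#'   `deviations` (site_id, examiner, round, landmark, deviation_mm,
#'   reference_kappa_per_mm, snapped), plus `reports` (per-site detection
#'   reports).
#' @export
batch_measure <- function(sections, picks = NULL,
                          min_prominence = 0.1, min_run = 0.05) {
  sections <- normalise_sections(sections)
  meas <- list(); devs <- list(); reports <- list()
  detections <- list()
  for (site in names(sections)) {
    profile <- sections[[site]]
    det <- tryCatch(
      detect_landmarks(profile, site_id = site,
                       min_prominence = min_prominence, min_run = min_run),
      error = function(e) e)
    if (inherits(det, "error")) {
      meas[[length(meas) + 1L]] <- data.frame(
        site_id = site, method = "automated", round = NA_integer_,
        cej_s = NA_real_, gm_s = NA_real_, cej_y = NA_real_,
        cej_z = NA_real_, gm_y = NA_real_, gm_z = NA_real_,
        depth_mm = NA_real_, status = conditionMessage(det))
      next
    }
    detections[[site]] <- det
    reports[[site]] <- det$report
    meas[[length(meas) + 1L]] <- data.frame(
      site_id = site, method = "automated", round = NA_integer_,
      cej_s = det$cej$s, gm_s = det$gm$s,
      cej_y = det$cej$point[1], cej_z = det$cej$point[2],
      gm_y = det$gm$point[1], gm_z = det$gm$point[2],
      depth_mm = recession_depth(det$cej, det$gm), status = "ok")
  }
  if (!is.null(picks)) {
    picks <- as.data.frame(picks)
    req <- c("site_id", "examiner", "round", "landmark")
    if (!all(req %in% names(picks)))
      stop("picks table needs columns: ", paste(req, collapse = ", "))
    key <- interaction(picks$site_id, picks$examiner, picks$round,
                       picks$landmark, drop = TRUE)
    if (anyDuplicated(key))
      stop("duplicate (site, examiner, round, landmark) rows in picks")
    manual_pts <- list()
    for (i in seq_len(nrow(picks))) {
      row <- picks[i, ]
      site <- as.character(row$site_id)
      det <- detections[[site]]
      if (is.null(det)) next                 # site flagged above
      profile <- sections[[site]]
      ref <- if (row$landmark == "CEJ") det$cej else det$gm
      manual <- if ("s" %in% names(picks) && !is.na(row$s))
        c(s = row$s) else c(row$y, row$z)
      dr <- tryCatch(arc_length_deviation(manual, ref, profile$curve),
                     error = function(e) e)
      if (inherits(dr, "error")) {
        devs[[length(devs) + 1L]] <- data.frame(
          site_id = site, examiner = row$examiner, round = row$round,
          landmark = row$landmark, deviation_mm = NA_real_,
          reference_kappa_per_mm = ref$kappa, snapped = NA,
          status = conditionMessage(dr))
        next
      }
      devs[[length(devs) + 1L]] <- data.frame(
        site_id = site, examiner = row$examiner, round = row$round,
        landmark = row$landmark, deviation_mm = dr$deviation,
        reference_kappa_per_mm = ref$kappa, snapped = dr$snapped,
        status = "ok")
      # remember the snapped manual point for manual depth records
      i_s <- which.min(abs(profile$curve$s - dr$s_manual))
      manual_pts[[paste(site, row$examiner, row$round, row$landmark)]] <-
        profile$curve$points[i_s, ]
    }
    # manual depth records for complete CEJ/GM pairs
    combos <- unique(picks[, c("site_id", "examiner", "round")])
    for (i in seq_len(nrow(combos))) {
      site <- as.character(combos$site_id[i])
      ex <- combos$examiner[i]; rd <- combos$round[i]
      pc <- manual_pts[[paste(site, ex, rd, "CEJ")]]
      pg <- manual_pts[[paste(site, ex, rd, "GM")]]
      if (is.null(pc) || is.null(pg)) next
      meas[[length(meas) + 1L]] <- data.frame(
        site_id = site, method = paste0("examiner-", ex),
        round = as.integer(rd),
        cej_s = NA_real_, gm_s = NA_real_,
        cej_y = pc[1], cej_z = pc[2], gm_y = pg[1], gm_z = pg[2],
        depth_mm = recession_depth(pc, pg), status = "ok")
    }
  }
  list(measurements = do.call(rbind, meas),
       deviations = if (length(devs)) do.call(rbind, devs) else
         data.frame(site_id = character(), examiner = character(),
                    round = integer(), landmark = character(),
                    deviation_mm = numeric(),
                    reference_kappa_per_mm = numeric(),
                    snapped = logical(), status = character()),
       reports = reports)
}

normalise_sections <- function(sections) {
  if (inherits(sections, "curvature_profile")) sections <- list(sections)
  if (is.null(names(sections)) || any(names(sections) == "")) {
    ids <- vapply(seq_along(sections), function(i) {
      el <- sections[[i]]
      if (is.list(el) && !is.null(el$site_id)) as.character(el$site_id)
      else sprintf("site%03d", i)
    }, "")
    names(sections) <- ids
  }
  lapply(sections, function(el) {
    if (inherits(el, "curvature_profile")) el
    else if (is.list(el) && inherits(el$profile, "curvature_profile"))
      el$profile
    else stop("sections must contain curvature_profile objects")
  })
}
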