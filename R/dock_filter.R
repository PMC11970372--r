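#' Read docked pose coordinates and scores from TSV
#'
#' Expects a header row and columns `pose`, `score` (kcal/mol) and two
#' Cartesian triples in Angstrom: `rx, ry, rz` (substrate reactive atom)
#' and `fx, fy, fz` (the iron of the iron-oxo centre). Such a table is
#' exported from standard pose files (PDBQT or SDF) by taking, per pose,
#' the docking score and the coordinates of the chosen reactive atom and of
#' the haem iron.
#'
#' @param path Path to the TSV file.
#' @return A tibble of poses.
#' @export
read_poses_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("poses TSV not found: ", path))
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("pose", "score", "rx", "ry", "rz", "fx", "fy", "fz")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("poses TSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  num <- df[, setdiff(need, "pose")]
  if (any(!vapply(num, is.numeric, TRUE)) || any(!is.finite(as.matrix(num)))) {
    abort("non-finite value in poses TSV")
  }
  as_tibble(df[, need])
}

#' Distance from the substrate reactive atom to the iron-oxo centre
#'
#' Euclidean distance in Angstrom between the two coordinate triples of
#' each pose. Which substrate atom is "reactive" (a specific carbon or a
#' centroid) is the caller's choice when the pose table is built.
#'
#' @param poses Pose tibble as from [read_poses_tsv()].
#' @return The tibble with a `dist` column (Angstrom) appended.
#' @export
pose_distance <- function(poses) {
  m <- as.matrix(poses[, c("rx", "ry", "rz", "fx", "fy", "fz")])
  if (any(!is.finite(m))) abort("non-finite pose coordinates")
  poses$dist <- sqrt((poses$rx - poses$fx)^2 + (poses$ry - poses$fy)^2 +
                       (poses$rz - poses$fz)^2)
  poses
}

#' Filter docked poses by catalytic distance and score
#'
#' Keeps reasonable conformations: reactive-atom-to-iron distance within
#' `max_dist` (inclusive) and, by default, a negative docking score. The
#' result is sorted by distance, then score — deterministic and idempotent.
#'
#' @param poses Pose tibble; `dist` is computed via [pose_distance()] if
#'   absent.
#' @param max_dist Maximum catalytic distance (Angstrom, inclusive).
#' @param require_negative_score Drop poses with score >= 0.
#' @return The retained poses, sorted by `dist` then `score`.
#' @export
filter_poses <- function(poses, max_dist = 5.0,
                         require_negative_score = TRUE) {
  if (nrow(poses) == 0) abort("empty pose set")
  if (!"dist" %in% names(poses)) poses <- pose_distance(poses)
  kept <- poses[poses$dist <= max_dist, , drop = FALSE]
  if (require_negative_score) kept <- kept[kept$score < 0, , drop = FALSE]
  arrange(kept, .data$dist, .data$score, .data$pose)
}
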