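# Unit-based assessment: Jaccard index on per-action unit sets, duration
# error, existence accuracy, frame/unit-level accuracy, and precision/recall
# for the binary dry-hands detector.

#' Jaccard index (IoU) between ground-truth and predicted unit sets
#'
#' For one action, J = |intersection| / |union| of the sets of 30-frame unit
#' indices labelled with that action. When both sets are empty the action is
#' absent and not predicted, which is a perfect outcome: J = 1 by convention.
#'
#' @param gt_units,pred_units integer vectors of unit indices (treated as
#'   sets).
#' @return numeric in \[0, 1\].
#' @export
jaccard_index <- function(gt_units, pred_units) {
  g <- unique(gt_units); p <- unique(pred_units)
  if (length(g) == 0 && length(p) == 0) return(1)
  length(intersect(g, p)) / length(union(g, p))
}

#' Absolute duration error in seconds
#'
#' Units are 1 s long, so the duration of an action is its unit count. The
#' error is the absolute difference between predicted and ground-truth unit
#' counts; it is symmetric in its arguments.
#'
#' @inheritParams jaccard_index
#' @return non-negative seconds.
#' @export
duration_error <- function(gt_units, pred_units) {
  abs(length(unique(gt_units)) - length(unique(pred_units)))
}

#' Existence accuracy across videos
#'
#' Fraction of videos for which the predicted presence/absence flag for an
#' action matches ground truth.
#'
#' @param pred_flags,gt_flags logical vectors of equal, positive length.
#' @return fraction in \[0, 1\].
#' @export
existence_accuracy <- function(pred_flags, gt_flags) {
  if (length(pred_flags) == 0) stop("empty flag vectors")
  if (length(pred_flags) != length(gt_flags)) {
    stop("flag vectors differ in length: ", length(pred_flags), " vs ",
         length(gt_flags))
  }
  mean(pred_flags == gt_flags)
}

#' Frame- or unit-level accuracy of a label track
#'
#' @param pred_track,gt_track aligned label vectors (per frame or per unit).
#' @param level `"frame"` or `"unit"`; informational, both compute
#'   matches/total at the given granularity.
#' @return fraction in \[0, 1\].
#' @export
level_accuracy <- function(pred_track, gt_track,
                           level = c("frame", "unit")) {
  level <- match.arg(level)
  if (length(pred_track) != length(gt_track)) {
    stop(level, "-level tracks differ in length: ", length(pred_track),
         " vs ", length(gt_track))
  }
  if (length(pred_track) == 0) stop("empty tracks")
  mean(pred_track == gt_track)
}

#' Precision, recall and accuracy for the binary dry-hands task
#'
#' Dry-hands frames are the positive class and non-hygiene frames the
#' negative class. If no positive is predicted, precision is undefined and
#' reported as `NA` with a warning (never silently 0).
#'
#' @param pred_frames,gt_frames logical vectors (`TRUE` = dry hands).
#' @return list with `precision`, `recall`, `accuracy`.
#' @export
dry_hands_pr <- function(pred_frames, gt_frames) {
  stopifnot(length(pred_frames) == length(gt_frames))
  tp <- sum(pred_frames & gt_frames)
  fp <- sum(pred_frames & !gt_frames)
  fn <- sum(!pred_frames & gt_frames)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions; precision undefined")
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  list(precision = precision, recall = recall,
       accuracy = mean(pred_frames == gt_frames))
}

#' Evaluate a predicted unit track against ground truth
#'
#' Computes, per action: the unit set Jaccard index, duration error, and
#' presence flags; plus overall unit accuracy. This is the per-video summary
#' used to assemble duration-type (rubbing) and existence-type
#' (soap, dry hands, faucet) assessments.
#'
#' @param pred_track,gt_track data.frames with `unit` and `label` over the
#'   same units.
#' @param vocab action vocabulary.
#' @return list with `per_action` data.frame (action, jaccard,
#'   duration_error_s, gt_present, pred_present) and `unit_accuracy`.
#' @export
evaluate_unit_track <- function(pred_track, gt_track, vocab = standard7) {
  if (!identical(pred_track$unit, gt_track$unit)) {
    stop("tracks are not aligned on the same units")
  }
  per <- do.call(rbind, lapply(vocab, function(a) {
    g <- gt_track$unit[gt_track$label == a]
    p <- pred_track$unit[pred_track$label == a]
    data.frame(action = a,
               jaccard = jaccard_index(g, p),
               duration_error_s = duration_error(g, p),
               gt_present = length(g) > 0,
               pred_present = length(p) > 0)
  }))
  list(per_action = per,
       unit_accuracy = level_accuracy(pred_track$label, gt_track$label,
                                      "unit"))
}
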