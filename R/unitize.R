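# Unit representation: non-overlapping runs of 30 consecutive frames (1 s at
# 30 FPS), the system's atomic prediction and evaluation granularity.

#' Partition a frame count into non-overlapping 30-frame units
#'
#' Units are half-open frame spans `[unit_len * i, unit_len * (i + 1))` with
#' 0-based unit indices. Trailing frames that do not fill a whole unit are
#' discarded (with a message), since the unit is the smallest span for which
#' a prediction is defined.
#'
#' @param n_frames non-negative integer number of frames.
#' @param unit_len frames per unit (default 30, i.e. 1 s at 30 FPS).
#' @return data.frame with columns `unit` (0-based index), `first_frame`,
#'   `last_frame` (0-based, inclusive).
#' @export
partition_units <- function(n_frames, unit_len = 30L) {
  stopifnot(length(n_frames) == 1, n_frames >= 0, unit_len >= 1)
  n_units <- n_frames %/% unit_len
  rem <- n_frames %% unit_len
  if (rem > 0) {
    message(rem, " trailing frame(s) do not fill a unit and are discarded")
  }
  if (n_units == 0) {
    if (n_frames > 0) warning("fewer frames (", n_frames,
                              ") than one unit; 0 units produced")
    return(data.frame(unit = integer(0), first_frame = integer(0),
                      last_frame = integer(0)))
  }
  u <- seq_len(n_units) - 1L
  data.frame(unit = u, first_frame = u * unit_len,
             last_frame = u * unit_len + unit_len - 1L)
}

#' Majority label of one unit
#'
#' The unit label is the most frequent frame label among the unit's frames.
#' Ties break to the label that appears earlier in `vocab` (canonical order).
#'
#' @param frame_labels character vector of exactly `unit_len` labels.
#' @param vocab label vocabulary in canonical (tie-break) order.
#' @param unit_len expected number of labels.
#' @return single label.
#' @export
majority_unit_label <- function(frame_labels, vocab = standard7,
                                unit_len = 30L) {
  if (length(frame_labels) != unit_len) {
    stop("expected ", unit_len, " frame labels, got ", length(frame_labels))
  }
  check_actions(frame_labels, vocab)
  counts <- table(factor(frame_labels, levels = vocab))
  vocab[which.max(counts)]  # which.max takes the first maximum: tie-break
}

#' Average per-frame confidences into one unit prediction
#'
#' The unit confidence vector is the arithmetic mean of the frame probability
#' vectors; the unit label is its argmax, ties breaking to the earlier vocab
#' entry.
#'
#' @param frame_probs matrix with one row per frame and one column per label
#'   (columns named by, and ordered as, `vocab`); each row sums to 1.
#' @param vocab label vocabulary in canonical order.
#' @return list with `label` and `conf` (named mean probability vector).
#' @export
aggregate_unit_confidence <- function(frame_probs, vocab = standard7) {
  frame_probs <- as.matrix(frame_probs)
  if (ncol(frame_probs) != length(vocab)) {
    stop("probability vectors have length ", ncol(frame_probs),
         " but vocabulary has ", length(vocab))
  }
  conf <- colMeans(frame_probs)
  names(conf) <- vocab
  list(label = vocab[which.max(conf)], conf = conf)
}

#' Convert a per-frame label track to a per-unit label track
#'
#' @param frame_labels per-frame labels for a whole video.
#' @inheritParams majority_unit_label
#' @return data.frame with columns `unit` and `label`.
#' @export
unitize_labels <- function(frame_labels, vocab = standard7, unit_len = 30L) {
  parts <- suppressMessages(partition_units(length(frame_labels), unit_len))
  lab <- vapply(seq_len(nrow(parts)), function(i) {
    majority_unit_label(
      frame_labels[(parts$first_frame[i] + 1L):(parts$last_frame[i] + 1L)],
      vocab = vocab, unit_len = unit_len)
  }, character(1))
  data.frame(unit = parts$unit, label = if (length(lab)) lab else character(0))
}

#' Write / read a unit label track as CSV
#'
#' Columns: `unit_index`, `label`, then optional `conf_<label>` columns.
#' @param track data.frame with `unit` and `label`, optionally a `conf`
#'   matrix attribute or conf_ columns.
#' @param path CSV file path.
#' @export
write_unit_track <- function(track, path) {
  df <- data.frame(unit_index = track$unit, label = track$label)
  conf <- attr(track, "conf")
  if (!is.null(conf)) {
    colnames(conf) <- paste0("conf_", colnames(conf))
    df <- cbind(df, as.data.frame(conf))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_unit_track
#' @export
read_unit_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(unit = df$unit_index, label = df$label)
  cc <- grep("^conf_", names(df), value = TRUE)
  if (length(cc)) {
    conf <- as.matrix(df[cc])
    colnames(conf) <- sub("^conf_", "", cc)
    attr(out, "conf") <- conf
  }
  out
}
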