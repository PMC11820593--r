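#' Slicing configuration
#'
#' @param window_s Window length in seconds. Default 5.
#' @param overlap_fraction Overlap between neighboring windows, in
#'   `[0, 1)`. Default 0.5 (stride of half a window).
#' @param fs Sampling rate in Hz. Default 360 (so the default window is
#'   1800 points).
#' @return Object of class `slice_config`.
#' @export
slice_config <- function(window_s = 5, overlap_fraction = 0.5, fs = 360) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  w <- window_s * fs
  if (abs(w - round(w)) > 1e-9) stop("window_s * fs must be an integer")
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 fs = fs, window = as.integer(round(w))),
            class = "slice_config")
}

#' Cut a record into overlapping fixed-length windows
#'
#' Windows start every `window * (1 - overlap_fraction)` samples (0-based
#' starts); each window covers the half-open sample interval
#' `[start, start + window)` and collects the AAMI labels of every beat
#' annotation falling inside it, in order of occurrence. A trailing
#' partial window is dropped.
#'
#' @param record An [ecg_record()] (annotation symbols are mapped through
#'   [map_symbol_to_aami()] unless already AAMI labels).
#' @param cfg A [slice_config()].
#' @param lead Lead index to slice. Default 1.
#' @return List of windows; each has `samples` (length-`window` numeric),
#'   `beat_labels` (character, first-occurrence order), `start` (0-based)
#'   and `source`.
#' @export
slice_record <- function(record, cfg = slice_config(), lead = 1L) {
  stopifnot(inherits(record, "ecg_record"), inherits(cfg, "slice_config"))
  n <- nrow(record$signal)
  w <- cfg$window
  if (n < w) stop("record shorter than one window (", w, " samples)")
  stride <- as.integer(round(w * (1 - cfg$overlap_fraction)))
  if (stride < 1L) stride <- 1L
  starts <- seq.int(0L, n - w, by = stride)
  x <- record$signal[, lead]
  ann <- record$annotations
  lab <- if (nrow(ann)) {
    if (all(ann$symbol %in% aami_levels())) ann$symbol
    else map_symbol_to_aami(ann$symbol)
  } else character(0)
  lapply(starts, function(s) {
    inside <- which(ann$sample >= s & ann$sample < s + w)
    list(samples = x[(s + 1L):(s + w)],
         beat_labels = lab[inside],
         start = s,
         source = "record")
  })
}

#' Assign one AAMI label to a slice from its beat labels
#'
#' The four slice-typing rules, applied to the beats contained in the
#' window (in first-occurrence order):
#' 1. all beats normal -> `N`;
#' 2. exactly one abnormal type present -> that type;
#' 3. several abnormal types -> the most frequent abnormal type;
#' 4. tie in counts -> the abnormal type occurring first.
#'
#' The labeling therefore never needs R-peak/QRS detection.
#'
#' @param beat_labels Character vector of AAMI labels in occurrence order;
#'   must be nonempty.
#' @return A single AAMI label.
#' @export
#' @examples
#' label_slice(c("N", "N", "V"))       # rule 2 -> "V"
#' label_slice(c("N", "S", "S", "V"))  # rule 3 -> "S"
label_slice <- function(beat_labels) {
  if (!length(beat_labels)) stop("no beats in slice")
  stopifnot(all(beat_labels %in% aami_levels()))
  abn <- beat_labels[beat_labels != "N"]
  if (!length(abn)) return("N")
  types <- unique(abn)                       # first-occurrence order
  if (length(types) == 1L) return(types)
  counts <- vapply(types, function(t) sum(abn == t), 0L)
  types[which.max(counts)]                   # ties resolve to the earliest
}

#' Slice and label every window of a record
#'
#' Convenience wrapper: [slice_record()] then [label_slice()], dropping
#' windows that contain no beat.
#'
#' @inheritParams slice_record
#' @return A `segment_set`: list with `segments` (matrix, one row per
#'   window) and `labels` (factor over the AAMI levels).
#' @export
make_segments <- function(record, cfg = slice_config(), lead = 1L) {
  sl <- slice_record(record, cfg, lead)
  keep <- vapply(sl, function(s) length(s$beat_labels) > 0L, TRUE)
  sl <- sl[keep]
  if (!length(sl)) stop("no window contains a beat")
  segment_set(
    segments = do.call(rbind, lapply(sl, `[[`, "samples")),
    labels = vapply(sl, function(s) label_slice(s$beat_labels), ""),
    starts = vapply(sl, `[[`, 0L, "start"))
}

#' Labeled segment container
#'
#' @param segments Numeric matrix, one row per fixed-length slice.
#' @param labels AAMI labels, one per row.
#' @param starts Optional 0-based start indices.
#' @param synthetic Logical flag per row: `TRUE` for SMOTE-generated rows.
#' @return Object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, starts = NULL, synthetic = NULL) {
  segments <- as.matrix(segments)
  labels <- factor(as.character(labels), levels = aami_levels())
  stopifnot(nrow(segments) == length(labels), !anyNA(labels))
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(segments))
  structure(list(segments = segments, labels = labels,
                 starts = starts, synthetic = synthetic),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples\n",
              nrow(x$segments), ncol(x$segments)))
  print(table(x$labels))
  if (any(x$synthetic)) cat("  (", sum(x$synthetic), "SMOTE-synthetic )\n")
  invisible(x)
}

subset_segments <- function(ss, idx) {
  segment_set(ss$segments[idx, , drop = FALSE], ss$labels[idx],
              starts = if (!is.null(ss$starts)) ss$starts[idx],
              synthetic = ss$synthetic[idx])
}

# stratified index split: draw `frac` of each class for the second part
stratified_split <- function(labels, frac, seed) {
  with_seed(seed, {
    hold <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (!length(idx)) next
      if (length(idx) < 2) stop("class ", cl, " has < 2 members; cannot stratify")
      k <- round(frac * length(idx))
      hold <- c(hold, sample(idx, k))
    }
    sort(hold)
  })
}

#' Split segments into train / validation / test with SMOTE balancing
#'
#' `test_fraction` of the data (stratified by label) is held out *before*
#' any balancing, so no held-out segment ever participates in the SMOTE
#' neighbor search. The remainder is balanced with [smote_oversample()],
#' then split `val_fraction` / `1 - val_fraction` into validation and
#' training; a fractional sample rounds toward the validation set
#' (`ceiling`), matching the convention that 30% of 47,015 is 14,105.
#'
#' @param segset A [segment_set()].
#' @param test_fraction Held-out fraction. Default 0.2.
#' @param val_fraction Validation fraction of the balanced remainder.
#'   Default 0.3.
#' @param seed Integer seed.
#' @param smote_cfg A [smote_config()], or `NULL` to skip balancing.
#' @return List with `train`, `val`, `test` (each a `segment_set`).
#' @export
partition_segments <- function(segset, test_fraction = 0.2,
                               val_fraction = 0.3, seed = 1L,
                               smote_cfg = smote_config(seed = seed)) {
  stopifnot(inherits(segset, "segment_set"))
  if (!nrow(segset$segments)) stop("no segments to partition")
  present <- droplevels(segset$labels)
  test_idx <- stratified_split(present, test_fraction,
                               derive_seed(seed, "partition-test"))
  test <- subset_segments(segset, test_idx)
  rest <- subset_segments(segset, setdiff(seq_along(segset$labels), test_idx))
  balanced <- if (is.null(smote_cfg)) rest else smote_oversample(rest, smote_cfg)
  n <- nrow(balanced$segments)
  n_val <- ceiling(val_fraction * n)
  val_idx <- with_seed(derive_seed(seed, "partition-val"),
                       sort(sample(n, n_val)))
  list(train = subset_segments(balanced, setdiff(seq_len(n), val_idx)),
       val = subset_segments(balanced, val_idx),
       test = test)
}
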