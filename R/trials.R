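#' Construct and validate a foraging trial log
#'
#' A trial log is a long-format `data.frame` with one row per screen tap, in
#' collection order: columns `participant`, `age`, `condition` (`"feature"`
#' or `"conjunction"`), `set_size`, `trial`, `order` (1-based rank within the
#' trial), pick-time coordinates `x`, `y` (pixels, origin top-left), and
#' optionally `t` (seconds since trial start), `item_class`, and `is_target`.
#' Because the task is non-exhaustive — the observer may abandon a patch at
#' will — trials have varying numbers of picks.
#'
#' Distractor taps (`is_target = FALSE`) are retained in the log but are
#' excluded from all organization scoring and from the choice-model
#' likelihood, which are defined over collected targets only.
#'
#' @param df data.frame with the columns above (missing `t`, `item_class`,
#'   `is_target` are filled with `NA`/`TRUE`).
#' @param bounds optional `c(width, height)` in pixels; when supplied,
#'   coordinates are checked against `[0, width] x [0, height]`.
#' @return The validated data.frame with class `"forage_trials"`.
#' @export
forage_trials <- function(df, bounds = NULL) {
  required <- c("participant", "age", "condition", "set_size",
                "trial", "order", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("trial log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"t" %in% names(df)) df$t <- NA_real_
  if (!"item_class" %in% names(df)) df$item_class <- NA_character_
  if (!"is_target" %in% names(df)) df$is_target <- TRUE
  for (col in c("age", "set_size", "order", "x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at row(s) %s",
                     col, paste(utils::head(bad, 5), collapse = ", ")))
      df[[col]] <- vn
    }
  }
  df$is_target <- as.logical(df$is_target)
  bad_cond <- !df$condition %in% c("feature", "conjunction")
  if (any(bad_cond))
    stop("condition must be 'feature' or 'conjunction' (first bad row: ",
         which(bad_cond)[1], ")")
  if (any(df$age <= 0)) stop("age must be positive")
  if (!is.null(bounds)) {
    out <- df$x < 0 | df$x > bounds[1] | df$y < 0 | df$y > bounds[2]
    if (any(out))
      stop("coordinates outside declared display bounds at row(s) ",
           paste(utils::head(which(out), 5), collapse = ", "))
  }
  key <- trial_key(df)
  df <- df[order(key, df$order), , drop = FALSE]
  rownames(df) <- NULL
  key <- trial_key(df)
  for (k in unique(key)) {
    ord <- df$order[key == k]
    if (anyDuplicated(ord))
      stop("duplicate (trial, order) pair in trial ", k,
           " at order ", ord[duplicated(ord)][1])
    expected <- seq_along(ord)
    if (!identical(as.integer(ord), expected)) {
      miss <- which(as.integer(ord) != expected)[1]
      stop("order values in trial ", k,
           " are not consecutive from 1: expected ", expected[miss],
           ", found ", ord[miss])
    }
  }
  class(df) <- c("forage_trials", "data.frame")
  df
}

trial_key <- function(df) {
  paste(df$participant, df$condition, df$trial, sep = "\r")
}

#' Read a trial-log CSV
#'
#' Reads a comma-separated, UTF-8, header-row trial log and validates it via
#' [forage_trials()].  `schema` renames nonstandard column headers, e.g.
#' `c(participant = "subj_id")` declares that the file's `subj_id` column
#' holds the participant identifier.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical names to the
#'   file's column names (only for columns that differ).
#' @param bounds optional display bounds passed to [forage_trials()].
#' @return A `forage_trials` data.frame, picks sorted by trial and order.
#' @export
read_trials <- function(path, schema = NULL, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  forage_trials(df, bounds = bounds)
}

#' Write a trial-log CSV
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, f))` reproduces
#' `x` field for field.  An empty log writes a header-only file.
#'
#' @param trials a `forage_trials` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant", "age", "condition", "set_size", "trial",
            "order", "x", "y", "t", "item_class", "is_target")
  df <- as.data.frame(trials)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a trial log into per-trial pick data frames
#'
#' @param trials a `forage_trials` data.frame.
#' @param targets_only drop distractor taps (the default; organization
#'   metrics and the choice model are defined over collected targets).
#' @return Named list of per-trial data.frames, ordered by pick order.
#' @export
split_trials <- function(trials, targets_only = TRUE) {
  df <- as.data.frame(trials)
  if (targets_only) df <- df[df$is_target %in% TRUE, , drop = FALSE]
  out <- split(df, trial_key(df))
  lapply(out, function(d) d[order(d$order), , drop = FALSE])
}

#' Score every trial in a log on the four organization indicators
#'
#' Computes [score_sequence()] per trial, either on the whole pick sequence
#' (`bins = 1`) or separately on its two halves (`bins = 2`, see
#' [split_bins()]).  Distractor taps are excluded before scoring.
#'
#' @param trials a `forage_trials` data.frame.
#' @param bins `1` for whole-trial scores, `2` for first/second-half scores.
#' @param min_picks_per_bin with `bins = 2`, trials whose halves fall below
#'   this many picks are excluded (reason `"bin_too_small"`).
#' @param exact_max exact-solver threshold for [pao()].
#' @return data.frame with one row per trial (x bin): participant, age,
#'   condition, set_size, trial, and the [score_sequence()] columns.
#' @export
score_trials <- function(trials, bins = 1L, min_picks_per_bin = 4L,
                         exact_max = 10L) {
  per <- split_trials(trials)
  rows <- lapply(per, function(d) {
    meta <- d[1, c("participant", "age", "condition", "set_size", "trial")]
    if (bins == 1L) {
      sc <- score_sequence(d$x, d$y, "whole", exact_max = exact_max)
      return(cbind(meta, sc, row.names = NULL))
    }
    sb <- split_bins(nrow(d), min_picks = min_picks_per_bin)
    if (!is.null(sb$reason)) {
      sc <- data.frame(bin = "excluded", n_picks = nrow(d),
                       best_r = NA_real_, mean_itd = NA_real_,
                       pao = NA_real_, intersection_rate = NA_real_,
                       reasons = sb$reason, stringsAsFactors = FALSE)
      return(cbind(meta, sc, row.names = NULL))
    }
    rbind(
      cbind(meta, score_sequence(d$x[sb$bin1], d$y[sb$bin1], "bin1",
                                 exact_max = exact_max), row.names = NULL),
      cbind(meta, score_sequence(d$x[sb$bin2], d$y[sb$bin2], "bin2",
                                 exact_max = exact_max), row.names = NULL))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
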