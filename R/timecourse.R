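#' Split a pick sequence into two time bins
#'
#' To study how organization evolves within a patch, each trial's target
#' picks are divided into two halves: the first half of the targets
#' collected (bin 1) and the second half (bin 2).  Odd-length trials give
#' the extra pick to bin 1, so `|bin1| - |bin2|` is 0 or 1.  The distance
#' between the last bin-1 pick and the first bin-2 pick belongs to neither
#' bin: each bin is scored as a self-contained sequence.
#'
#' @param n number of target picks in the trial.
#' @param min_picks minimum picks a bin must hold for the trial to stay in
#'   the binned analysis (default 4, the smallest count at which all four
#'   indicators are computable).
#' @return List with integer index vectors `bin1`, `bin2`, and `reason`
#'   (`NULL` when the trial is usable, otherwise `"too_few_picks"` or
#'   `"bin_too_small"`).
#' @examples
#' split_bins(7)  # bin1 = 1:4, bin2 = 5:7
#' @export
split_bins <- function(n, min_picks = 4L) {
  if (n < 2L)
    return(list(bin1 = integer(0), bin2 = integer(0),
                reason = "too_few_picks"))
  h <- ceiling(n / 2)
  bin1 <- seq_len(h)
  bin2 <- seq.int(h + 1L, n)
  if (length(bin1) < min_picks || length(bin2) < min_picks)
    return(list(bin1 = bin1, bin2 = bin2, reason = "bin_too_small"))
  list(bin1 = bin1, bin2 = bin2, reason = NULL)
}

#' Build the long score table for mixed-model analysis
#'
#' Scores every trial in both time bins and assembles the long-format table
#' crossing participant x condition x set size x bin, with `log_age =
#' ln(age in years)` added as the age predictor (development of search
#' organization is closer to logarithmic than linear in age).  Trials whose
#' bins are too short are dropped from the table and reported in the
#' exclusion ledger.
#'
#' @param trials a `forage_trials` data.frame.
#' @param min_picks_per_bin passed to [split_bins()].
#' @param exact_max exact-solver threshold for [pao()].
#' @return List with `scores` (one row per trial x bin; columns participant,
#'   age, log_age, condition, set_size, trial, bin, n_picks, the four
#'   indicators, reasons) and `excluded` (trial-level ledger with reasons).
#' @export
build_score_table <- function(trials, min_picks_per_bin = 4L,
                              exact_max = 10L) {
  sc <- score_trials(trials, bins = 2L,
                     min_picks_per_bin = min_picks_per_bin,
                     exact_max = exact_max)
  excluded <- sc[sc$bin == "excluded",
                 c("participant", "condition", "trial", "n_picks", "reasons")]
  scores <- sc[sc$bin != "excluded", , drop = FALSE]
  scores$log_age <- log(scores$age)
  scores <- scores[, c("participant", "age", "log_age", "condition",
                       "set_size", "trial", "bin", "n_picks", "best_r",
                       "mean_itd", "pao", "intersection_rate", "reasons")]
  rownames(scores) <- NULL
  rownames(excluded) <- NULL
  list(scores = scores, excluded = excluded)
}
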