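#' Apply staged cohort exclusions
#'
#' Bookkeeping helper for cohort quality control: starting from the number of
#' available subjects, sequentially applies named exclusion counts (e.g. fat
#' water swaps, erroneous masks, corrupt raw data) and returns the count
#' remaining after each stage.
#'
#' @param nAvailable subjects available at baseline
#' @param exclusions named integer vector of exclusion counts, applied in order
#' @return data.frame with columns `stage`, `excluded`, `remaining`
#' @examples
#' applyExclusions(11026, c(fat_water_swap = 78, mask_error = 266,
#'                          corrupt_raw = 10))
#' @export
applyExclusions <- function(nAvailable, exclusions) {
  stopifnot(nAvailable >= 0, all(exclusions >= 0))
  remaining <- nAvailable - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) stopf("exclusions exceed available subjects")
  data.frame(stage = names(exclusions),
             excluded = as.integer(exclusions),
             remaining = as.integer(remaining),
             stringsAsFactors = FALSE)
}

#' Percentage of a subgroup within a cohort
#'
#' @param nGroup subgroup size
#' @param nTotal cohort size
#' @param digits decimals to round the percentage to (default 2)
#' @return percentage, rounded
#' @examples
#' sexSplitPercent(5484, 10672) # 51.39
#' @export
sexSplitPercent <- function(nGroup, nTotal, digits = 2) {
  stopifnot(nTotal > 0, nGroup >= 0, nGroup <= nTotal)
  round(100 * nGroup / nTotal, digits)
}
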