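# Parasitization performance indices.
#
# A 4-h exposure of one female wasp to 25 host larvae yields counts:
#   f  adult flies emerged,
#   e  emerged flies carrying >= 1 encapsulated wasp egg,
#   w  emerged flies without a capsule (f = e + w),
#   p  adult wasp offspring emerged.
# Same-day unexposed control vials give n_bar, the mean number of emerging
# flies per vial, which plays the role of the expected survivors in the
# absence of wasps. All indices are percentages of n_bar-scaled totals.

#' Summarize same-day control vials
#'
#' Computes the mean number of emerging flies per unexposed control vial for
#' each testing day, the baseline against which exposure assays are
#' standardized.
#'
#' @param vials data.frame with columns `day_id`, `n_larvae`, `n_emerged`
#'   (one row per control vial).
#' @param day optional day id; if given, only that day is summarized (error
#'   if it has no control vials).
#' @return data.frame with columns `day_id`, `n_bar`, `n_vials`.
#' @examples
#' v <- data.frame(day_id = "d1", n_larvae = 25, n_emerged = c(20, 22, 18))
#' summarizeDayControls(v)
#' @export
summarizeDayControls <- function(vials, day = NULL) {
  stopifnot(is.data.frame(vials),
            all(c("day_id", "n_emerged") %in% names(vials)))
  if (!is.null(day)) {
    vials <- vials[vials$day_id %in% day, , drop = FALSE]
    if (nrow(vials) == 0L) {
      stop("no control vials for day '", day, "'", call. = FALSE)
    }
  }
  if (nrow(vials) == 0L) stop("no control vials", call. = FALSE)
  if (any(vials$n_emerged < 0)) stop("negative emergence count", call. = FALSE)
  agg <- aggregate(n_emerged ~ day_id, data = vials,
                   FUN = function(x) c(m = mean(x), n = length(x)))
  out <- data.frame(day_id = agg$day_id,
                    n_bar = agg$n_emerged[, "m"],
                    n_vials = as.integer(agg$n_emerged[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$day_id), , drop = FALSE]
}

checkNbar <- function(n_bar) {
  if (any(!is.finite(n_bar)) || any(n_bar <= 0)) {
    stop("degenerate control: mean control survival n_bar must be > 0",
         call. = FALSE)
  }
  n_bar
}

#' Attack rate
#'
#' Percentage of hosts parasitized: excess mortality relative to unexposed
#' controls plus survivors that carry an encapsulated egg,
#' 100 * (n_bar - w) / n_bar with w = f - e. Clamped to \[0, 100\] (negative
#' values arise by sampling when more flies emerge than in controls).
#'
#' @param f flies emerged in the exposure vial.
#' @param e emerged flies with at least one encapsulated egg.
#' @param n_bar mean emerging flies per same-day control vial (> 0).
#' @return percentage in \[0, 100\], vectorized over inputs.
#' @examples
#' attackRate(f = 10, e = 4, n_bar = 20) # 70
#' @export
attackRate <- function(f, e, n_bar) {
  checkNbar(n_bar)
  w <- f - e
  pmin(pmax(100 * (n_bar - w) / n_bar, 0), 100)
}

#' Killing rate
#'
#' Percentage of hosts killed in excess of control mortality,
#' 100 * (n_bar - f) / n_bar, floored at 0 when more flies emerge than in
#' the unexposed controls (f > n_bar).
#'
#' @inheritParams attackRate
#' @return percentage in \[0, 100\], vectorized.
#' @examples
#' killingRate(f = 10, n_bar = 20) # 50
#' killingRate(f = 22, n_bar = 18) # 0, negative excess mortality
#' @export
killingRate <- function(f, n_bar) {
  checkNbar(n_bar)
  pmax(100 * (n_bar - f) / n_bar, 0)
}

#' Lethal attack rate (killing efficiency)
#'
#' Killed hosts as a percentage of attacked hosts,
#' 100 * (n_bar - f) / (n_bar - w). Undefined (`NA`) when no host was
#' attacked (n_bar - w <= 0); clamped to \[0, 100\] otherwise.
#'
#' @inheritParams attackRate
#' @return percentage in \[0, 100\] or `NA`, vectorized.
#' @examples
#' lethalAttackRate(f = 10, e = 4, n_bar = 20) # 100 * 10 / 14
#' @export
lethalAttackRate <- function(f, e, n_bar) {
  checkNbar(n_bar)
  w <- f - e
  attacked <- n_bar - w
  out <- ifelse(attacked > 0,
                pmin(pmax(100 * (n_bar - f) / attacked, 0), 100),
                NA_real_)
  out
}

#' Successful parasitism
#'
#' Killed hosts that yielded an adult wasp, as a percentage of killed hosts:
#' 100 * p / (n_bar - f). Undefined (`NA`) when no host was killed
#' (n_bar - f <= 0); clamped to \[0, 100\].
#'
#' @param p wasp offspring emerged.
#' @inheritParams attackRate
#' @return percentage in \[0, 100\] or `NA`, vectorized.
#' @examples
#' successfulParasitism(p = 1, f = 10, n_bar = 20) # 10
#' @export
successfulParasitism <- function(p, f, n_bar) {
  checkNbar(n_bar)
  killed <- n_bar - f
  ifelse(killed > 0, pmin(pmax(100 * p / killed, 0), 100), NA_real_)
}

#' Quality-control filter on testing-day blocks
#'
#' Excludes testing days whose mean control survival falls below
#' `ratio_threshold` times the median over all days ("about half" of the
#' remaining blocks indicates a low-quality host batch, which makes
#' performance estimates for that day unreliable). The median is computed
#' once over the input blocks; the rule is a single pass.
#'
#' @param summaries data.frame as returned by [summarizeDayControls()].
#' @param ratio_threshold fraction of the median below which a block is
#'   dropped (default 0.6).
#' @return list with `retained` and `excluded` (both data.frames in input
#'   row order) and `cutoff`, the absolute n_bar threshold used.
#' @examples
#' s <- data.frame(day_id = paste0("b", 1:5),
#'                 n_bar = c(10.8, 21.1, 20.0, 22.0, 20.0), n_vials = 10)
#' qcFilterBlocks(s)$retained$day_id # four blocks survive
#' @export
qcFilterBlocks <- function(summaries, ratio_threshold = 0.6) {
  stopifnot(is.data.frame(summaries), "n_bar" %in% names(summaries))
  if (nrow(summaries) < 2L) stop("need at least two blocks", call. = FALSE)
  cutoff <- ratio_threshold * median(summaries$n_bar)
  keep <- summaries$n_bar >= cutoff
  if (!any(keep)) stop("all blocks excluded by quality control", call. = FALSE)
  list(retained = summaries[keep, , drop = FALSE],
       excluded = summaries[!keep, , drop = FALSE],
       cutoff = cutoff)
}

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Success/failure count pairs for model fitting
#'
#' Converts one exposure assay into the integer (successes, failures) pair
#' that a binomial threshold model consumes, using the day's control mean
#' n_bar (rounded half away from zero) as the trial total. Totals and
#' successes are floored at zero; for the conditional indices
#' (`"lethal_attack"`, `"successful_parasitism"`) the pair is undefined
#' (`NA`) when the conditioning count is zero or negative.
#'
#' @param f,e,p counts as in [attackRate()] / [successfulParasitism()].
#' @param n_bar same-day control mean.
#' @param index one of `"killing"`, `"attack"`, `"lethal_attack"`,
#'   `"successful_parasitism"`.
#' @return data.frame with integer columns `successes`, `failures` and
#'   logical `defined`, vectorized over inputs.
#' @examples
#' standardizedCounts(f = 10, e = 4, p = 0, n_bar = 20.4, index = "killing")
#' @export
standardizedCounts <- function(f, e = 0, p = 0, n_bar,
                               index = c("killing", "attack", "lethal_attack",
                                         "successful_parasitism")) {
  index <- match.arg(index)
  checkNbar(n_bar)
  k <- max(length(f), length(e), length(p), length(n_bar))
  f <- rep_len(f, k); e <- rep_len(e, k); p <- rep_len(p, k)
  n_bar <- rep_len(n_bar, k)
  total <- roundHalfAway(n_bar)
  w <- f - e
  if (index == "killing") {
    succ <- pmax(total - pmin(f, total), 0)
    fail <- total - succ
    def <- rep(TRUE, k)
  } else if (index == "attack") {
    succ <- pmin(pmax(total - w, 0), total)
    fail <- total - succ
    def <- rep(TRUE, k)
  } else if (index == "lethal_attack") {
    attacked <- pmin(pmax(total - w, 0), total)
    succ <- pmin(pmax(total - f, 0), attacked)
    fail <- attacked - succ
    def <- attacked > 0
  } else {
    killed <- pmax(total - f, 0)
    succ <- pmin(p, killed)
    fail <- killed - succ
    def <- killed > 0
  }
  succ[!def] <- NA_integer_; fail[!def] <- NA_integer_
  data.frame(successes = as.integer(succ), failures = as.integer(fail),
             defined = def)
}

#' Per-female performance table
#'
#' The module's main entry point: joins exposure trials with their same-day
#' control summaries, optionally applies the block quality-control filter,
#' and returns one row per female with the four indices plus defined/clamped
#' flags.
#'
#' @param trials data.frame with columns `female_id`, `day_id`, `line_id`,
#'   `generation`, `n_larvae`, `flies_emerged`, `flies_encapsulated`,
#'   `wasp_offspring` (see [readTrialsTable()]).
#' @param controls data.frame of control vials (see [readControlsTable()]).
#' @param qc apply [qcFilterBlocks()] to the testing days (default TRUE).
#' @param qc_threshold ratio threshold passed on to the filter.
#' @return data.frame of indices with attributes `controls` (the retained
#'   day summaries) and `excluded_days`.
#' @export
performanceTable <- function(trials, controls, qc = TRUE, qc_threshold = 0.6) {
  ctl <- summarizeDayControls(controls)
  excluded <- ctl[0, , drop = FALSE]
  if (qc && nrow(ctl) >= 2L) {
    flt <- qcFilterBlocks(ctl, qc_threshold)
    ctl <- flt$retained
    excluded <- flt$excluded
  }
  keep <- trials$day_id %in% ctl$day_id
  tr <- trials[keep, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials left after quality control", call. = FALSE)
  nb <- ctl$n_bar[match(tr$day_id, ctl$day_id)]
  f <- tr$flies_emerged; e <- tr$flies_encapsulated; p <- tr$wasp_offspring
  w <- f - e
  out <- data.frame(
    female_id = tr$female_id, day_id = tr$day_id, line_id = tr$line_id,
    generation = tr$generation, n_bar = nb,
    attack_rate = attackRate(f, e, nb),
    killing_rate = killingRate(f, nb),
    lethal_attack_rate = lethalAttackRate(f, e, nb),
    successful_parasitism = successfulParasitism(p, f, nb),
    attack_clamped = (100 * (nb - w) / nb) < 0 | (100 * (nb - w) / nb) > 100,
    killing_clamped = f > nb,
    lethal_defined = (nb - w) > 0,
    parasitism_defined = (nb - f) > 0,
    stringsAsFactors = FALSE)
  attr(out, "controls") <- ctl
  attr(out, "excluded_days") <- excluded
  out
}
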