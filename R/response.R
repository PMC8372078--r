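# Selection-response statistics: per-generation selection differentials and
# responses, realized heritability as the through-origin regression of
# cumulative response on cumulative selection differential, truncation
# selection intensity and breeder's-equation projections.

#' Per-generation selection differentials and responses
#'
#' For each line and generation interval t -> t+1: the selection
#' differential S = mean of the selected parents minus the mean of the full
#' parental cohort, and the response R = offspring-cohort mean minus the
#' full parental mean, plus their prefix sums in generation order. Trait
#' values are the day-standardized killing percentages.
#'
#' @param means either a [SelectionTrajectory-class] or a data.frame with
#'   columns `line`, `generation`, `mean_all`, `mean_selected` and
#'   optionally `mean_offspring` (if absent, the next generation's
#'   `mean_all` is the offspring mean).
#' @param lines optional subset of line ids (defaults: for a trajectory,
#'   the selected lines only).
#' @return data.frame with columns `line`, `generation` (parental), `S`,
#'   `R`, `S_cum`, `R_cum`.
#' @export
responsePoints <- function(means, lines = NULL) {
  if (is(means, "SelectionTrajectory")) {
    s <- trajectorySummary(means)
    if (is.null(lines)) lines <- unique(s$line[!s$control])
    means <- s
  }
  stopifnot(is.data.frame(means),
            all(c("line", "generation", "mean_all", "mean_selected")
                %in% names(means)))
  if (!is.null(lines)) means <- means[means$line %in% lines, , drop = FALSE]
  out <- lapply(split(means, means$line), function(m) {
    m <- m[order(m$generation), , drop = FALSE]
    if (nrow(m) < 2L && !("mean_offspring" %in% names(m))) {
      stop("need at least two generations per line", call. = FALSE)
    }
    if (any(diff(m$generation) != 1L)) {
      stop("missing generation in line ", m$line[1], call. = FALSE)
    }
    if ("mean_offspring" %in% names(m)) {
      par <- m
      off <- m$mean_offspring
    } else {
      par <- m[-nrow(m), , drop = FALSE]
      off <- m$mean_all[-1L]
    }
    S <- par$mean_selected - par$mean_all
    R <- off - par$mean_all
    data.frame(line = par$line, generation = par$generation,
               S = S, R = R, S_cum = cumsum(S), R_cum = cumsum(R))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Realized heritability (through-origin regression)
#'
#' Slope of the no-intercept least-squares regression of cumulative
#' response on cumulative selection differential,
#' slope = sum(S_cum R_cum) / sum(S_cum^2), with its standard error,
#' F(1, n-1) statistic, adjusted R-squared and p-value. Points from several
#' lines may be pooled: they enter one regression (the "average" estimate).
#'
#' @param points data.frame from [responsePoints()], optionally filtered to
#'   a generation interval with `through_generation`.
#' @param through_generation keep only parental generations <= this value
#'   (e.g. 3 for the interval up to F4).
#' @return data.frame with `h2_realized`, `se`, `F`, `df1`, `df2`,
#'   `adj_r_squared`, `p_value`, `n_points`.
#' @export
realizedHeritability <- function(points, through_generation = NULL) {
  stopifnot(all(c("S_cum", "R_cum") %in% names(points)))
  if (!is.null(through_generation)) {
    points <- points[points$generation <= through_generation, , drop = FALSE]
  }
  if (nrow(points) < 2L) stop("need at least two points", call. = FALSE)
  if (all(points$S_cum == 0)) {
    stop("undefined slope: all cumulative selection differentials are zero",
         call. = FALSE)
  }
  fit <- lm(R_cum ~ 0 + S_cum, data = points)
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(h2_realized = co[1, 1], se = co[1, 2],
             F = co[1, 3]^2, df1 = 1L, df2 = fit$df.residual,
             adj_r_squared = sm$adj.r.squared,
             p_value = co[1, 4], n_points = nrow(points))
}

#' Selection intensity under truncation
#'
#' Standardized selection differential when the best fraction `p` of a
#' normally distributed trait is retained: i = phi(z) / p with z the upper
#' p-quantile of the standard normal. Retaining the top half gives
#' i = 0.798.
#'
#' @param p retained fraction in (0, 1\].
#' @return selection intensity (0 when p = 1), vectorized.
#' @examples
#' selectionIntensity(0.5) # 0.798
#' @export
selectionIntensity <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  z <- qnorm(p, lower.tail = FALSE)
  ifelse(p == 1, 0, dnorm(z) / p)
}

#' Breeder's-equation projection of the selection response
#'
#' Per-generation expected latent gain R = i * sigma_a * sqrt(h2), mapped
#' to an observed percentage trajectory. Because the latent-to-observed
#' mapping of a threshold trait is not unique, three strategies are
#' exposed: `"probit_unit"` (default), p_t = Phi(Phi^-1(p_0) + t R);
#' `"probit_scaled"`, the same with the gain divided by the total liability
#' SD `sigma_p`; `"linear"`, p_t = p_0 + t R with R read directly in
#' percentage points.
#'
#' @param i selection intensity (e.g. [selectionIntensity()]).
#' @param sigma_a additive genetic standard deviation, liability units
#'   (percentage points for `"linear"`).
#' @param h2 narrow-sense heritability.
#' @param start_percent starting mean percentage in (0, 100).
#' @param generations number of projected generations.
#' @param mapping latent-to-observed strategy (see above).
#' @param sigma_p total liability SD, required for `"probit_scaled"`.
#' @return list with `gain_per_generation` (latent) and `trajectory`
#'   (data.frame generation, percent).
#' @export
breedersProjection <- function(i, sigma_a, h2, start_percent = 24,
                               generations = 7,
                               mapping = c("probit_unit", "probit_scaled",
                                           "linear"),
                               sigma_p = NULL) {
  mapping <- match.arg(mapping)
  stopifnot(i >= 0, sigma_a >= 0, h2 >= 0, h2 <= 1)
  if (start_percent <= 0 || start_percent >= 100) {
    stop("start_percent must lie strictly between 0 and 100", call. = FALSE)
  }
  gain <- i * sigma_a * sqrt(h2)
  t_ <- 0:generations
  pct <- switch(mapping,
    probit_unit = 100 * pnorm(qnorm(start_percent / 100) + t_ * gain),
    probit_scaled = {
      if (is.null(sigma_p)) stop("sigma_p required for probit_scaled",
                                 call. = FALSE)
      100 * pnorm(qnorm(start_percent / 100) + t_ * gain / sigma_p)
    },
    linear = pmin(pmax(start_percent + t_ * gain, 0), 100))
  list(gain_per_generation = gain,
       trajectory = data.frame(generation = t_, percent = pct))
}
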