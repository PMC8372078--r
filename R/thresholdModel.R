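# Bayesian liability-threshold animal model for binomial performance counts.
#
# Trait records are (successes, trials) pairs per female, with testing day
# and mother as iid random effects and the animal (breeding value) effect
# structured by the haplodiploid relatedness matrix. The residual variance
# on the liability scale is fixed (default 1; not identifiable for binomial
# data) and heritability is computed per draw as
#   h2 = Va / (Va + Vday + Vmother + Vr + Vlink),
# where the link variance is 1 for the probit link and pi^2/3 for logit.

#' Sampler configuration for the threshold animal model
#'
#' @param link `"probit"` (default) or `"logit"`; the link only changes the
#'   binomial likelihood and the link variance entering the heritability
#'   denominator (1 vs pi^2/3).
#' @param n_samples post-burn-in iterations (default 20000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10, so the
#'   defaults retain 2000 draws; at least 1000 retained draws are required).
#' @param prior list with elements `V`, `nu`, `alpha_mu`, `alpha_V`. The
#'   implemented prior is the large-`nu` limit of the parameter-expanded
#'   inverse-Wishart: each variance component equals `alpha^2` with
#'   `alpha ~ N(alpha_mu, alpha_V * V)`, i.e. a scaled chi-square with one
#'   degree of freedom (the default `V = 1`, `alpha_V = 1` gives chi^2_1).
#' @param residual_variance fixed liability-scale residual variance
#'   (default 1).
#' @param seed integer seed used for the whole fit.
#' @return list of class `tamConfig`.
#' @export
thresholdModelConfig <- function(link = c("probit", "logit"),
                                 n_samples = 20000L, burn_in = 10000L,
                                 thin = 10L,
                                 prior = list(V = 1, nu = 1000,
                                              alpha_mu = 0, alpha_V = 1),
                                 residual_variance = 1, seed = 1L) {
  link <- match.arg(link)
  n_samples <- as.integer(n_samples); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(n_samples >= 1, burn_in >= 0, thin >= 1, residual_variance > 0)
  if (n_samples %/% thin < 1000L) {
    stop("configuration retains fewer than 1000 draws", call. = FALSE)
  }
  if (!is.null(prior$alpha_mu) && prior$alpha_mu != 0) {
    stop("only alpha_mu = 0 is supported", call. = FALSE)
  }
  structure(list(link = link, n_samples = n_samples, burn_in = burn_in,
                 thin = thin, prior = prior,
                 residual_variance = residual_variance,
                 seed = as.integer(seed)),
            class = "tamConfig")
}

linkVariance <- function(link) if (link == "probit") 1 else pi^2 / 3

#' Heritability from variance components
#'
#' h2 = Va / (Va + Vday + Vmother + Vr + Vlink); the link variance (1 for
#' probit) is added to the denominator because the liability scale carries
#' the implicit link-distribution variance on top of the fixed residual.
#'
#' @param va,vday,vmother,vr variance components (vectorized).
#' @param link `"probit"` or `"logit"`.
#' @return numeric in \[0, 1).
#' @examples
#' h2FromComponents(2, 0, 0) # 2 / (2 + 1 + 1) = 0.5
#' @export
h2FromComponents <- function(va, vday = 0, vmother = 0, vr = 1,
                             link = "probit") {
  va / (va + vday + vmother + vr + linkVariance(link))
}

#' Additive variance implied by a target heritability
#'
#' Inverse of [h2FromComponents()] in `va`; used to parameterize simulators
#' by latent-scale heritability.
#'
#' @param h2 target heritability in \[0, 1).
#' @inheritParams h2FromComponents
#' @return additive variance `va`.
#' @export
vaForTargetH2 <- function(h2, vday = 0, vmother = 0, vr = 1,
                          link = "probit") {
  stopifnot(h2 >= 0, h2 < 1)
  h2 * (vday + vmother + vr + linkVariance(link)) / (1 - h2)
}

#' Fit the liability-threshold animal model
#'
#' Gibbs sampler with a univariate slice update for the record-level latent
#' liabilities and conjugate Gaussian blocks for the intercept, breeding
#' values (in the eigenbasis of the relatedness matrix), day and mother
#' effects and the expansion parameters. One latent liability per record;
#' the binomial likelihood is evaluated directly.
#'
#' Two observation models are available. `"survival_adjusted"` (default for
#' killing rate) fits the raw emerged-fly counts,
#' `flies_emerged ~ Binomial(n_larvae, s_day (1 - linkinv(l)))`, with the
#' day's baseline survival `s_day` taken from its control vials — the
#' day-standardization lives in the likelihood, which avoids the
#' variance-eroding floor of zero-clamped standardized counts.
#' `"standardized_counts"` fits pre-built (successes, trials) pairs as
#' `successes ~ Binomial(trials, linkinv(l))` (see [standardizedCounts()]).
#'
#' @param data data.frame with one row per phenotyped female and columns
#'   `animal_id`, `day_id`, `mother_id`, plus, for
#'   `method = "standardized_counts"`: `successes`, `trials`; for
#'   `method = "survival_adjusted"`: `flies_emerged`, `n_larvae`,
#'   `day_survival` (see [rawTraitData()]).
#' @param A a [RelatednessMatrix-class] covering all `animal_id`s (extra ids
#'   are dropped via [phenotypedSubmatrix()]).
#' @param config a [thresholdModelConfig()].
#' @param method observation model, see above; the default is chosen from
#'   the columns present in `data`.
#' @param likelihood internal switch; `FALSE` samples the prior
#'   (prior-predictive checks), ignoring the counts.
#' @return a [ThresholdModelFit-class].
#' @export
fitThresholdModel <- function(data, A, config = thresholdModelConfig(),
                              method = c("auto", "survival_adjusted",
                                         "standardized_counts"),
                              likelihood = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data),
            all(c("animal_id", "day_id", "mother_id") %in% names(data)),
            is(A, "RelatednessMatrix"), inherits(config, "tamConfig"))
  if (nrow(data) == 0L) stop("empty trait dataset", call. = FALSE)
  if (method == "auto") {
    method <- if ("day_survival" %in% names(data)) "survival_adjusted"
              else "standardized_counts"
  }
  if (method == "survival_adjusted") {
    need <- c("flies_emerged", "n_larvae", "day_survival")
    if (!all(need %in% names(data))) {
      stop("survival_adjusted needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    y <- data$flies_emerged; ntr <- data$n_larvae
    surv <- data$day_survival
    if (any(surv <= 0 | surv > 1)) stop("day_survival must be in (0, 1]",
                                        call. = FALSE)
    lik_mode <- 1L
  } else {
    if (!all(c("successes", "trials") %in% names(data))) {
      stop("standardized_counts needs columns successes, trials",
           call. = FALSE)
    }
    y <- data$successes; ntr <- data$trials
    surv <- rep(1, nrow(data))
    lik_mode <- 0L
  }
  if (any(y < 0 | y > ntr)) {
    stop("counts must lie in [0, trials]", call. = FALSE)
  }
  ids <- as.character(data$animal_id)
  if (anyDuplicated(ids)) {
    stop("one record per animal expected; aggregate repeated assays first",
         call. = FALSE)
  }
  Asub <- relatedness(phenotypedSubmatrix(A, ids))
  eg <- eigen(Asub, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(eg$values)) {
    stop("relatedness submatrix is not positive semi-definite", call. = FALSE)
  }
  lambda <- pmax(eg$values, 1e-10)
  day <- as.integer(factor(data$day_id)) - 1L
  mom <- as.integer(factor(data$mother_id)) - 1L
  alpha_v <- config$prior$alpha_V * config$prior$V
  set.seed(config$seed)
  m <- .tamSampler(as.integer(y), as.integer(ntr),
                   day, mom, eg$vectors, lambda,
                   config$n_samples, config$burn_in, config$thin,
                   alpha_v, config$residual_variance,
                   if (config$link == "probit") 0L else 1L,
                   isTRUE(likelihood), lik_mode, as.numeric(surv))
  d <- data.frame(mu = m[, 1], va = m[, 2], vday = m[, 3], vmother = m[, 4])
  d$h2 <- h2FromComponents(d$va, d$vday, d$vmother,
                           config$residual_variance, config$link)
  cfg_out <- unclass(config)
  cfg_out$method <- method
  new("ThresholdModelFit", draws = d, config = cfg_out)
}

#' Posterior mode via kernel density
#'
#' Mode of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) over the draws; the point estimate used for all reported
#' variance components and heritabilities.
#'
#' @param samples numeric vector of at least 100 draws.
#' @return the density-maximizing value.
#' @export
posteriorMode <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100L) stop("need at least 100 draws", call. = FALSE)
  if (sd(samples) == 0) return(samples[1])
  dd <- density(samples, bw = "nrd0", n = 1024)
  dd$x[which.max(dd$y)]
}

#' Highest posterior density interval
#'
#' Shortest empirical interval containing a given posterior mass.
#'
#' @param samples numeric vector of draws.
#' @param mass probability mass in (0, 1) (default 0.95).
#' @return numeric of length 2, `c(lower, upper)`.
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop("degenerate sample", call. = FALSE)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

# ---- convergence diagnostics ----

#' Effective sample size (initial monotone sequence)
#'
#' Geyer's initial monotone positive sequence estimator of the integrated
#' autocorrelation time; for iid draws ESS is approximately the chain
#' length.
#'
#' @param x numeric chain.
#' @return effective number of independent draws.
#' @export
effectiveSampleSize <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(0)
  if (n < 10L) return(n)
  rho <- as.numeric(acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf)
  # paired sums Gamma_m = rho_{2m} + rho_{2m+1}; rho[1] is lag 0
  npair <- length(rho) %/% 2L
  gam <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  neg <- which(gam <= 0)
  if (length(neg)) gam <- gam[seq_len(neg[1] - 1L)]
  if (length(gam) > 1L) gam <- cummin(gam)  # initial monotone sequence
  tau <- max(1, -1 + 2 * sum(gam))
  n / tau
}

# Cramer-von Mises goodness-of-fit distribution (asymptotic CDF)
pcramer <- function(q) {
  if (q <= 0) return(0)
  k <- 0:3
  z <- (4 * k + 1)^2 / (16 * q)
  term <- ifelse(z > 700, 0,
                 gamma(k + 0.5) * sqrt(4 * k + 1) / factorial(k) *
                   exp(-z) * besselK(z, 0.25))
  min(1, max(0, sum(term) / (pi^1.5 * sqrt(q))))
}

# spectral density at frequency zero via an AR fit (used to studentize the
# Brownian-bridge statistic)
spectrum0 <- function(x) {
  if (sd(x) == 0) return(0)
  fit <- try(ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger-Welch stationarity test
#'
#' Cramer-von-Mises test on the cumulative-sum Brownian bridge of the
#' chain, studentized by the spectral density at zero; on failure the
#' initial 10% of the chain is discarded and the test repeated, up to half
#' the chain.
#'
#' @param x numeric chain.
#' @param alpha significance level (default 0.05).
#' @return list with `passed`, `p_value`, `start` (first retained index).
#' @export
heidelbergerWelch <- function(x, alpha = 0.05) {
  n0 <- length(x)
  if (n0 < 100L) stop("chain too short for stationarity testing", call. = FALSE)
  # spectral density at zero from the second half of the chain, assumed
  # closest to stationarity (the classical formulation)
  s0 <- spectrum0(x[(n0 %/% 2L):n0])
  start <- 1L
  repeat {
    y <- x[start:n0]
    n <- length(y)
    if (s0 <= 0) return(list(passed = TRUE, p_value = 1, start = start))
    cs <- cumsum(y)
    t_ <- seq_len(n)
    b <- (cs - t_ * mean(y)) / sqrt(n * s0)
    cvm <- sum(b^2) / n
    p <- 1 - pcramer(cvm)
    if (p >= alpha || start > n0 %/% 2L) {
      return(list(passed = p >= alpha, p_value = p, start = start))
    }
    start <- start + max(1L, n0 %/% 10L)
  }
}

#' Convergence diagnostics for a model fit
#'
#' Lag-1 autocorrelation of the retained (thinned) chains, effective sample
#' size and the Heidelberger-Welch stationarity test for every sampled
#' parameter, with pass flags at the conventional thresholds
#' (autocorrelation < 0.1, ESS > 1000, stationarity at level 0.05).
#'
#' @param fit a [ThresholdModelFit-class] with at least 1000 retained draws.
#' @return data.frame, one row per parameter.
#' @export
modelDiagnostics <- function(fit) {
  stopifnot(is(fit, "ThresholdModelFit"))
  d <- draws(fit)
  if (nrow(d) < 1000L) stop("need at least 1000 retained draws", call. = FALSE)
  res <- lapply(names(d), function(p) {
    x <- d[[p]]
    l1 <- if (sd(x) == 0) 0 else acf(x, lag.max = 1, plot = FALSE)$acf[2]
    ess <- effectiveSampleSize(x)
    hw <- heidelbergerWelch(x)
    data.frame(parameter = p, lag1_autocorr = l1, ess = ess,
               stationary = hw$passed, hw_p = hw$p_value,
               autocorr_ok = abs(l1) < 0.1, ess_ok = ess > 1000)
  })
  do.call(rbind, res)
}
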