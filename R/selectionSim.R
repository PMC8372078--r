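# Genotype-explicit forward simulator of the truncation-selection
# experiment: three selected and three control lines of 100 females, the
# top 50 (by day-standardized killing rate) contributing eight pupae each,
# for seven generations, under a drifting host-fitness environment.
#
# Genetics: n_loci additive loci with free recombination; females carry two
# haplotypes, males one. A daughter receives her sire's haplotype and one
# recombined maternal gamete, a son one maternal gamete (haplodiploidy).
# Founder allelic values are iid Normal with per-haplotype, per-locus
# variance Va / (2 n_loci) so female breeding values have variance Va.
#
# Host-fitness drift: control survival s_t is flat up to the trend start
# generation and then rises linearly to (1 + host_survival_increase) x
# baseline at the final generation. Laboratory adaptation of the host is
# modeled as raising host resistance on the liability scale by
# resistance_coupling * (qnorm(s_t) - qnorm(s_0)), so the visible survival
# trend and the drop in realized killing share one cause; coupling 0
# decouples them (survival trend only, which day-standardization cancels).

#' Configuration of the selection experiment simulator
#'
#' Defaults are the reference experimental design (3 + 3 lines of 100
#' females, top-50 truncation, 7 generations, 25 larvae per assay, 8 pupae
#' per selected mother, ~30% rise in baseline host survival from generation
#' 2 onward). Variance-component defaults are the half-sib posterior modes
#' for day-standardized killing rate shipped with the package.
#'
#' @param n_lines_selected,n_lines_control numbers of lines.
#' @param females_per_line,males_per_line assayed females / available males.
#' @param selected_per_generation mothers retained by truncation (50).
#' @param generations selected generations after the base (7).
#' @param n_loci additive loci (100; approximates the infinitesimal model).
#' @param true_va,true_vday,true_vmother liability-scale variance components.
#' @param base_mean_liability mean liability of the base population; the
#'   default -1.3 puts the expected initial killing rate near 24%.
#' @param baseline_host_survival control survival probability at the start
#'   (0.74, so a 30% rise stays below 1).
#' @param host_survival_increase total proportional rise by the final
#'   generation (0.30).
#' @param trend_start_generation generation after which survival rises (2).
#' @param resistance_coupling liability-scale shift per probit unit of the
#'   survival trend (1 = laboratory adaptation raises resistance in step
#'   with survival; 0 = survival trend only).
#' @param larvae_per_assay larvae per exposure vial (25).
#' @param days_per_generation testing days over which each line's females
#'   are spread within a generation (3, within the protocol's 2-5 days);
#'   each day has its own day effect and control vials.
#' @param control_vials_per_day unexposed vials per testing day (10).
#' @param pupae_per_mother offspring pupae taken per selected mother (8).
#' @param sex_ratio probability an offspring is female (0.5).
#' @param encapsulation_prob probability a surviving attacked larva shows a
#'   capsule (0.25).
#' @param offspring_success_prob probability a killed host yields a wasp
#'   (0: development on the novel host essentially always fails).
#' @return list of class `selConfig`.
#' @export
selectionConfig <- function(n_lines_selected = 3L, n_lines_control = 3L,
                            females_per_line = 100L, males_per_line = 100L,
                            selected_per_generation = 50L, generations = 7L,
                            n_loci = 100L,
                            true_va = 1.077, true_vday = 0.3453,
                            true_vmother = 0.001,
                            base_mean_liability = -1.3,
                            baseline_host_survival = 0.74,
                            host_survival_increase = 0.30,
                            trend_start_generation = 2L,
                            resistance_coupling = 1,
                            larvae_per_assay = 25L,
                            days_per_generation = 3L,
                            control_vials_per_day = 10L,
                            pupae_per_mother = 8L, sex_ratio = 0.5,
                            encapsulation_prob = 0.25,
                            offspring_success_prob = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$selected_per_generation <= cfg$females_per_line,
            cfg$true_va >= 0, cfg$true_vday >= 0, cfg$true_vmother >= 0,
            cfg$baseline_host_survival > 0, cfg$baseline_host_survival <= 1,
            cfg$baseline_host_survival * (1 + cfg$host_survival_increase) <= 1,
            cfg$generations >= 1, cfg$n_loci >= 1)
  structure(cfg, class = "selConfig")
}

#' Host survival path over generations
#'
#' @param config a [selectionConfig()].
#' @param generation integer vector (0 = base population).
#' @return survival probabilities.
#' @export
hostSurvivalPath <- function(config, generation) {
  s0 <- config$baseline_host_survival
  g0 <- config$trend_start_generation
  G <- config$generations
  prog <- pmax(0, pmin(1, (generation - g0) / max(1, G - g0)))
  pmin(s0 * (1 + config$host_survival_increase * prog), 0.995)
}

#' Found a base population
#'
#' Draws founder haplotypes so that female breeding values (sum of allelic
#' values over both haplotypes) have variance `true_va` and mean 0.
#'
#' @param config a [selectionConfig()].
#' @param n_females,n_males population sizes (defaults from the config).
#' @return list with matrices `fem1`, `fem2` (n_females x n_loci) and
#'   `male` (n_males x n_loci).
#' @export
initBasePopulation <- function(config, n_females = config$females_per_line,
                               n_males = config$males_per_line) {
  sdl <- sqrt(config$true_va / (2 * config$n_loci))
  L <- config$n_loci
  list(fem1 = matrix(rnorm(n_females * L, 0, sdl), n_females, L),
       fem2 = matrix(rnorm(n_females * L, 0, sdl), n_females, L),
       male = matrix(rnorm(n_males * L, 0, sdl), n_males, L))
}

#' Female breeding values of a simulated population
#'
#' Sum of allelic effects over both haplotypes.
#'
#' @param pop population list as from [initBasePopulation()] or
#'   [breedNextGeneration()].
#' @return numeric vector, one value per female.
#' @export
breedingValues <- function(pop) rowSums(pop$fem1) + rowSums(pop$fem2)

gamete <- function(h1, h2) {
  pick <- matrix(runif(length(h1)) < 0.5, nrow(h1), ncol(h1))
  ifelse(pick, h1, h2)
}

#' Simulate one generation of exposure assays
#'
#' For each female: liability l = base mean + breeding value + day effect +
#' mother effect + N(0,1) residual; per-larva kill probability
#' q = Phi(l - resistance shift); flies emerged f ~ Binomial(larvae,
#' s_t (1 - q)); capsules e ~ Binomial(f, encapsulation_prob); offspring
#' p ~ Binomial(killed, offspring_success_prob).
#'
#' @param g numeric vector of breeding values.
#' @param day_effect scalar testing-day effect on the liability scale.
#' @param mother_effect numeric vector (per female).
#' @param host_survival current control survival s_t.
#' @param config a [selectionConfig()].
#' @return data.frame with columns `n_larvae`, `flies_emerged`,
#'   `flies_encapsulated`, `wasp_offspring`, `liability`.
#' @export
assayPhenotype <- function(g, day_effect = 0, mother_effect = 0,
                           host_survival = config$baseline_host_survival,
                           config = selectionConfig()) {
  n <- length(g)
  L <- config$larvae_per_assay
  shift <- if (config$resistance_coupling == 0 ||
               host_survival == config$baseline_host_survival) 0
  else config$resistance_coupling *
    (qnorm(host_survival) - qnorm(config$baseline_host_survival))
  l <- config$base_mean_liability + g + day_effect + mother_effect + rnorm(n)
  q <- pnorm(l - shift)
  f <- rbinom(n, L, host_survival * (1 - q))
  e <- rbinom(n, f, config$encapsulation_prob)
  killed <- pmax(L - f, 0)
  p <- rbinom(n, killed, config$offspring_success_prob)
  data.frame(n_larvae = L, flies_emerged = f, flies_encapsulated = e,
             wasp_offspring = p, liability = l)
}

#' Truncation selection on a trait
#'
#' Indices of the `k` highest trait values; ties are broken uniformly at
#' random. With `random = TRUE` (control lines) a uniformly random
#' k-subset is returned instead.
#'
#' @param trait numeric vector.
#' @param k number to retain (1..length(trait)).
#' @param random select at random instead of by trait value.
#' @return integer indices of the selected individuals.
#' @export
truncationSelect <- function(trait, k, random = FALSE) {
  n <- length(trait)
  if (k <= 0 || k > n) stop("k must be in 1..n", call. = FALSE)
  if (random) return(sample.int(n, k))
  ord <- order(trait, runif(n), decreasing = TRUE)
  ord[seq_len(k)]
}

#' Breed the next generation from selected mothers
#'
#' Each selected mother (already mated to one male of her line's pool)
#' contributes `pupae_per_mother` offspring; sex follows fertilization
#' (daughters diploid, sons haploid). The pooled offspring then mate among
#' each other implicitly: the returned population holds 100 sampled
#' daughters and all sons, from which the next round draws mates.
#'
#' @param mothers list with `fem1`, `fem2` haplotype matrices of the
#'   selected mothers.
#' @param sires matrix of the line's male haplotypes; each mother is
#'   assigned one uniformly drawn mate.
#' @param config a [selectionConfig()].
#' @return population list (`fem1`, `fem2`, `male`) plus `dam` (index of
#'   each daughter's mother) as attribute `dam`.
#' @export
breedNextGeneration <- function(mothers, sires, config) {
  nm <- nrow(mothers$fem1)
  if (nm == 0L) stop("no mothers selected", call. = FALSE)
  if (nrow(sires) == 0L) stop("mating failure: no males available", call. = FALSE)
  mate <- sample.int(nrow(sires), nm, replace = TRUE)
  np <- config$pupae_per_mother
  dam <- rep(seq_len(nm), each = np)
  female <- runif(length(dam)) < config$sex_ratio
  mat_gam <- gamete(mothers$fem1[dam, , drop = FALSE],
                    mothers$fem2[dam, , drop = FALSE])
  d_idx <- which(female)
  s_idx <- which(!female)
  fem1 <- sires[mate[dam[d_idx]], , drop = FALSE]   # paternal haplotype
  fem2 <- mat_gam[d_idx, , drop = FALSE]
  malh <- mat_gam[s_idx, , drop = FALSE]
  if (nrow(malh) == 0L) stop("mating failure: no male offspring", call. = FALSE)
  nf <- config$females_per_line
  if (nrow(fem1) < nf) {
    stop("fewer daughters (", nrow(fem1), ") than assayed cohort size (",
         nf, ")", call. = FALSE)
  }
  keep <- sample.int(nrow(fem1), nf)
  pop <- list(fem1 = fem1[keep, , drop = FALSE],
              fem2 = fem2[keep, , drop = FALSE],
              male = malh)
  attr(pop, "dam") <- dam[d_idx][keep]
  pop
}

#' Run the full selection experiment
#'
#' Simulates all selected and control lines over the configured
#' generations; generation 0 is the assayed base population. Day effects
#' are drawn fresh per line and generation, control vials give the n_bar
#' used for day-standardized killing rates, and mother effects are drawn
#' per dam.
#'
#' @param config a [selectionConfig()].
#' @param seed integer seed.
#' @return a [SelectionTrajectory-class].
#' @export
runExperiment <- function(config = selectionConfig(), seed = 1L) {
  set.seed(seed)
  lines <- c(paste0("S", seq_len(config$n_lines_selected)),
             paste0("C", seq_len(config$n_lines_control)))
  is_control <- grepl("^C", lines)
  rec_list <- list(); sum_list <- list()
  for (li in seq_along(lines)) {
    pop <- initBasePopulation(config)
    dam_idx <- NULL   # base population: unknown dams
    mother_eff_by_dam <- NULL
    for (gen in 0:config$generations) {
      s_t <- hostSurvivalPath(config, gen)
      nd <- config$days_per_generation
      day_of <- rep_len(seq_len(nd), nrow(pop$fem1))
      day_eff <- rnorm(nd, 0, sqrt(config$true_vday))
      if (is.null(dam_idx)) {
        mom_eff <- rnorm(nrow(pop$fem1), 0, sqrt(config$true_vmother))
      } else {
        mom_eff <- mother_eff_by_dam[dam_idx]
      }
      g <- breedingValues(pop)
      asy <- assayPhenotype(g, day_eff[day_of], mom_eff, s_t, config)
      n_bar_day <- vapply(seq_len(nd), function(d) {
        mean(rbinom(config$control_vials_per_day, config$larvae_per_assay,
                    s_t))
      }, numeric(1))
      n_bar <- n_bar_day[day_of]
      kr <- killingRate(asy$flies_emerged, n_bar)
      k <- config$selected_per_generation
      sel <- truncationSelect(kr, k, random = is_control[li])
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        line = lines[li], generation = gen,
        female = seq_along(g), day = day_of, asy, breeding_value = g,
        killing_rate_std = kr, n_bar = n_bar,
        selected = seq_along(g) %in% sel)
      sum_list[[length(sum_list) + 1L]] <- data.frame(
        line = lines[li], generation = gen, control = is_control[li],
        mean_all = mean(kr), mean_selected = mean(kr[sel]),
        mean_g = mean(g), n_bar = mean(n_bar_day), host_survival = s_t)
      if (gen < config$generations) {
        mothers <- list(fem1 = pop$fem1[sel, , drop = FALSE],
                        fem2 = pop$fem2[sel, , drop = FALSE])
        mother_eff_by_dam <- rnorm(k, 0, sqrt(config$true_vmother))
        pop <- breedNextGeneration(mothers, pop$male, config)
        dam_idx <- attr(pop, "dam")
      }
    }
  }
  new("SelectionTrajectory",
      records = do.call(rbind, rec_list),
      summary = do.call(rbind, sum_list),
      config = unclass(config))
}
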