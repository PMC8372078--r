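test_that("base population realizes the target additive variance", {
  cfg <- selectionConfig()
  set.seed(1)
  expect_equal(breedingValues(initBasePopulation(
    selectionConfig(true_va = 0), 50, 10)), rep(0, 50))
  pop <- initBasePopulation(selectionConfig(true_va = 1), 1e4, 10)
  expect_lt(abs(var(breedingValues(pop)) - 1), 0.05)
})

test_that("assay counts follow the liability model", {
  set.seed(2)
  base0 <- selectionConfig(true_va = 0, true_vday = 0, true_vmother = 0,
                           baseline_host_survival = 1,
                           host_survival_increase = 0,
                           resistance_coupling = 0,
                           base_mean_liability = -50)
  asy <- assayPhenotype(rep(0, 200), host_survival = 1, config = base0)
  expect_true(all(asy$flies_emerged == 25))     # nothing killed
  base1 <- base0; base1$base_mean_liability <- 50
  asy1 <- assayPhenotype(rep(0, 200), host_survival = 1, config = base1)
  expect_true(all(asy1$flies_emerged == 0))     # everything killed

  # mean emergence = survival x P(not killed) = 0.8 x 0.5 at mean liability 0
  cfg <- selectionConfig(true_va = 0, true_vday = 0, true_vmother = 0,
                         baseline_host_survival = 0.8,
                         host_survival_increase = 0,
                         base_mean_liability = 0, resistance_coupling = 0)
  asy2 <- assayPhenotype(rep(0, 1e5), host_survival = 0.8, config = cfg)
  expect_lt(abs(mean(asy2$flies_emerged) / 25 - 0.4), 0.005)
})

test_that("truncation selection takes the top k, ties broken uniformly", {
  set.seed(3)
  x <- c(5, 9, 1, 7, 3)
  expect_setequal(truncationSelect(x, 2), c(2L, 4L))
  expect_setequal(truncationSelect(x, 5), 1:5)
  expect_error(truncationSelect(x, 0), "k must be")

  picks <- vapply(1:4000, function(i) truncationSelect(rep(1, 4), 1),
                  integer(1))
  expect_gt(chisq.test(table(picks))$p.value, 0.01)
})

test_that("breeding transmits haplotypes and matches expected relatedness", {
  cfg <- selectionConfig(true_va = 1, pupae_per_mother = 2L,
                         females_per_line = 5000L)
  set.seed(4)
  # clonal single mother: all daughters share the sire's haplotype
  loci <- cfg$n_loci
  mo <- list(fem1 = matrix(0.3, 1, loci), fem2 = matrix(0.3, 1, loci))
  si <- matrix(0.1, 1, loci)
  cl <- selectionConfig(pupae_per_mother = 40L, females_per_line = 10L,
                        selected_per_generation = 5L)
  pop <- breedNextGeneration(mo, si, cl)
  expect_true(all(pop$fem1 == 0.1))
  expect_true(all(pop$fem2 == 0.3))

  # many mothers: daughter breeding values track parent means, and full
  # sisters covary at 0.75 Va
  base <- initBasePopulation(cfg, 6000, 6000)
  pop2 <- breedNextGeneration(list(fem1 = base$fem1, fem2 = base$fem2),
                              base$male, cfg)
  g <- breedingValues(pop2)
  gm <- rowSums(base$fem1) + rowSums(base$fem2)
  expect_lt(abs(mean(g) - mean(gm) / 2), 4 * sd(g) / sqrt(length(g)))
  dam <- attr(pop2, "dam")
  sib <- split(seq_along(dam), dam)
  sib <- sib[lengths(sib) == 2]
  pairs <- t(vapply(sib, function(i) g[i], numeric(2)))
  # full sisters here (one mate per mother): cov = 0.75 Va
  expect_lt(abs(cov(pairs[, 1], pairs[, 2]) - 0.75), 0.12)
  expect_error(breedNextGeneration(mo, si[0, , drop = FALSE], cl),
               "no males")
})

test_that("null experiment shows no realized heritability", {
  slopes <- vapply(1:8, function(s) {
    cfg <- selectionConfig(true_va = 0, host_survival_increase = 0,
                           n_lines_control = 1L)
    realizedHeritability(responsePoints(runExperiment(cfg, seed = s)))$h2_realized
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("selection increases killing rate when heritable and untrended", {
  va <- vaForTargetH2(0.28, 0.3453, 0.001)
  up <- vapply(1:12, function(s) {
    cfg <- selectionConfig(true_va = va, host_survival_increase = 0,
                           n_lines_control = 1L)
    tr <- trajectorySummary(runExperiment(cfg, seed = s))
    sel <- tr[!tr$control, ]
    m <- aggregate(mean_all ~ generation, sel, mean)
    cor(m$generation, m$mean_all, method = "spearman")
  }, numeric(1))
  expect_gte(sum(up > 0), 10)
  # and control lines stay flat on average
  ctl <- vapply(1:12, function(s) {
    cfg <- selectionConfig(true_va = va, host_survival_increase = 0,
                           n_lines_selected = 1L, n_lines_control = 1L)
    tr <- trajectorySummary(runExperiment(cfg, seed = 100 + s))
    co <- tr[tr$control, ]
    coef(lm(mean_all ~ generation, co))[2]
  }, numeric(1))
  expect_lt(abs(mean(ctl)), 1.5)
})

test_that("the host survival path is flat, then rises 30% by the end", {
  cfg <- selectionConfig()
  s <- hostSurvivalPath(cfg, 0:7)
  expect_equal(s[1:3], rep(cfg$baseline_host_survival, 3))
  expect_equal(s[8] / s[1], 1.30, tolerance = 1e-8)
  expect_true(all(diff(s) >= 0))
})
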