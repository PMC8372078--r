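test_that("default design reports the realized family totals", {
  d <- halfsibDesign()
  sim <- generateHalfsib(d, halfsibTruth(), seed = 1)
  expect_equal(sim$truth$realized$n_sires, 68L)
  expect_equal(sim$truth$realized$n_dams, 28 + 2 * 33 + 3 * 7)   # 115
  expect_equal(sim$truth$realized$n_daughters, 3 * 115)          # 345
  expect_equal(nrow(sim$trials), 345L)
  expect_equal(nrow(sim$controls), 5 * 10)
  expect_error(halfsibDesign(n_sires = 10,
                             dams_per_sire = c("1" = 3, "2" = 3, "3" = 3)))
})

test_that("all-zero variances give every daughter the same kill probability", {
  tr <- halfsibTruth(va = 0, vday = 0, vmother = 0, vr = 0,
                     day_survival_sd = 0)
  sim <- generateHalfsib(smallHalfsibDesign(), tr, seed = 2)
  expect_equal(var(sim$truth$liabilities), 0)
  expect_equal(var(sim$truth$breeding_values), 0)
})

test_that("generated tables round-trip through the validated readers", {
  sim <- generateHalfsib(smallHalfsibDesign(), halfsibTruth(), seed = 3)
  td <- withr::local_tempdir()
  writeTableCsv(sim$trials, file.path(td, "trials.csv"))
  writeTableCsv(sim$controls, file.path(td, "controls.csv"))
  writeTableCsv(sim$pedigree, file.path(td, "ped.csv"))
  tr <- readTrialsTable(file.path(td, "trials.csv"))
  expect_equal(tr$flies_emerged, sim$trials$flies_emerged)
  ct <- readControlsTable(file.path(td, "controls.csv"))
  expect_equal(ct$n_emerged, sim$controls$n_emerged)
  ped <- buildPedigree(readPedigreeTable(file.path(td, "ped.csv")))
  expect_equal(sort(pedIds(ped)), sort(sim$pedigree$id))
})

test_that("generation is deterministic in the seed", {
  a <- generateHalfsib(smallHalfsibDesign(), halfsibTruth(), seed = 11)
  b <- generateHalfsib(smallHalfsibDesign(), halfsibTruth(), seed = 11)
  c <- generateHalfsib(smallHalfsibDesign(), halfsibTruth(), seed = 12)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$breeding_values, b$truth$breeding_values)
  expect_false(identical(a$trials$flies_emerged, c$trials$flies_emerged))
})

test_that("liability variance decomposes as configured (sib-analysis oracle)", {
  # paternal half-sisters (same sire, different dams) covary at Va / 2
  # under haplodiploidy, so the moment estimator 2 x (mean cross-dam
  # product of centred liabilities) recovers Va, and the implied h2 the
  # configured heritability, independent of the Bayesian machinery
  va_t <- vaForTargetH2(0.3, 0.3453, 0.001)
  est <- vapply(1:40, function(s) {
    sim <- generateHalfsib(halfsibDesign(), halfsibTruth(va = va_t),
                           seed = 400 + s)
    tr <- sim$trials
    x <- sim$truth$liabilities[as.character(tr$female_id)] -
      sim$truth$day_effects[as.character(tr$day_id)]
    x <- x - mean(x)
    prods <- unlist(lapply(split(seq_len(nrow(tr)), tr$sire_id),
                           function(idx) {
      if (length(unique(tr$mother_id[idx])) < 2) return(NULL)
      pr <- outer(x[idx], x[idx])
      diff_dam <- outer(tr$mother_id[idx], tr$mother_id[idx], "!=")
      pr[upper.tri(pr) & diff_dam]
    }))
    2 * mean(prods)
  }, numeric(1))
  va_hat <- mean(est)
  h2_hat <- va_hat / (va_hat + 0.3453 + 0.001 + 2)
  expect_lt(abs(h2_hat - 0.3), 0.05)
})

test_that("index computation inverts the generative probabilities", {
  # noise-free corner: everything survives, nothing killed
  tr0 <- halfsibTruth(va = 0, vday = 0, vmother = 0, vr = 0,
                      base_mean = -50, baseline_survival = 1,
                      day_survival_sd = 0, encapsulation_prob = 0)
  sim <- generateHalfsib(smallHalfsibDesign(), tr0, seed = 5)
  perf <- performanceTable(sim$trials, sim$controls, qc = FALSE)
  expect_true(all(perf$killing_rate == 0))
  expect_true(all(perf$attack_rate == 0))
  # moderate kill probability: mean standardized killing ~ Phi(l)
  tr1 <- halfsibTruth(va = 0, vday = 0, vmother = 0, vr = 0,
                      base_mean = -0.5, day_survival_sd = 0)
  sim1 <- generateHalfsib(halfsibDesign(), tr1, seed = 6)
  perf1 <- performanceTable(sim1$trials, sim1$controls, qc = FALSE)
  expect_lt(abs(mean(perf1$killing_rate) / 100 - pnorm(-0.5)), 0.04)
})

test_that("block-quality scenario reproduces one low day among four good", {
  ctl <- generateBlockQualityScenario(seed = 9)
  s <- summarizeDayControls(ctl)
  expect_equal(nrow(s), 5L)
  expect_true(all(abs(s$n_bar - c(10.8, 21.1, 20.0, 22.0, 20.0)) <= 1))
  expect_equal(nrow(qcFilterBlocks(s)$retained), 4L)

  flat <- generateBlockQualityScenario(seed = 9, targets = rep(20, 5))
  expect_equal(nrow(qcFilterBlocks(summarizeDayControls(flat))$retained), 5L)
})
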