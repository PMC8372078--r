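test_that("day control summaries are per-day arithmetic means", {
  v <- data.frame(day_id = rep(c("d1", "d2"), c(3, 1)),
                  n_larvae = 25, n_emerged = c(20, 22, 18, 25))
  s <- summarizeDayControls(v)
  expect_equal(s$n_bar[s$day_id == "d1"], 20)
  expect_equal(s$n_vials[s$day_id == "d1"], 3L)
  expect_equal(s$n_bar[s$day_id == "d2"], 25)
  expect_error(summarizeDayControls(v, day = "d9"), "no control vials")
})

test_that("the four indices reproduce hand-computed cases", {
  # n_bar 20, f 10 of which 4 encapsulated (w = 6), 1 wasp offspring
  expect_equal(attackRate(f = 10, e = 4, n_bar = 20), 70)
  expect_equal(killingRate(f = 10, n_bar = 20), 50)
  expect_equal(lethalAttackRate(f = 10, e = 4, n_bar = 20), 100 * 10 / 14)
  expect_equal(successfulParasitism(p = 1, f = 10, n_bar = 20), 10)

  # full survival, no capsules: nothing attacked, nothing killed
  expect_equal(attackRate(20, 0, 20), 0)
  expect_equal(killingRate(20, 20), 0)
  expect_true(is.na(lethalAttackRate(20, 0, 20)))
  expect_true(is.na(successfulParasitism(0, 20, 20)))

  # better-than-control survival clamps to zero
  expect_equal(killingRate(f = 22, n_bar = 18), 0)
  expect_equal(attackRate(f = 22, e = 0, n_bar = 18), 0)

  # all attacked flies killed; zero offspring from real kills
  expect_equal(lethalAttackRate(f = 12, e = 0, n_bar = 20), 100)
  expect_equal(successfulParasitism(p = 0, f = 10, n_bar = 20), 0)

  expect_error(killingRate(5, n_bar = 0), "degenerate")
})

test_that("index identities and invariances hold across random counts", {
  set.seed(42)
  for (i in 1:200) {
    n_bar <- runif(1, 5, 30)
    f <- rbinom(1, 25, runif(1))
    e <- rbinom(1, f, runif(1))
    expect_lte(killingRate(f, n_bar), attackRate(f, e, n_bar))
    # scale invariance under integer inflation of all counts
    k <- sample(2:5, 1)
    expect_equal(attackRate(k * f, k * e, k * n_bar),
                 attackRate(f, e, n_bar))
    expect_equal(killingRate(k * f, k * n_bar), killingRate(f, n_bar))
    expect_equal(lethalAttackRate(k * f, k * e, k * n_bar),
                 lethalAttackRate(f, e, n_bar))
    # with no encapsulation, killing efficiency is all-or-nothing
    if (f <= n_bar) {
      lar <- lethalAttackRate(f, 0, n_bar)
      kr <- killingRate(f, n_bar)
      if (kr > 0) expect_equal(lar, 100) else expect_true(is.na(lar))
    }
  }
})

test_that("block quality control drops low-survival days once", {
  s <- data.frame(day_id = paste0("b", 1:3), n_bar = c(5, 20, 20),
                  n_vials = 10)
  out <- qcFilterBlocks(s, 0.6)
  expect_equal(nrow(out$retained), 2L)
  expect_equal(out$excluded$day_id, "b1")

  same <- data.frame(day_id = paste0("b", 1:4), n_bar = 20, n_vials = 10)
  expect_equal(nrow(qcFilterBlocks(same)$retained), 4L)

  # order independence and idempotency on realistic scenarios
  set.seed(7)
  for (i in 1:20) {
    nb <- c(runif(1, 8, 12), runif(4, 18, 23))
    sc <- data.frame(day_id = paste0("b", 1:5), n_bar = nb, n_vials = 10)
    perm <- sc[sample(5), , drop = FALSE]
    r1 <- qcFilterBlocks(sc)$retained
    r2 <- qcFilterBlocks(perm)$retained
    expect_setequal(r1$day_id, r2$day_id)
    expect_setequal(qcFilterBlocks(r1)$retained$day_id, r1$day_id)
  }

  expect_error(qcFilterBlocks(s[1, , drop = FALSE]), "at least two")
  low <- data.frame(day_id = c("a", "b"), n_bar = c(0, 0), n_vials = 1)
  expect_error(qcFilterBlocks(transform(low, n_bar = c(1, 100)),
                              ratio_threshold = 2), "all blocks excluded")
})

test_that("standardized count pairs use the rounded control mean as total", {
  expect_equal(standardizedCounts(f = 10, n_bar = 20.4, index = "killing")[
    , c("successes", "failures")], data.frame(successes = 10L, failures = 10L))
  expect_equal(standardizedCounts(f = 20, n_bar = 20, index = "killing")$successes, 0L)
  att <- standardizedCounts(f = 10, e = 4, n_bar = 20, index = "attack")
  expect_equal(c(att$successes, att$failures), c(14L, 6L))
  und <- standardizedCounts(f = 20, e = 0, n_bar = 20, index = "lethal_attack")
  expect_false(und$defined)
  # half-away-from-zero rounding of the total (20.5 -> 21, not 20)
  expect_equal(standardizedCounts(f = 0, n_bar = 20.5,
                                  index = "killing")$successes, 21L)
})

test_that("performanceTable joins, filters and flags", {
  set.seed(1)
  ctl <- generateBlockQualityScenario(seed = 3)
  trials <- data.frame(
    female_id = sprintf("w%d", 1:10),
    day_id = rep(sprintf("B%d", 1:5), each = 2),
    line_id = "L", generation = 0L, n_larvae = 25L,
    flies_emerged = c(10, 22, 15, 3, 20, 8, 25, 0, 12, 18),
    flies_encapsulated = c(4, 0, 2, 1, 0, 3, 0, 0, 5, 2),
    wasp_offspring = 0L)
  tab <- performanceTable(trials, ctl)
  expect_equal(attr(tab, "excluded_days")$day_id, "B1")
  expect_false(any(tab$day_id == "B1"))
  expect_true(all(tab$killing_rate >= 0 & tab$killing_rate <= 100))
  expect_true(all(tab$attack_rate >= tab$killing_rate, na.rm = TRUE))
  # a female with full emergence and no capsules has undefined efficiency
  i <- which(tab$female_id == "w7")
  expect_false(tab$lethal_defined[i])
  expect_true(is.na(tab$lethal_attack_rate[i]))
})
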