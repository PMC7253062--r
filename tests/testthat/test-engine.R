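# The per-timepoint pipeline: staging table, feeding competition, survival
# draws, movement bounds, clonal reproduction, and whole-run bookkeeping.

test_that("the staging table is applied exactly as specified", {
  g <- genotype(F1 = 4, F2 = 4)
  grid <- uniform_grid(5)

  st <- make_state(g, grid, c(L0, L1, L1, L1A, L1A, L2, L2, DAUER, DAUER, ADULT),
                   fed = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                           TRUE, FALSE, TRUE),
                   age = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 3),
                   starve = c(0, 0, 0, 2, 2, 0, 0, 5, 5, 0))
  out <- stage_step(st)
  expect_equal(out$stage,
               c(L1,      # L0 hatches
                 L2,      # fed L1 develops
                 L1A,     # starved L1 arrests
                 L2,      # fed arrested L1 resumes
                 L1A,     # starved arrested L1 stays (counter ticks)
                 ADULT,   # fed L2 matures
                 DAUER,   # starved L2 enters diapause
                 ADULT,   # fed dauer resumes as adult
                 DAUER,   # starved dauer stays
                 ADULT))  # adult stays adult
  expect_equal(out$age[c(6, 8)], c(0L, 0L))     # fresh adults start at age 0
  expect_equal(out$age[10], 4L)                 # existing adult aged one day
  expect_equal(out$starve[5], 3L)               # arrested counter incremented
  expect_equal(out$starve[9], 6L)
  expect_equal(out$dauer_entries, 1L)           # only the new dauer counts
  expect_true(out$dauer_ever[7])
})

test_that("arrested stages die when the starvation limit is reached", {
  g <- genotype(L1s_s = 6, L2s_s = 30)
  grid <- uniform_grid(5)
  st <- make_state(g, grid, c(L1A, DAUER), fed = FALSE, starve = c(5L, 29L))
  out <- stage_step(st)                          # 6th / 30th starved day
  expect_equal(length(out$stage), 0L)
  expect_equal(out$deaths[["l1_arrest_starvation"]], 1L)
  expect_equal(out$deaths[["dauer_starvation"]], 1L)

  st2 <- make_state(g, grid, c(L1A, DAUER), fed = FALSE, starve = c(4L, 28L))
  out2 <- stage_step(st2)                        # one day short of the limit
  expect_equal(length(out2$stage), 2L)
})

test_that("an individual entering dauer is counted exactly once, even after resuming", {
  g <- genotype()
  st <- make_state(g, uniform_grid(3, 2000), DAUER, fed = TRUE, starve = 10L)
  st$dauer_ever <- TRUE
  st$dauer_entries <- 1L
  out <- stage_step(st)                          # fed dauer resumes as adult
  expect_equal(out$stage, ADULT)
  expect_equal(out$dauer_entries, 1L)
  out$fed <- FALSE
  out2 <- stage_step(out)                        # starved adult stays adult
  expect_equal(out2$stage, ADULT)
  expect_equal(out2$dauer_entries, 1L)
})

test_that("feeding is all-or-nothing against the current cell content", {
  g <- genotype()
  st <- make_state(g, food_grid(matrix(1000, 3, 3)), ADULT, x = 2, y = 2)
  out <- feed_step(st)
  expect_true(out$fed)
  expect_equal(out$cells[2, 2], 0)
  expect_equal(out$consumed_adult, 1000)

  # two larvae compete for 75 units: exactly one 50-unit meal is served
  st2 <- make_state(g, food_grid(matrix(75, 1, 1)), c(L1, L1), x = 1, y = 1)
  set.seed(75)
  out2 <- feed_step(st2)
  expect_equal(sum(out2$fed), 1L)
  expect_equal(out2$cells[1, 1], 25)
  expect_equal(out2$consumed_larva, 50)

  # a starved adult removes nothing; a larva behind it can still feed
  st3 <- make_state(g, food_grid(matrix(999, 1, 1)), c(ADULT, L1), x = 1, y = 1)
  out3 <- feed_step(st3)
  expect_false(out3$fed[1])
  expect_true(out3$fed[2])
  expect_equal(out3$cells[1, 1], 949)
})

test_that("eggs demand nothing and arrested stages pay one larval meal to resume", {
  g <- genotype()
  st <- make_state(g, food_grid(matrix(0, 3, 3)), L0, x = 2, y = 2)
  out <- feed_step(st)
  expect_true(out$fed)                           # zero demand is satisfied
  expect_equal(sum(out$cells), 0)

  st2 <- make_state(g, food_grid(matrix(60, 1, 1)), c(L1A, DAUER), x = 1, y = 1)
  set.seed(76)
  out2 <- feed_step(st2)
  expect_equal(sum(out2$fed), 1L)                # 60 units buy one meal only
  expect_equal(out2$cells[1, 1], 10)
  expect_equal(out2$consumed_larva, 50)
})

test_that("survival draws respect stage-specific probabilities", {
  grid <- uniform_grid(5)
  # eggs always survive
  g0 <- genotype(m_larva = 1)
  st <- make_state(g0, grid, rep(L0, 200))
  set.seed(77)
  expect_equal(length(survival_step(st)$stage), 200L)
  # adults without aging never die of age
  st2 <- make_state(genotype(M2 = 1), grid, rep(ADULT, 500), age = 10L)
  expect_equal(length(survival_step(st2)$stage), 500L)
  # binomial check: 10,000 larvae at m_larva = 0.05
  st3 <- make_state(genotype(), grid, rep(L1, 10000))
  set.seed(78)
  out3 <- survival_step(st3)
  deaths <- 10000 - length(out3$stage)
  expect_lt(abs(deaths - 500), 3 * sqrt(10000 * 0.05 * 0.95))
  expect_equal(out3$deaths[["larva_mortality"]], deaths)
})

test_that("movement draws stay within per-axis range and grid bounds", {
  grid <- uniform_grid(20)
  g <- genotype(s_fed = 0.5, s_hungry = 0.9)
  st <- make_state(g, grid, rep(ADULT, 400), x = 10, y = 10, fed = TRUE)
  set.seed(79)
  out <- move_step(st)
  expect_true(all(abs(out$x - 10) <= 5))         # s = 0.5 means +/- 5 cells
  expect_true(all(abs(out$y - 10) <= 5))
  reached <- unique(cbind(out$x, out$y))
  expect_gt(nrow(reached), 20)                   # both axes actually move

  # a worm at the boundary whose draw would leave the grid is clamped to it
  st2 <- make_state(g, grid, rep(L1, 300), x = 20, y = 20, fed = FALSE)
  out2 <- move_step(st2)
  expect_true(all(out2$x >= 1 & out2$x <= 20 & out2$y >= 1 & out2$y <= 20))
  expect_true(any(out2$x == 20))                 # positive draws hit the wall

  # zero movement scale freezes positions
  st3 <- make_state(genotype(s_fed = 0, s_hungry = 0), grid, rep(L2, 50),
                    x = 7, y = 3)
  out3 <- move_step(st3)
  expect_true(all(out3$x == 7 & out3$y == 3))
})

test_that("adults spawn fecundity(age) eggs clonally at their own cell", {
  g <- genotype(F1 = 4, F2 = 4)
  st <- make_state(g, uniform_grid(9), ADULT, x = 5, y = 4, age = 0L)
  out <- reproduce_step(st)
  expect_equal(sum(out$stage == L0), 4L)
  expect_true(all(out$x[out$stage == L0] == 5))
  expect_true(all(out$y[out$stage == L0] == 4))
  expect_equal(out$births, st$births + 4L)

  st$age <- 1L                                   # day 2: schedule is exhausted
  expect_equal(sum(reproduce_step(st)$stage == L0), 0L)

  st_larva <- make_state(g, uniform_grid(9), L2)
  expect_equal(length(reproduce_step(st_larva)$stage), 1L)
})

test_that("a fixed seed reproduces a run bit-for-bit", {
  g <- genotype(F1 = 10, F2 = 10, M2 = 0.9, s_fed = 0.3)
  grid <- small_patch()
  r1 <- run_colony(g, grid, seed = 123)
  r2 <- run_colony(g, grid, seed = 123)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_colony(g, grid, seed = 124)
  expect_false(identical(r1$series, r3$series))
})

test_that("food is conserved and the birth/death ledger balances over a run", {
  r <- run_colony(genotype(F1 = 20, F2 = 20, M2 = 0.85, s_fed = 0.2),
                  small_patch(), seed = 31)
  s <- r$summary
  expect_lt(s$conservation_error, 1e-9)
  expect_equal(s$births - sum(s$deaths), s$pop_end)
  expect_equal(s$consumed_adult + s$consumed_larva + s$food_remaining,
               2e4, tolerance = 1e-6)
  expect_true(all(diff(r$series$cum_dauers) >= 0))
  expect_lte(s$peak_dauers, s$fitness)
  expect_gte(s$hatched, s$founders)
  expect_lte(s$hatched, s$births)
})

test_that("a founder on a foodless grid can never found a colony", {
  g <- genotype(m_larva = 0)                     # isolate starvation dynamics
  r <- run_colony(g, food_grid(matrix(0, 20, 20)), seed = 5)
  # with no feedable cell anywhere the dauer yield is provably frozen at 0
  # and the run ends immediately; the arrested founder's starvation death
  # itself is covered by the staging-table tests
  expect_equal(r$summary$termination, "food_exhausted")
  expect_equal(r$summary$t_end, 1L)
  expect_true(r$summary$null)
  expect_equal(r$summary$fitness, 0L)
  expect_equal(r$summary$pop_end, 1L)            # the arrested founder
})

test_that("a sterile founder matures, dies and leaves no colony", {
  g <- genotype(F1 = 0, M2 = 0.8, m_larva = 0)
  r <- run_colony(g, uniform_grid(20), seed = 8, t_max = 60)
  expect_equal(r$summary$fitness, 0L)
  expect_true(r$summary$null)
  expect_equal(r$summary$termination, "extinct")
})

test_that("without mortality or decline the colony follows the stage recurrence", {
  g <- genotype(F1 = 2, F2 = 0, M2 = 1, m_larva = 0, m_dauer = 0,
                s_fed = 0.9, s_hungry = 0.9)
  r <- run_colony(g, uniform_grid(30, 1e9), seed = 17, t_max = 5)
  # independent tally: L0 -> L1 -> L2 -> adult, everyone fed, 2 eggs/adult/day
  pop <- c(L0 = 0, L1 = 1, L2 = 0, adult = 0)
  oracle <- matrix(0, 5, 4, dimnames = list(NULL, names(pop)))
  for (t in 1:5) {
    pop <- c(L0 = 0, L1 = unname(pop["L0"]), L2 = unname(pop["L1"]),
             adult = unname(pop["adult"] + pop["L2"]))
    pop["L0"] <- 2 * pop["adult"]
    oracle[t, ] <- pop
  }
  got <- r$series[, c("n_L0", "n_L1", "n_L2", "n_adult")]
  expect_equal(unname(as.matrix(got)), unname(oracle))
  expect_true(r$summary$truncated)
})

test_that("a colony on ample food produces a dauer boom when the patch runs out", {
  # reduced-scale analogue of the reference demonstration run
  r <- run_colony(genotype(F1 = 50, F2 = 0, M2 = 0.99, s_fed = 0.9),
                  small_patch(), seed = 21)
  expect_gt(r$summary$fitness, 100)
  expect_equal(r$summary$termination, "food_exhausted")
  expect_false(r$summary$null)
})
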