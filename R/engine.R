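# The per-timepoint simulation pipeline. A colony state holds the food grid
# plus parallel per-individual vectors (structure-of-arrays rather than one
# object per worm: populations reach 1e5-1e6 individuals). Every timepoint
# applies, to the whole population in strict order:
#   feed -> stage -> survive -> move -> reproduce
# Within the feed step individuals compete for cell food in a seeded random
# order; all other steps are order-free and vectorised.

#' Initialise a colony on a food grid
#'
#' Creates a colony state with `founders` L1 larvae placed at the centre of
#' the grid (or at explicit positions), a zeroed clock and empty counters.
#'
#' @param g a [genotype()].
#' @param grid a [food_grid()]; modified copies live inside the state.
#' @param founders number of founding L1 larvae (`>= 1`).
#' @param positions optional 2-column matrix (x, y) of founder positions;
#'   defaults to the centre cell for every founder.
#' @return An object of class `"colony_state"`.
#' @seealso [run_colony()] drives a state to termination; [feed_step()] and
#'   friends advance it one sub-step at a time.
#' @export
new_colony <- function(g, grid, founders = 1, positions = NULL) {
  stopifnot(inherits(g, "genotype"), inherits(grid, "food_grid"))
  if (founders < 1) stop("founders must be >= 1")
  if (is.null(positions)) {
    cx <- max(1L, round(grid$width / 2))
    cy <- max(1L, round(grid$height / 2))
    positions <- cbind(rep(cx, founders), rep(cy, founders))
  }
  positions <- matrix(as.integer(positions), ncol = 2)
  if (nrow(positions) != founders) stop("positions must have one row per founder")
  if (any(positions[, 1] < 1 | positions[, 1] > grid$width |
          positions[, 2] < 1 | positions[, 2] > grid$height))
    stop("founder positions outside grid bounds")
  n <- as.integer(founders)
  state <- list(
    g = g,
    cells = grid$cells,
    width = grid$width, height = grid$height,
    initial_total = grid$initial_total,
    clock = 0L,
    stage = rep(ST_L1, n),
    age = integer(n),
    x = positions[, 1], y = positions[, 2],
    fed = logical(n),
    starve = integer(n),
    dauer_ever = logical(n),
    id = seq_len(n),
    next_id = n + 1L,
    founders = n,
    births = n,                      # founders included (ledger identity)
    hatched = n,                     # individuals that ever reached L1
    dauer_entries = 0L,
    peak_dauers = 0L,
    consumed_adult = 0,
    consumed_larva = 0,
    deaths = c(larva_mortality = 0L, dauer_mortality = 0L,
               adult_mortality = 0L, l1_arrest_starvation = 0L,
               dauer_starvation = 0L)
  )
  class(state) <- "colony_state"
  state
}

#' @export
print.colony_state <- function(x, ...) {
  counts <- tabulate(x$stage, length(STAGE_LEVELS))
  names(counts) <- STAGE_LEVELS
  cat(sprintf("<colony_state> t = %d, %d live individuals, %.0f food units left\n",
              x$clock, length(x$stage), sum(x$cells)))
  print(counts)
  invisible(x)
}

# drop individuals flagged in `gone` from all per-individual vectors
drop_individuals <- function(state, gone) {
  if (!any(gone)) return(state)
  keep <- !gone
  for (f in c("stage", "age", "x", "y", "fed", "starve", "dauer_ever", "id"))
    state[[f]] <- state[[f]][keep]
  state
}

# smallest per-meal demand any feeding-capable stage can ever have; used by
# the food-exhaustion termination test
min_feed_demand <- function(g) {
  sched <- g$consumption_schedule
  adult_min <- if (is.null(sched)) g$c_adult else {
    pos <- sched[sched > 0]
    if (length(pos)) g$c_adult * min(pos) else Inf
  }
  min(g$c_larva, adult_min)
}

#' Feeding step
#'
#' Every live individual competes for the food in its cell in a seeded
#' random order. All larval stages — L1, L2 and the arrested stages
#' (L1_arrested, dauer) — demand `c_larva`; adults demand
#' [consumption_at()] their age. Meals are all-or-nothing: a starved
#' individual removes nothing (so a cheaper consumer behind it can still
#' feed), a fed one removes exactly its demand. A fed arrested larva or
#' dauer therefore pays one larval meal for resuming development, which
#' keeps the food ledger honest: every dauer ever produced has consumed at
#' least one meal on its way through L2. Eggs (L0) demand nothing and are
#' trivially flagged fed.
#'
#' @param state a [new_colony()] state.
#' @return The state with `fed` flags set, cell food decremented and the
#'   adult/larva consumption ledgers updated.
#' @export
feed_step <- function(state) {
  n <- length(state$stage)
  state$fed <- logical(n)
  if (n == 0L) return(state)
  st <- state$stage
  g <- state$g
  # eggs demand nothing; a zero-demand meal is trivially satisfied, so they
  # carry a fed flag (hence move at the fed speed on the day they hatch)
  state$fed[st == ST_L0] <- TRUE
  part <- st != ST_L0
  if (!any(part)) return(state)
  idx <- which(part)
  sti <- st[idx]
  need <- numeric(length(idx))
  take <- numeric(length(idx))
  larv <- sti != ST_ADULT          # L1, L1_arrested, L2, dauer feed as larvae
  need[larv] <- g$c_larva
  take[larv] <- g$c_larva
  ad <- sti == ST_ADULT
  if (any(ad)) {
    dem <- consumption_at(g, state$age[idx][ad])
    need[ad] <- dem
    take[ad] <- dem
  }
  cell <- (state$x[idx] - 1L) * state$height + state$y[idx]
  ord <- sample.int(length(idx))
  res <- resolve_feeding(ord, cell, need, take, state$cells)
  state$cells <- res$food
  fed <- res$fed
  state$fed[idx] <- fed
  state$consumed_adult <- state$consumed_adult + sum(take[ad & fed])
  state$consumed_larva <- state$consumed_larva + sum(take[larv & fed])
  state
}

#' Staging step
#'
#' Applies the stage-transition table to every live individual exactly once,
#' using the fed flags set by [feed_step()]:
#' L0 -> L1; L1 fed -> L2, starved -> L1_arrested; L1_arrested fed -> L2,
#' starved -> stays (consecutive starved days counted, death at `L1s_s`);
#' L2 fed -> adult (age 0), starved -> dauer; dauer fed -> adult (age 0),
#' starved -> stays (death at `L2s_s`); adults age by one day. Entering
#' dauer increments the cumulative dauer counter once per individual.
#'
#' @inheritParams feed_step
#' @export
stage_step <- function(state) {
  n <- length(state$stage)
  if (n == 0L) return(state)
  st <- state$stage
  fed <- state$fed
  g <- state$g
  new_st <- st
  age <- state$age
  starve <- state$starve
  dead <- logical(n)

  old_adult <- st == ST_ADULT
  age[old_adult] <- age[old_adult] + 1L

  eggs <- st == ST_L0
  new_st[eggs] <- ST_L1
  state$hatched <- state$hatched + sum(eggs)

  i <- st == ST_L1
  new_st[i & fed] <- ST_L2
  j <- i & !fed
  new_st[j] <- ST_L1A
  starve[j] <- 1L

  i <- st == ST_L1A
  j <- i & fed
  new_st[j] <- ST_L2
  starve[j] <- 0L
  j <- i & !fed
  starve[j] <- starve[j] + 1L
  died <- j & starve >= g$L1s_s
  dead[died] <- TRUE
  state$deaths[["l1_arrest_starvation"]] <-
    state$deaths[["l1_arrest_starvation"]] + sum(died)

  i <- st == ST_L2
  j <- i & fed
  new_st[j] <- ST_ADULT
  age[j] <- 0L
  j <- i & !fed
  new_st[j] <- ST_DAUER
  starve[j] <- 1L
  state$dauer_entries <- state$dauer_entries + sum(j)
  state$dauer_ever[j] <- TRUE

  i <- st == ST_DAUER
  j <- i & fed
  new_st[j] <- ST_ADULT
  age[j] <- 0L
  starve[j] <- 0L
  j <- i & !fed
  starve[j] <- starve[j] + 1L
  died <- j & starve >= g$L2s_s
  dead[died] <- TRUE
  state$deaths[["dauer_starvation"]] <-
    state$deaths[["dauer_starvation"]] + sum(died)

  state$stage <- new_st
  state$age <- age
  state$starve <- starve
  state <- drop_individuals(state, dead)
  state$peak_dauers <- max(state$peak_dauers, sum(state$stage == ST_DAUER))
  state
}

#' Stochastic survival step
#'
#' One Bernoulli death draw per live individual: eggs (L0) always survive,
#' L1/L1_arrested/L2 die with `m_larva`, dauers with `m_dauer`, adults with
#' [p_death()] at their current age.
#'
#' @inheritParams feed_step
#' @export
survival_step <- function(state) {
  n <- length(state$stage)
  if (n == 0L) return(state)
  st <- state$stage
  g <- state$g
  p <- numeric(n)
  larv <- st == ST_L1 | st == ST_L1A | st == ST_L2
  p[larv] <- g$m_larva
  dau <- st == ST_DAUER
  p[dau] <- g$m_dauer
  ad <- st == ST_ADULT
  if (any(ad)) p[ad] <- p_death(g, state$age[ad])
  die <- runif(n) < p
  state$deaths[["larva_mortality"]] <- state$deaths[["larva_mortality"]] + sum(die & larv)
  state$deaths[["dauer_mortality"]] <- state$deaths[["dauer_mortality"]] + sum(die & dau)
  state$deaths[["adult_mortality"]] <- state$deaths[["adult_mortality"]] + sum(die & ad)
  drop_individuals(state, die)
}

#' Movement step
#'
#' Every individual except eggs takes an independent uniform integer step
#' per axis in `[-floor(10 s), +floor(10 s)]`, with `s = s_fed` when fed
#' and `s = s_hungry` when starved, clamped to the grid bounds (a worm
#' whose draw would leave the grid is placed on the boundary).
#'
#' @inheritParams feed_step
#' @export
move_step <- function(state) {
  n <- length(state$stage)
  if (n == 0L) return(state)
  mob <- state$stage != ST_L0
  if (!any(mob)) return(state)
  g <- state$g
  kf <- floor(10 * g$s_fed)
  kh <- floor(10 * g$s_hungry)
  k <- ifelse(state$fed[mob], kf, kh)
  m <- sum(mob)
  dx <- pmin(floor(runif(m) * (2 * k + 1)), 2 * k) - k
  dy <- pmin(floor(runif(m) * (2 * k + 1)), 2 * k) - k
  state$x[mob] <- pmin(pmax(state$x[mob] + as.integer(dx), 1L), state$width)
  state$y[mob] <- pmin(pmax(state$y[mob] + as.integer(dy), 1L), state$height)
  state
}

#' Reproduction step
#'
#' Each live adult lays [fecundity()] of its current age eggs (L0) at its
#' own cell; reproduction is clonal and does not require the adult to have
#' fed. Newly laid eggs are first processed at the next timepoint.
#'
#' @inheritParams feed_step
#' @export
reproduce_step <- function(state) {
  ad <- which(state$stage == ST_ADULT)
  if (length(ad) == 0L) return(state)
  counts <- fecundity(state$g, state$age[ad])
  tot <- sum(counts)
  if (tot == 0L) return(state)
  lay <- counts > 0L
  state$stage <- c(state$stage, rep(ST_L0, tot))
  state$age <- c(state$age, integer(tot))
  state$x <- c(state$x, rep(state$x[ad][lay], counts[lay]))
  state$y <- c(state$y, rep(state$y[ad][lay], counts[lay]))
  state$fed <- c(state$fed, logical(tot))
  state$starve <- c(state$starve, integer(tot))
  state$dauer_ever <- c(state$dauer_ever, logical(tot))
  state$id <- c(state$id, seq.int(state$next_id, length.out = tot))
  state$next_id <- state$next_id + tot
  state$births <- state$births + tot
  state
}

#' Advance a colony by one timepoint
#'
#' Applies feed, stage, survival, movement and reproduction in order and
#' increments the clock.
#'
#' @inheritParams feed_step
#' @export
advance_timepoint <- function(state) {
  state <- feed_step(state)
  state <- stage_step(state)
  state <- survival_step(state)
  state <- move_step(state)
  state <- reproduce_step(state)
  state$clock <- state$clock + 1L
  state
}

# Decide whether the run is over. Returns NULL (continue) or a reason string.
#
# "food_exhausted" fires as soon as no cell holds enough food for any
# feeding-capable stage AND no L2 is alive: from that point no individual or
# future descendant can ever be flagged fed, so no further L2 -> dauer entry
# can occur and the cumulative dauer count and food ledgers are final.
termination_reason <- function(state, t_max) {
  n <- length(state$stage)
  if (n == 0L) return("extinct")
  if (state$clock >= t_max) return("t_max")
  if (max(state$cells) < min_feed_demand(state$g) &&
      !any(state$stage == ST_L2)) return("food_exhausted")
  NULL
}

#' Run one colony to termination
#'
#' Places founders on the patch and iterates
#' feed -> stage -> survive -> move -> reproduce once per timepoint until
#' the population is extinct, the patch can no longer feed anything (at
#' which point the dauer yield is provably final), or `t_max` is reached
#' (recorded as truncation). Colony fitness is the cumulative number of
#' individuals that ever entered the dauer stage.
#'
#' A run is flagged *null* when the colony died out before any reproduction
#' (typically stochastic death of the founding larva); null runs are
#' excluded from mean-fitness aggregation by [run_sweep()].
#'
#' @inheritParams new_colony
#' @param grid a [food_grid()]; defaults to the reference patch
#'   (`make_gaussian_patch(300, 300, 1e6, 5)`).
#' @param seed integer seed; all randomness in the run flows from it, and a
#'   fixed seed gives a bit-identical result.
#' @param t_max maximum number of timepoints.
#' @param record_series keep the per-timepoint series? (summary counters are
#'   always kept).
#' @return An object of class `"colony_run"`: a list with `series` (one row
#'   per timepoint: stage counts, cumulative dauers, food remaining and the
#'   adult/larva consumption ledgers), `summary` (fitness, null flag,
#'   termination reason, births, deaths by cause, peak dauers, seed) and the
#'   genotype.
#' @examples
#' g <- genotype(F1 = 4, F2 = 4, M2 = 0.9, s_fed = 0.1)
#' run <- run_colony(g, make_gaussian_patch(60, 60, 2e4, 5), seed = 1)
#' run$summary$fitness
#' @export
run_colony <- function(g, grid = NULL, founders = 1, positions = NULL,
                       seed = NULL, t_max = 100, record_series = TRUE) {
  stopifnot(inherits(g, "genotype"))
  if (is.null(grid)) grid <- make_gaussian_patch()
  if (!is.null(seed)) set.seed(seed)
  state <- new_colony(g, grid, founders = founders, positions = positions)
  nstage <- length(STAGE_LEVELS)
  if (record_series) {
    rows <- vector("list", t_max)
  }
  reason <- NULL
  while (is.null(reason)) {
    state <- advance_timepoint(state)
    if (record_series) {
      counts <- tabulate(state$stage, nstage)
      rows[[state$clock]] <- c(state$clock, counts, state$dauer_entries,
                               sum(state$cells), state$consumed_adult,
                               state$consumed_larva, state$births,
                               sum(state$deaths))
    }
    reason <- termination_reason(state, t_max)
  }
  series <- NULL
  if (record_series) {
    m <- do.call(rbind, rows[seq_len(state$clock)])
    series <- as.data.frame(m)
    names(series) <- c("timepoint", paste0("n_", STAGE_LEVELS),
                       "cum_dauers", "food_remaining",
                       "consumed_adult", "consumed_larva",
                       "births_cum", "deaths_cum")
  }
  remaining <- sum(state$cells)
  summary <- list(
    fitness = state$dauer_entries,
    peak_dauers = state$peak_dauers,
    null = (state$births - state$founders) == 0L,
    termination = reason,
    truncated = identical(reason, "t_max"),
    t_end = state$clock,
    births = state$births,
    hatched = state$hatched,
    founders = state$founders,
    deaths = state$deaths,
    pop_end = length(state$stage),
    food_remaining = remaining,
    consumed_adult = state$consumed_adult,
    consumed_larva = state$consumed_larva,
    conservation_error = abs(state$initial_total -
      (remaining + state$consumed_adult + state$consumed_larva)) /
      state$initial_total,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  structure(list(series = series, summary = summary, genotype = g,
                 final_state = state),
            class = "colony_run")
}

#' @export
print.colony_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<colony_run> %d timepoints (%s)%s\n", s$t_end, s$termination,
              if (s$null) " [null run]" else ""))
  cat(sprintf("  fitness (cumulative dauers): %d  (peak concurrent %d)\n",
              s$fitness, s$peak_dauers))
  cat(sprintf("  births: %d (incl. %d founder%s), deaths: %d, final population: %d\n",
              s$births, s$founders, if (s$founders > 1) "s" else "",
              sum(s$deaths), s$pop_end))
  cat(sprintf("  food: %.0f remaining; adults ate %.0f, larvae %.0f\n",
              s$food_remaining, s$consumed_adult, s$consumed_larva))
  invisible(x)
}
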