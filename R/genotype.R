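#' Define a model genotype
#'
#' A genotype bundles the eleven life-history parameters of the in silico
#' worm plus an optional age-dependent adult feeding schedule. Defaults are
#' the reference parameterization: no reproductive decline, slow aging,
#' maximal dispersal, adult meals of 1,000 food units per day and larval
#' meals of 50.
#'
#' Fecundity follows `F1 - F2 * age^2.5` (clipped at zero, floored to an
#' integer), with adult age 0 on the first day of adulthood, so `F1` is the
#' brood laid on adult day 1 and `F2` sets how fast fertility collapses.
#' Adult mortality is a daily Bernoulli death with
#' `p_death(age) = 1 - M2^(M1 + age)`; `M2 = 1` disables aging entirely.
#'
#' @param F1 progeny count on the first adult day (non-negative integer).
#' @param F2 fecundity decline coefficient (non-negative).
#' @param M1 mortality age offset (non-negative; 0.5 in all reference runs).
#' @param M2 daily survival base in (0, 1]; smaller values age faster.
#' @param m_larva daily death probability for L1, L1_arrested and L2.
#' @param m_dauer daily death probability for dauers.
#' @param s_fed movement scale when fed; a worm moves up to `floor(10*s)`
#'   cells per axis per day, so `s_fed = 0.1 ... 0.9` is 1-9 cells/day.
#' @param s_hungry movement scale when starved (default 0.9, i.e. 9 cells/day).
#' @param c_adult adult food consumption, units/day.
#' @param c_larva larval (L1, L2) food consumption, units/day.
#' @param L1s_s maximum consecutive days an L1_arrested survives without food.
#' @param L2s_s maximum consecutive days a dauer survives without food.
#' @param consumption_schedule optional numeric vector of fractions in
#'   `[0, 1]`, indexed by adult age starting at age 0; entry `a + 1` scales
#'   `c_adult` on adult age `a`. Ages beyond the last entry reuse the last
#'   entry. `NULL` means a constant full feeding rate at all ages.
#' @return An object of class `"genotype"` (a validated named list).
#' @examples
#' g <- genotype(F1 = 4, F2 = 4, M2 = 0.8)   # 4 progeny on day 1 only
#' fecundity(g, 0:3)
#' @seealso [fecundity()], [p_death()], [make_schedule()], [consumption_at()]
#' @export
genotype <- function(F1 = 50, F2 = 0, M1 = 0.5, M2 = 0.99,
                     m_larva = 0.05, m_dauer = 0.005,
                     s_fed = 0.9, s_hungry = 0.9,
                     c_adult = 1000, c_larva = 50,
                     L1s_s = 6, L2s_s = 30,
                     consumption_schedule = NULL) {
  g <- list(F1 = F1, F2 = F2, M1 = M1, M2 = M2,
            m_larva = m_larva, m_dauer = m_dauer,
            s_fed = s_fed, s_hungry = s_hungry,
            c_adult = c_adult, c_larva = c_larva,
            L1s_s = L1s_s, L2s_s = L2s_s,
            consumption_schedule = consumption_schedule)
  class(g) <- "genotype"
  validate_genotype(g)
}

validate_genotype <- function(g) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("F1", "F2", "M1", "M2", "m_larva", "m_dauer", "s_fed",
               "s_hungry", "c_adult", "c_larva", "L1s_s", "L2s_s")) {
    if (!num1(g[[nm]])) stop("genotype parameter '", nm, "' must be a single finite number")
    if (g[[nm]] < 0) stop("genotype parameter '", nm, "' must be non-negative")
  }
  if (g$M2 <= 0 || g$M2 > 1) stop("M2 must lie in (0, 1]")
  if (g$m_larva > 1) stop("m_larva must lie in [0, 1]")
  if (g$m_dauer > 1) stop("m_dauer must lie in [0, 1]")
  if (g$F1 != floor(g$F1)) stop("F1 must be an integer count")
  sched <- g$consumption_schedule
  if (!is.null(sched)) {
    if (!is.numeric(sched) || length(sched) < 1L || anyNA(sched))
      stop("consumption_schedule must be a non-empty numeric vector")
    if (any(sched < 0 | sched > 1))
      stop("consumption_schedule values must lie in [0, 1]")
  }
  g
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>\n")
  cat(sprintf("  reproduction: F1 = %g, F2 = %g\n", x$F1, x$F2))
  cat(sprintf("  mortality:    M1 = %g, M2 = %g (larva %g, dauer %g)\n",
              x$M1, x$M2, x$m_larva, x$m_dauer))
  cat(sprintf("  movement:     fed %g cells/day, hungry %g cells/day\n",
              floor(10 * x$s_fed), floor(10 * x$s_hungry)))
  cat(sprintf("  consumption:  adult %g, larva %g units/day%s\n",
              x$c_adult, x$c_larva,
              if (is.null(x$consumption_schedule)) "" else " (age-scheduled)"))
  cat(sprintf("  arrest limits: L1 %g d, dauer %g d\n", x$L1s_s, x$L2s_s))
  invisible(x)
}

#' Age-specific progeny count
#'
#' Evaluates the fecundity law `max(0, floor(F1 - F2 * age^2.5))` at one or
#' more adult ages. Age 0 is the first adult day, so `fecundity(g, 0) == F1`.
#' With `F2 = 0` there is no reproductive decline.
#'
#' @param g a [genotype()].
#' @param age adult age(s) in days, starting at 0; non-negative.
#' @return Integer vector of progeny counts, same length as `age`.
#' @export
fecundity <- function(g, age) {
  stopifnot(inherits(g, "genotype"))
  if (any(age < 0)) stop("age must be non-negative")
  as.integer(pmax(0, floor(g$F1 - g$F2 * age^2.5)))
}

#' Daily probability of adult death
#'
#' `p_death(age) = 1 - M2^(M1 + age)`: non-decreasing in age for `M2 < 1`
#' and identically 0 when `M2 = 1` (no aging).
#'
#' @inheritParams fecundity
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
p_death <- function(g, age) {
  stopifnot(inherits(g, "genotype"))
  if (any(age < 0)) stop("age must be non-negative")
  1 - g$M2^(g$M1 + age)
}

#' Probability an adult survives its first t death draws
#'
#' Closed form for the product of per-day survival probabilities
#' `M2^(M1 + a)` over ages `a = 0 .. t-1`:
#' `S(t) = M2^(t*M1 + t*(t-1)/2)`. `S(0) = 1`.
#'
#' @inheritParams fecundity
#' @param t number of daily death draws survived (vectorised, `t >= 0`).
#' @export
survival_curve <- function(g, t) {
  stopifnot(inherits(g, "genotype"))
  if (any(t < 0)) stop("t must be non-negative")
  g$M2^(t * g$M1 + t * (t - 1) / 2)
}

#' Encode a curtailed reproductive schedule as (F1, F2)
#'
#' Returns the `(F1, F2)` pair for which fecundity equals `F1` on the first
#' adult day and is exactly zero at every adult age at or beyond `span` days:
#' `F2 = F1 / span^2.5` (or `F2 = 0` for an unbounded span). `span = 1`
#' yields reproduction on day 1 only.
#'
#' @param F1 progeny count on the first adult day.
#' @param span reproductive span in days (`>= 1`), or `Inf` / `"unbounded"`
#'   for no reproductive decline.
#' @return Named list with elements `F1` and `F2`.
#' @examples
#' make_schedule(30, 10)   # 30 progeny tapering off over 10 days
#' make_schedule(4, 1)     # 4 progeny on day 1 only
#' @export
make_schedule <- function(F1, span) {
  if (identical(span, "unbounded")) span <- Inf
  if (!is.numeric(span) || length(span) != 1L || span < 1)
    stop("span must be a single number >= 1, or \"unbounded\"")
  F2 <- if (is.infinite(span)) 0 else F1 / span^2.5
  list(F1 = F1, F2 = F2)
}

#' Food units demanded by an adult of a given age
#'
#' `c_adult` scaled by the genotype's consumption schedule (constant 1 when
#' no schedule is set). Adult age 0 is day 1 of adulthood; ages beyond the
#' end of the schedule reuse its last entry.
#'
#' @inheritParams fecundity
#' @return Numeric vector of food demands (units/day).
#' @export
consumption_at <- function(g, age) {
  stopifnot(inherits(g, "genotype"))
  if (any(age < 0)) stop("age must be non-negative")
  sched <- g$consumption_schedule
  if (is.null(sched)) return(rep_len(g$c_adult, length(age)))
  idx <- pmin(floor(age) + 1, length(sched))
  g$c_adult * sched[idx]
}

#' Precipitous feeding-decline schedule
#'
#' Adult feeding at the full rate on days 1 and 2 of adulthood and zero from
#' day 3 onwards, modelling an abrupt maturational shut-off of pharyngeal
#' pumping rather than a gradual senescent decline.
#'
#' @return A consumption-schedule vector usable as
#'   `genotype(consumption_schedule = precipitous_schedule())`.
#' @export
precipitous_schedule <- function() c(1, 1, 0)
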