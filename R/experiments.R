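# Scenario definitions and the replicated lifespan x dispersal sweep
# harness. A scenario is a genotype template plus the grids of swept values
# (aging rates M2, dispersal speeds in cells/day), patch settings, founder
# count and replicate bookkeeping. Per-run seeds are derived from the base
# seed and the (M2, dispersal, replicate) indices, so replicates are
# independent, parallelisable and reproducible.

#' Define a sweep scenario
#'
#' @param g genotype template; `M2` and `s_fed` are overwritten per cell.
#' @param M2_grid aging rates to sweep (default the five reference rates,
#'   mean lifespans ~12 down to ~2.4 days).
#' @param dispersal_grid fed dispersal speeds in cells/day (1-9; the
#'   movement scale is `s_fed = dispersal / 10`).
#' @param replicates repeat simulations per combination.
#' @param base_seed integer; per-run seeds are mixed from it.
#' @param grid a [food_grid()], or a list of arguments for
#'   [make_gaussian_patch()] (e.g. `list(total_food = 5e6)`).
#' @param founders founding L1 larvae per run.
#' @param t_max timepoint cap per run.
#' @param name optional label.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(g = genotype(),
                     M2_grid = c(0.99, 0.95, 0.90, 0.85, 0.80),
                     dispersal_grid = 1:9,
                     replicates = 100,
                     base_seed = 1,
                     grid = NULL,
                     founders = 1,
                     t_max = 100,
                     name = NULL) {
  stopifnot(inherits(g, "genotype"))
  if (length(M2_grid) < 1 || length(dispersal_grid) < 1)
    stop("sweep grids must be non-empty")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(grid)) grid <- make_gaussian_patch()
  if (is.list(grid) && !inherits(grid, "food_grid"))
    grid <- do.call(make_gaussian_patch, grid)
  structure(list(g = g, M2_grid = M2_grid, dispersal_grid = dispersal_grid,
                 replicates = replicates, base_seed = base_seed,
                 grid = grid, founders = founders, t_max = t_max,
                 name = name),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario>%s %d aging rates x %d dispersal speeds x %d replicates (%d runs)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "':"),
              length(x$M2_grid), length(x$dispersal_grid), x$replicates,
              length(x$M2_grid) * length(x$dispersal_grid) * x$replicates))
  invisible(x)
}

# Deterministic seed mixing: repeated (h * 69069 + k) mod (2^31 - 1) keeps
# everything in exact double arithmetic and below .Machine$integer.max.
mix_seed <- function(base, ...) {
  h <- as.numeric(base) %% 2147483647
  for (k in c(...)) h <- (h * 69069 + as.numeric(k)) %% 2147483647
  as.integer(h) + 1L
}

#' Run a replicated lifespan-by-dispersal sweep
#'
#' Runs `replicates` independent colonies for every (M2, dispersal)
#' combination of the scenario and aggregates colony fitness (cumulative
#' dauer yield). Mean fitness is computed over non-null replicates only
#' (runs where the founder died before any reproduction are excluded, and
#' counted); a cell whose replicates were all null carries `NA` fitness and
#' is flagged.
#'
#' @param sc a [scenario()].
#' @param replicates optional override of the scenario's replicate count
#'   (e.g. a reduced fast mode).
#' @param cores run replicates in parallel via `parallel::mclapply`; results
#'   are identical to the serial ones because every run derives its own seed.
#' @return An object of class `"sweep_result"`: list with `runs` (one row
#'   per run: M2, dispersal, replicate, seed, fitness, null flag, births,
#'   dauer entries, food ledgers, end time) and `cells` (per-combination
#'   mean/SD fitness over non-null runs, null counts, mean food shares,
#'   mean dauer fraction), plus the scenario.
#' @export
run_sweep <- function(sc, replicates = NULL, cores = 1) {
  stopifnot(inherits(sc, "scenario"))
  reps <- if (is.null(replicates)) sc$replicates else replicates
  combos <- expand.grid(i_M2 = seq_along(sc$M2_grid),
                        j_disp = seq_along(sc$dispersal_grid),
                        rep = seq_len(reps))
  run_one <- function(k) {
    i <- combos$i_M2[k]; j <- combos$j_disp[k]; r <- combos$rep[k]
    gk <- sc$g
    gk$M2 <- sc$M2_grid[i]
    gk$s_fed <- sc$dispersal_grid[j] / 10
    seed <- mix_seed(sc$base_seed, i, j, r)
    res <- run_colony(gk, sc$grid, founders = sc$founders, seed = seed,
                      t_max = sc$t_max, record_series = FALSE)
    s <- res$summary
    data.frame(M2 = sc$M2_grid[i], dispersal = sc$dispersal_grid[j],
               replicate = r, seed = seed, fitness = s$fitness,
               peak_dauers = s$peak_dauers, null = s$null,
               truncated = s$truncated, births = s$births,
               hatched = s$hatched,
               dauer_entries = s$fitness, t_end = s$t_end,
               consumed_adult = s$consumed_adult,
               consumed_larva = s$consumed_larva)
  }
  ks <- seq_len(nrow(combos))
  rows <- if (cores > 1 && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(ks, run_one, mc.cores = cores)
  } else {
    lapply(ks, run_one)
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, cells = aggregate_sweep(runs), scenario = sc),
            class = "sweep_result")
}

# per-cell aggregation over non-null runs; exchangeable under replicate order
aggregate_sweep <- function(runs) {
  key <- interaction(runs$M2, runs$dispersal, drop = TRUE)
  agg <- lapply(split(runs, key), function(d) {
    ok <- !d$null
    tot_food <- d$consumed_adult + d$consumed_larva
    data.frame(
      M2 = d$M2[1], dispersal = d$dispersal[1],
      replicates = nrow(d),
      n_used = sum(ok), n_null = sum(!ok),
      mean_fitness = if (any(ok)) mean(d$fitness[ok]) else NA_real_,
      sd_fitness = if (sum(ok) > 1) stats::sd(d$fitness[ok]) else NA_real_,
      all_null = !any(ok),
      mean_adult_share = if (any(ok & tot_food > 0))
        mean((d$consumed_adult / tot_food)[ok & tot_food > 0]) else NA_real_,
      mean_dauer_fraction = if (any(ok))
        mean((d$dauer_entries / d$hatched)[ok]) else NA_real_
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$M2, out$dispersal), ]
  rownames(out) <- NULL
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  %d runs, %d null; best cell mean fitness %.0f\n",
              nrow(x$runs), sum(x$runs$null),
              suppressWarnings(max(x$cells$mean_fitness, na.rm = TRUE))))
  invisible(x)
}

#' Heatmap matrix of mean dauer yield
#'
#' Rows are aging rates (labelled by M2 and the analytic mean lifespan),
#' columns dispersal speeds in cells/day, values the per-cell mean fitness
#' over non-null replicates.
#'
#' @param sw a [run_sweep()] result.
#' @export
heatmap_matrix <- function(sw) {
  stopifnot(inherits(sw, "sweep_result"))
  sc <- sw$scenario
  M2s <- sort(unique(sw$cells$M2), decreasing = TRUE)
  ds <- sort(unique(sw$cells$dispersal))
  m <- matrix(NA_real_, length(M2s), length(ds),
              dimnames = list(
                sprintf("M2=%.2f (%.1f d)", M2s, vapply(M2s, function(v) {
                  gv <- sc$g; gv$M2 <- v
                  analytic_mean_lifespan(gv)
                }, numeric(1))),
                sprintf("disp=%d", ds)))
  for (r in seq_len(nrow(sw$cells))) {
    i <- match(sw$cells$M2[r], M2s)
    j <- match(sw$cells$dispersal[r], ds)
    m[i, j] <- sw$cells$mean_fitness[r]
  }
  m
}

#' @export
plot.sweep_result <- function(x, main = NULL, ...) {
  m <- heatmap_matrix(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "dispersal speed (cells/day)", ylab = "",
                  axes = FALSE, main = main)
  graphics::axis(1, seq_len(ncol(m)), sub("disp=", "", colnames(m)))
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1, cex.axis = 0.7)
  invisible(m)
}

#' Adult versus larval share of cumulative food consumption
#'
#' Per-timepoint proportions of all food consumed so far charged to adults
#' and to larvae. Shares sum to 1 once any food has been consumed; before
#' that they are `NA` (0/0 is undefined).
#'
#' @param run a [run_colony()] result with a recorded series.
#' @return Data frame with `timepoint`, `adult_share`, `larva_share`.
#' @export
food_share_series <- function(run) {
  stopifnot(inherits(run, "colony_run"))
  if (is.null(run$series)) stop("run was executed with record_series = FALSE")
  tot <- run$series$consumed_adult + run$series$consumed_larva
  data.frame(timepoint = run$series$timepoint,
             adult_share = ifelse(tot > 0, run$series$consumed_adult / tot, NA_real_),
             larva_share = ifelse(tot > 0, run$series$consumed_larva / tot, NA_real_))
}

#' Fraction of hatched individuals that ever reached the dauer stage
#'
#' Distinct individuals that entered dauer divided by all individuals that
#' ever hatched into L1 larvae (founders included). Eggs laid on the final
#' timepoint never hatch and are not animals, so they do not enter the
#' denominator.
#'
#' @param run a [run_colony()] result.
#' @return A proportion in `[0, 1]`.
#' @export
dauer_fraction <- function(run) {
  stopifnot(inherits(run, "colony_run"))
  if (run$summary$hatched == 0) return(NA_real_)
  run$summary$fitness / run$summary$hatched
}

#' Named scenario presets
#'
#' Reads the versioned preset file shipped with the package
#' (`inst/extdata/presets.yaml`) and returns the named list of preset
#' definitions. Use [preset()] to instantiate one as a [scenario()].
#'
#' @return Named list of preset definitions.
#' @export
scenario_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "wormcolony")
  yaml::read_yaml(path)
}

#' Instantiate a named preset scenario
#'
#' @param name preset name (see [scenario_presets()] for the list).
#' @param ... overrides passed on to [scenario()] (e.g. `replicates`,
#'   `base_seed`).
#' @return A [scenario()].
#' @export
preset <- function(name, ...) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; see scenario_presets() for choices")
  p <- presets[[name]]
  gargs <- p$genotype
  if (!is.null(gargs$schedule)) {
    sch <- make_schedule(gargs$schedule$F1, gargs$schedule$span)
    gargs$schedule <- NULL
    gargs$F1 <- sch$F1
    gargs$F2 <- sch$F2
  }
  if (identical(gargs$consumption_schedule, "precipitous"))
    gargs$consumption_schedule <- precipitous_schedule()
  g <- do.call(genotype, gargs)
  args <- list(g = g, name = name)
  for (f in c("M2_grid", "dispersal_grid", "replicates", "founders", "t_max"))
    if (!is.null(p[[f]])) args[[f]] <- p[[f]]
  if (!is.null(p$grid)) args$grid <- p$grid
  args <- utils::modifyList(args, list(...))
  do.call(scenario, args)
}
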