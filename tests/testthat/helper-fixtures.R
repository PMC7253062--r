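# Fixtures are built in code: small uniform grids for deterministic engine
# checks and a reduced Gaussian patch for fast whole-colony runs.

uniform_grid <- function(n = 20, value = 1e6) {
  food_grid(matrix(value, n, n))
}

small_patch <- function() {
  make_gaussian_patch(width = 60, height = 60, total_food = 2e4, sigma = 5)
}

# a colony state with hand-placed individuals (stages, positions, fed flags)
make_state <- function(g, grid, stage, x = NULL, y = NULL, fed = FALSE,
                       age = 0L, starve = 0L) {
  n <- length(stage)
  st <- new_colony(g, grid, founders = n)
  st$stage <- as.integer(stage)
  if (!is.null(x)) st$x <- as.integer(rep_len(x, n))
  if (!is.null(y)) st$y <- as.integer(rep_len(y, n))
  st$fed <- rep_len(fed, n)
  st$age <- as.integer(rep_len(age, n))
  st$starve <- as.integer(rep_len(starve, n))
  st
}

# stage codes (mirrors the package-internal coding, asserted in tests)
L0 <- 1L; L1 <- 2L; L1A <- 3L; L2 <- 4L; DAUER <- 5L; ADULT <- 6L
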