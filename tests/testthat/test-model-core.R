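# Elementary dynamics: initialization, movement, binding, cleavage,
# heparinase flux, cytokine release.

test_that("initialization builds the full lattice and seeded state", {
  cfg <- simulation_config(n_steps = 1)
  st <- init_simulation(cfg, 0)
  expect_identical(length(st$heparinase), 2601L)
  expect_true(all(st$heparinase >= 0 & st$heparinase <= cfg$heparinase_max))
  expect_identical(length(st$cells$x), 200L)
  expect_identical(st$cells$free_sites, st$cells$total_sites)
  expect_identical(unname(st$released), unname(cfg$initial_release))
  expect_identical(st$t, 0L)
  check_invariants(st)
})

test_that("zero-variance site distribution gives every cell the mean count", {
  st <- init_simulation(small_config(site_sd = 0, site_mean = 5), 0)
  expect_true(all(st$cells$total_sites == 5L))
})

test_that("identical (config, replicate) pairs give identical initial states", {
  cfg <- small_config()
  expect_identical(init_simulation(cfg, 3), init_simulation(cfg, 3))
  a <- init_simulation(cfg, 0); b <- init_simulation(cfg, 1)
  expect_false(identical(a$heparinase, b$heparinase))
})

test_that("free factors random-walk unit steps on the torus", {
  st <- init_simulation(small_config(initial_release = c(1L, 0L, 0L),
                                     n_cells = 0), 0)
  W <- st$config$grid_width; H <- st$config$grid_height
  n <- 10000L
  dx <- numeric(n); dy <- numeric(n)
  for (i in seq_len(n)) {
    x0 <- st$factors$x[1]; y0 <- st$factors$y[1]
    st <- move_growth_factor(st, 1)
    # minimum-image displacement on the torus
    dx[i] <- ((st$factors$x[1] - x0 + W / 2) %% W) - W / 2
    dy[i] <- ((st$factors$y[1] - y0 + H / 2) %% H) - H / 2
  }
  expect_true(all(st$factors$x >= 0 & st$factors$x < W))
  expect_true(all(st$factors$y >= 0 & st$factors$y < H))
  # fixed step length of one patch width
  expect_equal(sqrt(dx^2 + dy^2), rep(1, n), tolerance = 1e-9)
  # isotropy: mean displacement per axis ~ 0 within 3 standard errors
  expect_lt(abs(mean(dx)), 3 * sd(dx) / sqrt(n))
  expect_lt(abs(mean(dy)), 3 * sd(dy) / sqrt(n))
})

test_that("movement is a no-op for bound and cleaved factors and zero step length", {
  st <- bound_triplet_state(h = 0)
  before <- st$factors
  st2 <- move_growth_factor(st, 1)
  expect_identical(st2$factors, before)
  st3 <- init_simulation(small_config(initial_release = c(1L, 0L, 0L)), 0)
  st4 <- move_growth_factor(st3, 1, step_length = 0)
  expect_identical(st4$factors$x, st3$factors$x)
  expect_identical(st4$factors$y, st3$factors$y)
})

test_that("binding follows the attachment probability and decrements free sites", {
  mk <- function(p) {
    cfg <- simulation_config(grid_width = 1, grid_height = 1, n_cells = 1,
                             site_mean = 3, site_sd = 0, attach_prob = p,
                             initial_release = c(1L, 0L, 0L),
                             heparinase_init = 0, flux_prob = 0,
                             n_steps = 1, seed = 11)
    init_simulation(cfg, 0)
  }
  # attach_prob = 0: never binds, free_sites never changes
  st <- mk(0)
  for (i in 1:50) st <- attempt_binding(st, 1)
  expect_identical(st$factors$state[1], 1L)
  expect_identical(st$cells$free_sites, st$cells$total_sites)
  # attach_prob = 1 with free_sites = 3: binds, free sites become 2
  st <- mk(1)
  st <- attempt_binding(st, 1)
  expect_identical(st$factors$state[1], 2L)
  expect_identical(st$cells$free_sites, 2L)
  expect_identical(st$factors$cell[1], 1L)
  # bound factor sits at its cell
  expect_identical(st$factors$x[1], st$cells$x[1])
  # second attempt on a bound factor is a no-op
  expect_identical(attempt_binding(st, 1), st)
})

test_that("empirical bind rate matches the Bernoulli probability", {
  n <- 10000L
  cfg <- simulation_config(grid_width = 1, grid_height = 1, n_cells = 1,
                           site_mean = 5, site_sd = 0, attach_prob = 0.5,
                           initial_release = c(0L, 0L, 0L),
                           heparinase_init = 0, flux_prob = 0,
                           n_steps = 1, seed = 17)
  st <- init_simulation(cfg, 0)
  st$cells$total_sites <- st$cells$free_sites <- n  # ample sites
  st <- release_cytokines(st, c(n, 0L, 0L))
  set.seed(1)
  st <- hscompete:::bind_phase(st, seq_len(n))
  rate <- mean(st$factors$state == 2L)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n))
  # conservation after mass binding
  check_invariants(st)
})

test_that("binding is not attempted without an eligible co-located cell", {
  st <- init_simulation(small_config(n_cells = 0,
                                     initial_release = c(1L, 0L, 0L)), 0)
  st2 <- attempt_binding(st, 1)
  expect_identical(st2$factors$state[1], 1L)
})

test_that("cleavage respects the class thresholds and restores sites", {
  # theta_LA <= h < theta_MA: LA cleaved, MA and HA remain bound
  st <- bound_triplet_state(h = 0.3)
  for (id in 1:3) st <- cleave_bound_factor(st, id)
  expect_identical(st$factors$state, c(3L, 2L, 2L))
  expect_identical(st$cells$free_sites, 1L)
  check_invariants(st)
  # h = 0: nothing cleaved
  st <- bound_triplet_state(h = 0)
  for (id in 1:3) st <- cleave_bound_factor(st, id)
  expect_identical(st$factors$state, c(2L, 2L, 2L))
  # h >= theta_HA: all cleaved, each cleavage restores one site
  st <- bound_triplet_state(h = 0.9)
  for (id in 1:3) st <- cleave_bound_factor(st, id)
  expect_identical(st$factors$state, c(3L, 3L, 3L))
  expect_identical(st$cells$free_sites, st$cells$total_sites)
  check_invariants(st)
  # recycle fate returns the factor to the free pool
  st <- bound_triplet_state(h = 0.9, cleaved_fate = "recycle")
  for (id in 1:3) st <- cleave_bound_factor(st, id)
  expect_identical(st$factors$state, c(1L, 1L, 1L))
  # no-op on a free factor
  expect_identical(cleave_bound_factor(st, 1), st)
})

test_that("cleavage is monotone in affinity: cleaved classes are nested", {
  for (h in c(0, 0.1, 0.25, 0.4, 0.5, 0.6, 0.75, 0.9, 1)) {
    st <- bound_triplet_state(h = h)
    for (id in 1:3) st <- cleave_bound_factor(st, id)
    cleaved <- st$factors$state == 3L  # order LA, MA, HA
    # HA cleaved => MA cleaved => LA cleaved
    expect_true(!cleaved[3] || cleaved[2])
    expect_true(!cleaved[2] || cleaved[1])
  }
})

test_that("heparinase flux is clamped, optional, and symmetric in the long run", {
  st <- init_simulation(small_config(), 0)
  # flux_prob = 0: field identical before and after
  st0 <- st; st0$config$flux_prob <- 0
  expect_identical(update_heparinase(st0)$heparinase, st0$heparinase)
  # values always stay inside [0, heparinase_max]
  st1 <- st; st1$config$flux_prob <- 1; st1$config$flux_magnitude <- 5
  for (i in 1:20) {
    st1 <- update_heparinase(st1)
    expect_true(all(st1$heparinase >= 0 & st1$heparinase <= 1))
  }
  # single patch, flux every step: time average ~ heparinase_max / 2
  cfg <- simulation_config(grid_width = 1, grid_height = 1, n_cells = 0,
                           initial_release = 0L, flux_prob = 1,
                           flux_magnitude = 0.1, n_steps = 1, seed = 23)
  stp <- init_simulation(cfg, 0)
  n <- 40000L
  h <- numeric(n)
  for (i in seq_len(n)) {
    stp <- update_heparinase(stp)
    h[i] <- stp$heparinase
  }
  # batch-means standard error (the walk is autocorrelated)
  bm <- colMeans(matrix(h, nrow = 2000L))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(h) - 0.5), 3 * se)
})

test_that("cytokine release places factors uniformly and keeps the books", {
  st <- init_simulation(small_config(initial_release = 0L), 0)
  expect_identical(release_cytokines(st, c(0L, 0L, 0L)), st)
  expect_error(release_cytokines(st, c(-1L, 0L, 0L)), "non-negative")
  st2 <- release_cytokines(st, c(5L, 1L, 0L))
  expect_identical(unname(st2$released), c(5L, 1L, 0L))
  expect_identical(length(st2$factors$x), 6L)
  # 1x1 grid: every released factor lands in the single patch
  st3 <- init_simulation(simulation_config(grid_width = 1, grid_height = 1,
                                           n_cells = 0, initial_release = 20L,
                                           n_steps = 1), 0)
  expect_true(all(hscompete:::patch_index(st3$factors$x, st3$factors$y, 1) == 1L))
})
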