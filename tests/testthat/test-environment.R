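grid_with_elevations <- function(map, seed = 1) {
  g <- parse_map_text(map)
  set.seed(seed)
  g$elevation <- sample_elevation(g$geo)
  g
}

test_that("pollution diffusion conserves mass and never moves uphill", {
  g <- grid_with_elevations(tiny_coast_map())
  g2 <- diffuse_pollution(g, 0.2)
  expect_identical(g2$pollution, g$pollution)  # all-zero stays zero

  for (seed in 1:5) {
    set.seed(seed)
    g$pollution <- runif(g$n, 0, 2) * rbinom(g$n, 1, 0.5)
    out <- diffuse_pollution(g, 0.25, slr_in_m = 0.1)
    expect_equal(sum(out$pollution), sum(g$pollution), tolerance = 1e-12)
    expect_true(all(out$pollution >= 0))
  }

  # a polluted land cell in a pit: all neighbours higher, nothing moves
  pit <- parse_map_text(uniform_map("990000", 3, 3))
  pit$elevation <- rep(50, 9)
  pit$elevation[5] <- 20
  pit$pollution[5] <- 1.5
  out <- diffuse_pollution(pit, 0.25)
  expect_identical(out$pollution, pit$pollution)
  # lower the neighbours and it drains equally to all of them
  pit$elevation[-5] <- 10
  out <- diffuse_pollution(pit, 0.2)
  expect_equal(out$pollution[5], 1.5 * 0.8)
  expect_equal(out$pollution[-5], rep(1.5 * 0.2 / 8, 8))
})

test_that("coastline pollution moves as a whole to one coastline neighbour", {
  g <- grid_with_elevations(tiny_coast_map())
  coastline <- which(g$geo == 50)
  g$pollution[coastline[3]] <- 1.0
  set.seed(2)
  out <- diffuse_pollution(g, 0.25)
  expect_equal(sum(out$pollution), 1.0, tolerance = 1e-12)
  expect_equal(out$pollution[coastline[3]], 0.75)
  moved <- which(out$pollution > 0 & seq_len(g$n) != coastline[3])
  expect_length(moved, 1L)
  expect_true(g$geo[moved] == 50)
  expect_true(moved %in% g$nb[coastline[3], ])
})

test_that("sudden events respect interval, affect probability and cap", {
  g <- parse_map_text(uniform_map("990000", 10, 10))
  p <- coast_params(sudden_event_interval = 50,
                    patches_affected_sudden_event = 0,
                    enviro_deg_from_sudden_event = 1.0)
  glb <- coastsim:::new_globals()
  # interval not yet reached: nothing happens
  out <- trigger_sudden_event(g, glb, p, tick = 10)
  expect_identical(out$grid$degradation, g$degradation)
  expect_true(is.na(out$globals$last_event_tick))
  # interval reached but zero patch probability: event fires, no cell hit
  set.seed(1)
  out <- trigger_sudden_event(g, glb, p, tick = 50)
  expect_equal(out$globals$last_event_tick, 50)
  expect_true(all(out$grid$degradation == 0))
  # full severity caps degradation at 1 even on pre-degraded cells
  p2 <- coast_params(sudden_event_interval = 35,
                     patches_affected_sudden_event = 10,
                     enviro_deg_from_sudden_event = 1.0)
  g$degradation[] <- 0.6
  set.seed(2)
  out <- trigger_sudden_event(g, glb, p2, tick = 35)
  hit <- out$grid$degradation > 0.6
  expect_gt(sum(hit), 0)
  expect_true(all(out$grid$degradation[hit] == 1))
  expect_true(all(out$grid$event_age[hit] == 0))
})

test_that("degradation persists quietly, then spreads or clears at 1/3 each", {
  g <- parse_map_text(uniform_map("990000", 4, 4))
  g$degradation[] <- 0.5
  g$event_age[] <- 0
  out <- evolve_degradation(g, persistence = 5)
  expect_identical(out$degradation, g$degradation)  # too young to evolve
  expect_true(all(out$event_age == 1))

  # sparse degraded cells (3 cells apart) cannot re-contaminate each other
  # by spreading, so the cleared fraction among them is exactly 1/3
  big <- parse_map_text(uniform_map("990000", 300, 300))
  x <- (seq_len(big$n) - 1L) %% 300L
  y <- (seq_len(big$n) - 1L) %/% 300L
  marked <- which(x %% 3L == 0L & y %% 3L == 0L)
  big$degradation[marked] <- 0.5
  big$event_age[marked] <- 10
  set.seed(3)
  out <- evolve_degradation(big, persistence = 5)
  cleared <- sum(out$degradation[marked] == 0)
  expect_binomial(cleared, length(marked), 1 / 3)
  expect_true(all(out$degradation <= 1))
  # spread lands on Moore neighbours only
  newly <- setdiff(which(out$degradation > 0), marked)
  expect_true(all(vapply(newly, function(i) {
    any(big$nb[i, ] %in% marked, na.rm = TRUE)
  }, logical(1))))
})

test_that("sea level rises linearly or piecewise faster, and erodes land", {
  g <- parse_map_text("200000 500000")
  g$elevation <- c(-10, 0.5)
  p <- coast_params(SLR_increase = 35, linear_SLR = TRUE, erosion_loss = 0)
  glb <- coastsim:::new_globals()
  for (t in 1:35) {
    out <- advance_sea_level(g, glb, p, t)
    glb <- out$globals
  }
  expect_equal(glb$slr_in_m, 0.035, tolerance = 1e-9)

  # non-linear mode multiplies the per-tick rate from tick 200 onwards
  pn <- coast_params(SLR_increase = 35, linear_SLR = FALSE)
  g1 <- advance_sea_level(g, coastsim:::new_globals(), pn, 199)$globals
  g2 <- advance_sea_level(g, coastsim:::new_globals(), pn, 200)$globals
  g3 <- advance_sea_level(g, coastsim:::new_globals(), pn, 1200)$globals
  expect_equal(g2$slr_in_m / g1$slr_in_m, 1.25)
  expect_equal(g3$slr_in_m / g1$slr_in_m, 2.0)

  # inundation: land bordering sea below sea level + erosion converts
  glb <- coastsim:::new_globals()
  glb$slr_in_m <- 0.45
  pz <- coast_params(SLR_increase = 0, erosion_loss = 0.10)
  out <- advance_sea_level(g, glb, pz, 1)
  expect_equal(out$inundated, 2L)
  expect_equal(out$grid$geo[2], 20L)
  # a mangrove buffer of 0.2 m saves the same cell
  out2 <- advance_sea_level(g, glb, pz, 1, mangrove_cells = 2L)
  expect_length(out2$inundated, 0L)
  expect_equal(out2$grid$geo[2], 50L)
})

test_that("resource health follows pollution/degradation arithmetic", {
  g <- parse_map_text("200000 200000 200000")
  res <- list(kind = rep("fish", 3), health = c(0.5, 0.5, 0.5),
              cell = 1:3, alive = rep(TRUE, 3), mobile = rep(TRUE, 3))
  g$pollution <- c(0, 0.3, 0.05)
  g$degradation <- c(0, 0.2, 0)
  out <- update_env_resources(res, g, sensitivity = 0.5)
  expect_equal(out$health, c(0.51, 0.44, 0.50))
  # clamped at 1
  res$health <- c(0.995, 0.5, 0.5)
  out <- update_env_resources(res, g, sensitivity = 0.5)
  expect_equal(out$health[1], 1)
})

test_that("weak resources die half the time; strong ones rarely reproduce", {
  g <- parse_map_text("200000")
  g$pollution <- 0.05  # keeps health static below the death threshold
  n <- 20000
  res <- list(kind = rep("fish", 1), health = 0.24, cell = 1L,
              alive = TRUE, mobile = TRUE)
  set.seed(4)
  deaths <- sum(vapply(seq_len(n), function(i) {
    !update_env_resources(res, g, 0.5)$alive[1]
  }, logical(1)))
  expect_binomial(deaths, n, 0.5)

  clean <- parse_map_text("200000")
  parent <- list(kind = "fish", health = 0.96, cell = 1L, alive = TRUE,
                 mobile = TRUE)
  set.seed(5)
  births <- sum(vapply(seq_len(n), function(i) {
    length(update_env_resources(parent, clean, 0.5)$kind) > 1L
  }, logical(1)))
  expect_binomial(births, n, 0.01)
})

test_that("reproduction respects per-cell caps and resets healths", {
  g <- parse_map_text("200000")
  res <- list(kind = c("fish", "fish"), health = c(0.96, 0.96),
              cell = c(1L, 1L), alive = c(TRUE, TRUE), mobile = c(TRUE, TRUE))
  # cell already at the 2-fish cap: no offspring can ever appear
  set.seed(6)
  for (i in 1:2000) {
    out <- update_env_resources(res, g, 0.5)
    expect_length(out$kind, 2L)
  }
  # an uncrowded parent that reproduces resets both healths to 0.5
  solo <- list(kind = "fish", health = 0.96, cell = 1L, alive = TRUE,
               mobile = TRUE)
  set.seed(7)
  repeat {
    out <- update_env_resources(solo, g, 0.5)
    if (length(out$kind) == 2L) break
  }
  expect_equal(out$health, c(0.5, 0.5))
})

test_that("stressed mobile marine life relocates, preferring reef cells", {
  m <- map_from_tokens(matrix(c("200100", "200000", "200000", "990000"), 1))
  g <- parse_map_text(m)
  g$elevation <- sample_elevation(g$geo)
  res0 <- list(kind = c("coral", "fish"), health = c(0.5, 0.5),
               cell = c(1L, 2L), alive = c(TRUE, TRUE),
               mobile = c(FALSE, TRUE))
  # below sensitivity: nobody moves
  out <- move_marine_life(res0, g, sensitivity = 0.5)
  expect_identical(out$cell, res0$cell)
  # stress the fish's cell; the reef cell is ideal but (being stressed
  # itself) not an alternative, so it draws exactly the 95% branch
  g$pollution <- c(0.6, 0.9, 0, 0)
  g$degradation <- c(0.6, 0.9, 0, 0)
  set.seed(8)
  n <- 5000
  landed <- vapply(seq_len(n), function(i) {
    move_marine_life(res0, g, 0.5)$cell[2]
  }, integer(1))
  expect_binomial(sum(landed == 1L), n, 0.95)
  expect_true(all(landed %in% c(1L, 3L)))  # ideal reef or clean alternative
  # corals never move even under stress
  out <- move_marine_life(res0, g, 0.5)
  expect_equal(out$cell[1], 1L)
})

test_that("operator pollution balance maps to the piecewise raw effect", {
  expect_equal(pollution_effect_rate(At = 2, Nt = 2, Ae = 1, Ne = 1), 0)
  expect_equal(pollution_effect_rate(At = 6, Nt = 2, Ae = 1, Ne = 1), 2)
  expect_equal(pollution_effect_rate(At = 0, Nt = 3, Ae = 2, Ne = 1), -2)
  expect_equal(pollution_effect_rate(At = 3, Nt = 2, Ae = 1, Ne = 1), 0)
  # nearshore special cases
  expect_equal(pollution_effect_rate(4, 1, 0, 0, nearshore = TRUE), 3 / 2)
  expect_equal(pollution_effect_rate(4, 1, 1, 0, nearshore = TRUE), 0)  # 1-Ae
  expect_equal(pollution_effect_rate(3, 1, 2, 0, nearshore = TRUE), -0.5)
  expect_equal(pollution_effect_rate(4, 1, 2, 0, nearshore = TRUE), 0)  # At=2Ae
  expect_equal(pollution_effect_rate(1, 1, 1, 0, nearshore = TRUE), -0.5)
  expect_equal(pollution_effect_rate(0, 1, 2, 0, nearshore = TRUE), 0)

  # applied to a cell: positive effect adds, negative cleans half the time
  st <- make_state(seed = 1)
  i <- which(st$ops$alive & st$ops$type == "hotel")[1]
  st$ops$alive[] <- FALSE
  st$ops$alive[i] <- TRUE
  st$ops$alloc[i, ] <- c(0L, st$ops$needed[i, "t"] + 4L,
                         st$ops$needed[i, "e"], 0L)
  cell <- st$ops$loc[i]
  g2 <- update_operator_pollution(st$ops, st$grid, st$params)
  expect_equal(g2$pollution[cell],
               st$grid$pollution[cell] + st$params$pollution_change * 2)
})
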