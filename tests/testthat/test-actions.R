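test_that("the action budget follows the reserve rules", {
  # reserves >= 3: the reserves themselves
  expect_equal(compute_max_possible_contribution(9, c(2, 1, 1, 0),
                                                 c(2, 2, 1, 0), 1), 5)
  # 0 <= reserves < 3: 3
  expect_equal(compute_max_possible_contribution(5, c(2, 1, 1, 0),
                                                 c(2, 2, 1, 0), 1), 3)
  # negative reserves, resources cover needs: 3; otherwise 2
  expect_equal(compute_max_possible_contribution(5, c(3, 2, 1, 0),
                                                 c(2, 2, 1, 0), 1), 3)
  expect_equal(compute_max_possible_contribution(4, c(3, 2, 1, 0),
                                                 c(2, 2, 1, 0), 1), 2)
  # strong saving preference holds one unit back
  expect_equal(compute_max_possible_contribution(2, c(0, 1, 0, 0),
                                                 c(2, 2, 1, 0), 3), 2)
  # budget above resources collapses to zero
  expect_equal(compute_max_possible_contribution(2, c(1, 1, 0, 0),
                                                 c(2, 2, 1, 0), 1), 0)
})

test_that("vulnerability thresholds gate each event kind", {
  g <- parse_map_text("200000 500000")
  g$elevation <- c(-10, 0.5)
  p <- coast_params(pollution_threshold = 0.25,
                    acceptable_enviro_degradation = 0.25,
                    min_acceptable_elevation_above_SL = 0.4)
  expect_false(is_vulnerable(g, 2, "pollution", p))
  g$pollution[2] <- 0.3
  expect_true(is_vulnerable(g, 2, "pollution", p))
  expect_false(is_vulnerable(g, 2, "sudden_event", p))
  g$degradation[2] <- 0.3
  expect_true(is_vulnerable(g, 2, "sudden_event", p))
  # water cells are never SLR-vulnerable, however low
  expect_false(is_vulnerable(g, 1, "slr", p, slr_in_m = 5))
  # land: vulnerable iff the freeboard drops below the acceptable minimum
  expect_true(is_vulnerable(g, 2, "slr", p, slr_in_m = 0.2))   # 0.4 > 0.3
  expect_false(is_vulnerable(g, 2, "slr", p, slr_in_m = 0.05)) # 0.4 < 0.45
})

test_that("willingness combines affectedness, immobility and link balance", {
  st <- make_state(seed = 20, link_chance = 0, links_to_my_base = FALSE)
  hotel <- which(st$ops$alive & st$ops$type == "hotel")[1]
  cell <- st$ops$loc[hotel]
  far <- which(st$grid$geo == 10)[1]
  # unaffected operator, individual mode: never acts
  expect_equal(willingness(st, hotel, far, "pollution", "individual"), 0)
  # directly affected, individual, immobile hotel: 0.50 + 0.20
  expect_equal(willingness(st, hotel, cell, "pollution", "individual"), 0.7)
  dive <- which(st$ops$alive & st$ops$type == "dive")[1]
  st$ops$loc[dive] <- cell
  expect_equal(willingness(st, dive, cell, "pollution", "individual"), 0.5)
  # collaborative, balanced links (none at all): direct+immobile+tie = 1.05
  expect_equal(willingness(st, hotel, cell, "pollution", "collab"),
               0.40 + 0.20 + 0.45)
  # more positive than negative out-links adds 0.30 even when unaffected
  st$links[hotel, dive] <- 0.5
  expect_equal(willingness(st, hotel, far, "pollution", "collab"), 0.30)
  # more negative than positive: no term for the unaffected
  st$links[hotel, dive] <- -0.5
  expect_equal(willingness(st, hotel, far, "pollution", "collab"), 0)
  # indirectly affected via a neighbouring cell
  nb <- st$grid$nb[cell, ]
  nb <- nb[!is.na(nb)][1]
  expect_equal(willingness(st, hotel, nb, "pollution", "individual"),
               0.20 + 0.20)
  # water-based operators are indirectly affected through their base
  st$ops$loc[dive] <- which(st$grid$geo == 20)[1]
  base <- st$ops$base[dive]
  expect_equal(willingness(st, dive, base, "pollution", "individual"), 0.20)
})

test_that("contribution limits reproduce the eight-row table", {
  # excess rows: keyed by saving tendency and affectedness
  expect_equal(table13_limits(TRUE, TRUE, TRUE, TRUE, 5, 8), c(C1 = 4, C2 = 4))
  expect_equal(table13_limits(TRUE, TRUE, TRUE, FALSE, 5, 8),
               c(C1 = 2, C2 = 3))
  expect_equal(table13_limits(TRUE, TRUE, FALSE, TRUE, 5, 8),
               c(C1 = 5, C2 = 5))
  expect_equal(table13_limits(TRUE, TRUE, FALSE, FALSE, 5, 8),
               c(C1 = 2, C2 = 4))
  # no-excess rows: keyed by meeting needs and affectedness
  expect_equal(table13_limits(FALSE, TRUE, TRUE, TRUE, 0, 8),
               c(C1 = 3, C2 = 4))
  expect_equal(table13_limits(FALSE, TRUE, FALSE, FALSE, 0, 8),
               c(C1 = 2, C2 = 4))
  expect_equal(table13_limits(FALSE, FALSE, TRUE, TRUE, 0, 8),
               c(C1 = 2, C2 = 6))
  expect_equal(table13_limits(FALSE, FALSE, FALSE, FALSE, 0, 8),
               c(C1 = 1, C2 = 7))
  # negative results floor at zero
  expect_equal(table13_limits(TRUE, TRUE, TRUE, TRUE, 0, 0), c(C1 = 0, C2 = 0))
})

test_that("event costs price pollution by the chunk", {
  g <- parse_map_text("500000")
  g$pollution <- 0.35
  p <- coast_params(cost_pollution = 10, cost_SLR = 12,
                    cost_extreme_event = 9)
  expect_equal(event_cost(g, 1, "pollution", p), 35)
  expect_equal(event_cost(g, 1, "slr", p), 12)
  expect_equal(event_cost(g, 1, "sudden_event", p), 9)
})

test_that("a single collaborator can never fund a whole action", {
  st <- make_state(seed = 21)
  i <- which(st$ops$alive)[1]
  cell <- st$ops$loc[i]
  st$ops$resources[i] <- 100
  st$ops$maxc[i] <- 100
  st$ops$alloc[i, ] <- 0L
  caps <- contribution_caps(st, i, cell, "slr", "collab")
  expect_lte(caps$Cp, caps$Ce - 1)
  caps_i <- contribution_caps(st, i, cell, "slr", "individual")
  expect_lte(caps_i$Cp, caps_i$Ce)
})

test_that("link strength updates reproduce the learning table", {
  pos <- 0.10
  neg <- 0.20
  upd <- function(aff, ca, cb, action) {
    update_link_strength(0, aff, ca, cb, action, pos, neg)
  }
  # A affected
  expect_equal(upd(TRUE, 1, 2, TRUE), 0.25 * pos)
  expect_equal(upd(TRUE, 1, 2, FALSE), 1 * pos)
  expect_equal(upd(TRUE, 2, 1, TRUE), -1 * neg)
  expect_equal(upd(TRUE, 2, 1, FALSE), 0.5 * pos)
  expect_equal(upd(TRUE, 2, 0, TRUE), -2 * neg)
  expect_equal(upd(TRUE, 2, 0, FALSE), -0.5 * neg)
  expect_equal(upd(TRUE, 0, 0, TRUE), -1 * neg)
  expect_equal(upd(TRUE, 0, 0, FALSE), -0.5 * neg)
  # A not affected
  expect_equal(upd(FALSE, 1, 2, TRUE), 0.25 * pos)
  expect_equal(upd(FALSE, 1, 2, FALSE), 0.5 * pos)
  expect_equal(upd(FALSE, 2, 1, TRUE), -0.5 * neg)
  expect_equal(upd(FALSE, 2, 1, FALSE), 0.25 * pos)
  expect_equal(upd(FALSE, 2, 0, TRUE), -1 * neg)
  expect_equal(upd(FALSE, 2, 0, FALSE), -0.25 * neg)
  expect_equal(upd(FALSE, 0, 0, TRUE), -0.5 * neg)
  expect_equal(upd(FALSE, 0, 0, FALSE), -0.25 * neg)
  # clamped to [-1, 1]
  expect_equal(update_link_strength(0.99, TRUE, 1, 2, FALSE, 1e3, 0.1), 1)
  expect_equal(update_link_strength(-0.99, TRUE, 2, 0, TRUE, 0.1, 1e3), -1)
})

test_that("contributions drain unallocated resources, then savings, then units", {
  st <- make_state(seed = 22)
  i <- which(st$ops$alive)[1]
  st$ops$resources[i] <- 10
  st$ops$alloc[i, ] <- c(2L, 3L, 1L, 1L)  # unallocated: 3
  st$ops$maxc[i] <- 8
  out <- charge_contribution(st, i, 2)
  expect_equal(out$ops$alloc[i, ], st$ops$alloc[i, ])
  expect_equal(out$ops$resources[i], 8)
  expect_equal(out$ops$maxc[i], 6)

  # unallocated 1 + savings 2 cover an amount of 3
  st$ops$resources[i] <- 8
  st$ops$alloc[i, ] <- c(2L, 3L, 0L, 2L)
  out <- charge_contribution(st, i, 3)
  expect_equal(unname(out$ops$alloc[i, "s"]), 0)
  expect_equal(out$ops$alloc[i, c("m", "t", "e")],
               st$ops$alloc[i, c("m", "t", "e")])
  expect_equal(out$ops$resources[i], 5)

  # bookkeeping identity: allocation cuts + unallocated used = amount
  st$ops$resources[i] <- 7
  st$ops$alloc[i, ] <- c(2L, 3L, 1L, 1L)  # unallocated 0, savings too small
  set.seed(23)
  out <- charge_contribution(st, i, 4)
  cuts <- sum(st$ops$alloc[i, ] - out$ops$alloc[i, ])
  expect_equal(cuts, 4)
  expect_equal(out$ops$resources[i], 3)
  expect_error(charge_contribution(st, i, 100), "contract violation")
})

test_that("action effects remediate pollution, degradation and elevation", {
  st <- make_state(seed = 24, increased_elevation = 0.6)
  land <- which(st$grid$geo == 61)[1]
  st$grid$pollution[land] <- 1.0  # ten chunks
  set.seed(25)
  out <- apply_action_effect(st, land, "pollution")
  expect_lte(out$grid$pollution[land], 1.0)
  expect_equal(round(out$grid$pollution[land] / 0.1) * 0.1,
               out$grid$pollution[land], tolerance = 1e-9)

  # degradation resolves fully or not at all
  st$grid$degradation[land] <- 0.8
  res <- replicate(200, apply_action_effect(st, land,
                                            "sudden_event")$grid$degradation[land])
  expect_setequal(unique(res), c(0, 0.8))

  # SLR effect: elevation up, reinforced land, maintenance obligations up
  front <- which(st$grid$geo == 60)
  cell <- front[which.max(vapply(front, function(c) {
    sum(st$ops$alive & !st$ops$mobile & st$ops$loc == c)
  }, numeric(1)))]
  onit <- which(st$ops$alive & !st$ops$mobile & st$ops$loc == cell)[1]
  based <- which(st$ops$alive & st$ops$mobile & st$ops$base == cell)
  elev0 <- st$grid$elevation[cell]
  nm0 <- st$ops$needed[onit, "m"]
  out <- apply_action_effect(st, cell, "slr")
  expect_equal(out$grid$elevation[cell], elev0 + 0.6)
  expect_equal(out$grid$geo[cell], 59L)
  expect_equal(geo_value(out$grid$geo[cell]), 0.75)
  expect_equal(out$ops$needed[onit, "m"], nm0 + 2)
  expect_equal(out$ops$default[onit, "m"], st$ops$default[onit, "m"] + 2)
  if (length(based)) {
    expect_equal(out$ops$needed[based[1], "m"],
                 st$ops$needed[based[1], "m"] + 1)
  }
  nbs <- st$grid$nb[cell, ]
  nbs <- nbs[!is.na(nbs)]
  beach_nb <- nbs[st$grid$geo[nbs] %in% c(60, 61, 65, 66)]
  expect_equal(out$grid$pollution[beach_nb],
               st$grid$pollution[beach_nb] + 0.3)
})

test_that("collaboration needs a quorum, fills to the cost exactly, or breaks", {
  st0 <- make_state(seed = 26, cost_pollution = 1,
                    positive_association = 0.1, negative_association = 0.2)
  cell <- which(st0$grid$geo == 61)[1]
  iso <- isolate_two_ops(st0, cell, cell, resources = 10, maxc = 10)
  st <- iso$state
  a <- iso$ids[1]; b <- iso$ids[2]
  st$grid$pollution[cell] <- 0.3  # vulnerable; Ce = 3

  # both directly affected + immobile + balanced links: W = 1.05, certain
  set.seed(27)
  out <- resolve_collaborative(st, cell, "pollution")
  expect_equal(out$outcome, "action")
  spent <- (st$ops$resources[c(a, b)] - out$state$ops$resources[c(a, b)])
  expect_equal(sum(spent), 3)  # exactly Ce
  expect_true(all(spent >= 1))  # round-robin spreads the load
  expect_equal(out$state$globals$total_num_collaborations, 1L)
  # links were created and updated between the pair
  expect_false(is.na(out$state$links[a, b]))
  expect_false(is.na(out$state$links[b, a]))

  # cap the budgets below the cost: breakdown, nothing spent
  st$ops$maxc[c(a, b)] <- 1
  st$grid$pollution[cell] <- 0.5  # Ce = 5 > 1 + 1
  set.seed(28)
  out <- resolve_collaborative(st, cell, "pollution")
  expect_equal(out$outcome, "breakdown")
  expect_equal(out$state$ops$resources[c(a, b)], st$ops$resources[c(a, b)])
  # breakdown with both affected and contributing equally: strengths rise
  # by half the positive association
  expect_equal(out$state$links[a, b], 0.5 * 0.1)

  # a single willing operator is no quorum and leaves links untouched
  st$ops$alive[b] <- FALSE
  set.seed(29)
  out <- resolve_collaborative(st, cell, "pollution")
  expect_equal(out$outcome, "no_quorum")
  expect_true(all(is.na(out$state$links)))
})

test_that("individual action requires covering the whole cost", {
  st0 <- make_state(seed = 30, cost_extreme_event = 5)
  cell <- which(st0$grid$geo == 61)[2]
  iso <- isolate_two_ops(st0, cell, which(st0$grid$geo == 10)[1],
                         resources = 20, maxc = 4)
  st <- iso$state
  a <- iso$ids[1]
  st$grid$degradation[cell] <- 0.9  # vulnerable sudden-event site
  # budget Ce-1: the operator can never act alone
  set.seed(31)
  for (k in 1:50) {
    out <- resolve_individual(st, cell, "sudden_event")
    expect_equal(out$outcome, "none")
  }
  # budget at the cost: the (certainly willing) operator eventually acts
  st$ops$maxc[a] <- 5
  set.seed(32)
  acted <- FALSE
  for (k in 1:50) {
    out <- resolve_individual(st, cell, "sudden_event")
    if (out$outcome == "action") {
      acted <- TRUE
      break
    }
  }
  expect_true(acted)
  expect_equal(out$state$ops$maxc[a], 0)  # lowered by the contribution Ce
  expect_equal(out$state$ops$resources[a], 15)
  expect_equal(out$state$globals$total_num_indiv_actions, 1L)
})

test_that("frozen associations freeze link strengths over a whole run", {
  st <- make_state(seed = 5)
  st$params$positive_association <- 0
  st$params$negative_association <- 0
  for (k in 1:30) st <- coast_step(st)
  lm <- st$links
  expect_true(all(lm[!is.na(lm)] %in% c(-0.10, 0)))
})
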