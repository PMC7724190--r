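# Economy: budgeting, revenue settlement with penalties, maintenance-delay
# accounting, operator movement, bankruptcy.

#' Add or remove one allocation unit by weighted preference
#'
#' One unit is added (direction +1, categories below their maximum eligible)
#' or removed (direction -1, categories above zero eligible) from one of the
#' four allocation categories, chosen with probability proportional to the
#' corresponding weight via a cumulative-threshold draw. With no eligible
#' category the allocation is returned unchanged.
#'
#' @param alloc length-4 allocation vector (maintenance, tourism,
#'   environment, savings).
#' @param weights length-4 weight vector with entries in \{1, 2, 3\}.
#' @param direction +1 to add a unit, -1 to remove one.
#' @param upper length-4 vector of maximum allocations (required for +1).
#' @return The adjusted allocation vector.
#' @export
weighted_unit_adjust <- function(alloc, weights, direction, upper = NULL) {
  eligible <- if (direction > 0) {
    stopifnot(!is.null(upper))
    which(alloc < upper)
  } else {
    which(alloc > 0)
  }
  if (length(eligible) == 0L) return(alloc)
  w <- weights[eligible]
  u <- stats::runif(1) * sum(w)
  k <- eligible[which(u < cumsum(w))[1]]
  alloc[k] <- alloc[k] + direction
  alloc
}

#' Allocate an operator's resources over the four categories
#'
#' Starts from the operator's default allocations, then adds units by the
#' positive weights while resources exceed the total allocation (stopping
#' when every category is at its maximum), or removes units by the negative
#' weights while the total allocation exceeds the resources.
#'
#' @param resources available resource units.
#' @param defaults,maxes length-4 default and maximum allocation vectors.
#' @param wpos,wneg length-4 positive and negative weight vectors.
#' @return Length-4 allocation vector.
#' @export
allocate_resources <- function(resources, defaults, maxes, wpos, wneg) {
  alloc <- defaults
  while (resources > sum(alloc) && any(alloc < maxes)) {
    alloc <- weighted_unit_adjust(alloc, wpos, +1, upper = maxes)
  }
  while (sum(alloc) > resources && any(alloc > 0)) {
    alloc <- weighted_unit_adjust(alloc, wneg, -1)
  }
  alloc
}

#' Maintenance-delay penalty and update
#'
#' A penalty of min(\code{maintenance_penalty}, \code{needed_m}) is charged
#' iff the operator enters the step in severe delay (delay > 1). The delay
#' then grows by the maintenance shortfall, shrinks by 0.5 when maintenance
#' was over-allocated, and is clamped to \[0, 2\].
#'
#' @param delay current delayed-maintenance level in \[0, 2\].
#' @param alloc_m,needed_m allocated and needed maintenance units.
#' @param maintenance_penalty penalty parameter in \[0, 3\].
#' @return \code{list(penalty, delay)}.
#' @export
update_maintenance_delay <- function(delay, alloc_m, needed_m,
                                     maintenance_penalty) {
  penalty <- if (delay > 1) min(maintenance_penalty, needed_m) else 0
  if (alloc_m < needed_m) {
    delay <- delay + (needed_m - alloc_m)
  } else if (alloc_m > needed_m) {
    delay <- delay - 0.5
  }
  list(penalty = penalty, delay = clamp(delay, 0, 2))
}

#' Revenue components of an operator
#'
#' Computes tourism income T (optionally capped when revenues are limited),
#' the pollution penalty P (own-cell term plus neighbourhood term, each
#' rounded before summing; the neighbourhood average is taken over the
#' neighbours polluted above 0.25 when they outnumber the threshold, else
#' over all neighbours), the degradation penalty E, and the location penalty
#' L (dive/boat: barren cell; hotel/beach: sub-par beach and/or fewer than
#' two coastline neighbours).
#'
#' @param state model state.
#' @param i operator index.
#' @return \code{list(T, P, E, L)}.
#' @export
revenue_terms <- function(state, i) {
  ops <- state$ops; grid <- state$grid; params <- state$params
  At <- unname(ops$alloc[i, "t"]); Nt <- unname(ops$needed[i, "t"])
  Tv <- if (params$revenue_limited && At > Nt + 1) {
    (Nt + 1) * params$tourism_returns +
      (At - Nt - 1) * (params$tourism_returns - 1)
  } else {
    At * params$tourism_returns
  }
  cell <- ops$loc[i]
  nbs <- grid$nb[cell, ]
  nbs <- nbs[!is.na(nbs)]
  pnb <- grid$pollution[nbs]
  hot <- pnb > 0.25
  avg <- if (sum(hot) > params$neighbor_pollution_threshold) {
    mean(pnb[hot])
  } else {
    mean(pnb)
  }
  P <- round_half_up(grid$pollution[cell] * params$pollution_penalty) +
    round_half_up(avg * params$neighbor_pollution_penalty)
  E <- if (grid$degradation[cell] > 0) {
    params$enviro_degradation_income_penalty
  } else 0
  L <- 0
  ty <- ops$type[i]
  if (ty %in% c("dive", "boat")) {
    res <- state$res
    barren <- !any(res$alive & res$cell == cell &
                   res$kind %in% c("coral", "turtle", "fish"))
    if (barren) L <- 1
  } else if (ty %in% c("hotel", "beach")) {
    if (grid$geo[cell] %in% c(65L, 66L)) L <- L + 1
    if (sum(grid$geo[nbs] == 50L) < 2L) L <- L + 1
  }
  list(T = Tv, P = P, E = E, L = L)
}

#' Settle one operator's expenditures and revenue
#'
#' Deducts the maintenance, tourism and environment allocations (savings are
#' retained as resources), charges the maintenance-delay penalty and updates
#' the delay, then books round(resources + T - P - E - L).
#'
#' @param state model state.
#' @param i operator index.
#' @return The updated state.
#' @export
settle_revenue <- function(state, i) {
  ops <- state$ops
  r <- ops$resources[i] - sum(ops$alloc[i, c("m", "t", "e")])
  md <- update_maintenance_delay(ops$delay[i], ops$alloc[i, "m"],
                                 ops$needed[i, "m"],
                                 state$params$maintenance_penalty)
  r <- r - md$penalty
  ops$delay[i] <- md$delay
  terms <- revenue_terms(state, i)
  ops$resources[i] <- round_half_up(r + terms$T - terms$P - terms$E - terms$L)
  state$ops <- ops
  state
}

settle_all_revenues <- function(state) {
  idx <- which(state$ops$alive)
  for (i in idx[shuffled(length(idx))]) state <- settle_revenue(state, i)
  state
}

.MOVE_GEO <- list(dive = 20L, boat = c(20L, 40L), nearshore = 40L)

#' Move mobile operators towards attractive water cells
#'
#' Each mobile operator prunes its site memory to cells within 0.10 of its
#' current attractiveness, adds the type-admissible cells at least as
#' attractive as its current cell, and picks uniformly from the result (the
#' current cell is always included, so staying put is possible).
#'
#' @param state model state.
#' @return The updated state.
#' @export
move_operators <- function(state) {
  grid <- state$grid
  ops <- state$ops
  att <- grid$attractiveness
  idx <- which(ops$alive & ops$mobile)
  for (i in idx[shuffled(length(idx))]) {
    allowed <- .MOVE_GEO[[ops$type[i]]]
    cur <- ops$loc[i]
    cand <- which(grid$geo %in% allowed & att >= att[cur])
    sites <- ops$sites[[i]]
    sites <- sites[grid$geo[sites] %in% allowed &
                   att[sites] >= att[cur] - 0.10]
    sites <- unique(c(sites, cand, cur))
    ops$loc[i] <- pick_one(sites)
    ops$sites[[i]] <- sites
  }
  state$ops <- ops
  state
}

#' Remove bankrupt operators
#'
#' Operators with zero or negative resources leave the simulation; their
#' links are destroyed and bankruptcy bookkeeping is updated.
#'
#' @param state model state.
#' @return The updated state.
#' @export
remove_bankrupt <- function(state) {
  gone <- which(state$ops$alive & state$ops$resources <= 0)
  if (length(gone)) {
    state$ops$alive[gone] <- FALSE
    state$ops$bankrupted[gone] <- TRUE
    state$ops$bankrupt_tick[gone] <- state$tick
    state$links[gone, ] <- NA_real_
    state$links[, gone] <- NA_real_
  }
  state
}
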