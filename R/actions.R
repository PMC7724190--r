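# Environmental actions: vulnerability checks, willingness, contribution
# caps, collaborative funding rounds, individual actions, effects, and
# link-strength learning.

.EVENTS <- c("sudden_event", "slr", "pollution")

#' Maximum contribution an operator can make to actions this tick
#'
#' Based on reserves (resources minus the maintenance, tourism and
#' environment allocations): reserves when >= 3, otherwise 3, or — with
#' negative reserves — 3 when resources still cover the needed allocations
#' and 2 when they do not. Operators with a strong saving preference
#' (positive saving weight > 2) hold one unit back, and the result drops to
#' 0 when it exceeds the resources at hand.
#'
#' @param resources current resources.
#' @param alloc length-4 allocation vector.
#' @param needed length-4 needed vector.
#' @param wpos_saving the operator's positive saving weight (1-3).
#' @return Contribution budget in whole units (>= 0).
#' @export
compute_max_possible_contribution <- function(resources, alloc, needed,
                                              wpos_saving) {
  reserves <- resources - sum(alloc[c(1L, 2L, 3L)])
  mpc <- if (reserves >= 3) {
    reserves
  } else if (reserves >= 0) {
    3
  } else if (resources >= sum(needed)) {
    3
  } else {
    2
  }
  if (wpos_saving > 2) mpc <- mpc - 1
  if (mpc > resources) mpc <- 0
  mpc
}

#' Is a cell vulnerable to an event?
#'
#' Pollution: pollution level above the pollution threshold. Sudden events:
#' degradation above the acceptable level. Sea-level rise: land cells whose
#' elevation above the current sea level falls below the minimum acceptable
#' elevation; water cells are never SLR-vulnerable.
#'
#' @param grid a \code{coast_grid}.
#' @param cell cell index (vectorised).
#' @param event one of \code{"sudden_event"}, \code{"slr"},
#'   \code{"pollution"}.
#' @param params a \code{coast_params} list.
#' @param slr_in_m current sea level.
#' @return Logical vector.
#' @export
is_vulnerable <- function(grid, cell, event, params, slr_in_m = 0) {
  switch(match.arg(event, .EVENTS),
    pollution = grid$pollution[cell] > params$pollution_threshold,
    sudden_event = grid$degradation[cell] > params$acceptable_enviro_degradation,
    slr = !is_water_code(grid$geo[cell]) &
      params$min_acceptable_elevation_above_SL >
        (grid$elevation[cell] - slr_in_m))
}

# Degree to which each operator is affected by an event on `cell`:
# 2 directly (on the cell), 1 indirectly (neighbouring cell, or the land
# base of a water-based operator), 0 unaffected. Dead operators get 0.
affect_degree <- function(state, cell) {
  ops <- state$ops
  nbs <- state$grid$nb[cell, ]
  deg <- integer(length(ops$id))
  direct <- ops$alive & ops$loc == cell
  indirect <- ops$alive & !direct &
    (ops$loc %in% nbs[!is.na(nbs)] | (ops$mobile & ops$base == cell))
  deg[indirect] <- 1L
  deg[direct] <- 2L
  deg
}

# Willingness of every operator for an event on `cell` (0 for dead ones).
# Includes the random +0.15 term for unaffected collaborators with balanced
# links, so each call consumes randomness.
willingness_all <- function(state, cell, event, mode = c("collab", "individual")) {
  mode <- match.arg(mode)
  ops <- state$ops
  n <- length(ops$id)
  deg <- affect_degree(state, cell)
  W <- numeric(n)
  W[deg == 2L] <- if (mode == "collab") 0.40 else 0.50
  W[deg == 1L] <- 0.20
  W <- W + 0.20 * (deg > 0L & !ops$mobile)
  if (mode == "collab") {
    pos <- rowSums(state$links > 0, na.rm = TRUE)
    neg <- rowSums(state$links < 0, na.rm = TRUE)
    W <- W + 0.30 * (pos > neg)
    W <- W + 0.35 * (pos < neg & deg == 2L)
    W <- W + 0.10 * (pos < neg & deg == 1L)
    W <- W + 0.45 * (pos == neg & deg == 2L)
    W <- W + 0.20 * (pos == neg & deg == 1L)
    tie_unaff <- which(ops$alive & pos == neg & deg == 0L)
    if (length(tie_unaff)) {
      lucky <- stats::runif(length(tie_unaff)) < 0.5
      W[tie_unaff[lucky]] <- W[tie_unaff[lucky]] + 0.15
    }
  }
  W[!ops$alive] <- 0
  W
}

#' Willingness of one operator to act on an event
#'
#' Base willingness depends on how the operator is affected (0.40/0.50 when
#' on the cell for collaborative/individual action, 0.20 for a neighbouring
#' cell or the land base, 0 otherwise) plus 0.20 for affected immobile
#' operators; for collaborative actions the balance of positive versus
#' negative out-links adds further terms, including a random +0.15
#' (probability 0.5) for unaffected operators with balanced links. Values
#' above 1 act as certainty in the subsequent Bernoulli draw.
#'
#' @param state model state.
#' @param i operator index.
#' @param cell cell index.
#' @param event event kind.
#' @param mode \code{"collab"} or \code{"individual"}.
#' @return The willingness W (possibly > 1).
#' @export
willingness <- function(state, i, cell, event,
                        mode = c("collab", "individual")) {
  willingness_all(state, cell, event, mode)[i]
}

#' Contribution limits C1 and C2
#'
#' The eight-row mapping from (excess resources?, resources at least what's
#' needed?, saving tendency, affected?) to the two maximum contributions,
#' with negative results reset to 0. Rows with excess resources are keyed by
#' saving tendency and affectedness; rows without excess by whether resources
#' cover the needed allocations and affectedness.
#'
#' @param excess does the operator have excess resources (resources above the
#'   total allocated, or positive savings allocation)?
#' @param meets_needed do resources cover the summed needed allocations?
#' @param saving_high is the positive saving weight above 2?
#' @param affected is the operator directly or indirectly affected?
#' @param reserves resources minus the maintenance+tourism+environment
#'   allocations.
#' @param allocated total of all four allocations.
#' @return Named numeric vector \code{c(C1, C2)}.
#' @export
table13_limits <- function(excess, meets_needed, saving_high, affected,
                           reserves, allocated) {
  lim <- if (excess) {
    if (saving_high) {
      if (affected) c(reserves - 1, reserves - 1)
      else c(floor(reserves / 2), reserves - 2)
    } else {
      if (affected) c(reserves, reserves)
      else c(2, reserves - 1)
    }
  } else {
    if (meets_needed) {
      if (affected) c(3, floor(allocated / 2))
      else c(2, floor(allocated / 2))
    } else {
      if (affected) c(2, allocated - 2)
      else c(1, allocated - 1)
    }
  }
  c(C1 = max(0, lim[1]), C2 = max(0, lim[2]))
}

#' Cost of handling an event on a cell
#'
#' Pollution is priced per 0.1 chunk (\code{ceil(pollution / 0.1 * cost)});
#' sea-level rise and sudden events have flat costs.
#'
#' @param grid a \code{coast_grid}.
#' @param cell cell index.
#' @param event event kind.
#' @param params a \code{coast_params} list.
#' @return Integer cost Ce in resource units.
#' @export
event_cost <- function(grid, cell, event, params) {
  switch(match.arg(event, .EVENTS),
    pollution = ceiling(grid$pollution[cell] / 0.1 * params$cost_pollution),
    slr = params$cost_SLR,
    sudden_event = params$cost_extreme_event)
}

#' Contribution caps of an operator for an event on a cell
#'
#' Assembles C1/C2 (see \code{table13_limits}), the event cost Ce, the
#' operator's remaining action budget Cx, and the potential contribution
#' Cp = min(Cx, Ce, C1, C2) for individual actions or
#' min(Cx, Ce - 1, C1, C2) for collaborative ones (so no single operator can
#' fund a collaboration alone), floored at 0.
#'
#' @param state model state.
#' @param i operator index.
#' @param cell cell index.
#' @param event event kind.
#' @param mode \code{"collab"} or \code{"individual"}.
#' @return \code{list(C1, C2, Ce, Cx, Cp)}.
#' @export
contribution_caps <- function(state, i, cell, event,
                              mode = c("collab", "individual")) {
  mode <- match.arg(mode)
  ops <- state$ops
  alloc <- ops$alloc[i, ]
  reserves <- ops$resources[i] - sum(alloc[c("m", "t", "e")])
  allocated <- sum(alloc)
  excess <- ops$resources[i] > allocated || alloc[["s"]] > 0
  meets <- ops$resources[i] >= sum(ops$needed[i, ])
  affected <- affect_degree(state, cell)[i] > 0L
  lim <- table13_limits(excess, meets, ops$wpos[i, "s"] > 2, affected,
                        reserves, allocated)
  Ce <- event_cost(state$grid, cell, event, state$params)
  Cx <- ops$maxc[i]
  budget <- if (mode == "collab") Ce - 1 else Ce
  list(C1 = lim[["C1"]], C2 = lim[["C2"]], Ce = Ce, Cx = Cx,
       Cp = max(0, min(Cx, budget, lim[["C1"]], lim[["C2"]])))
}

#' Update the strength of a directed link after a collaboration attempt
#'
#' The eight-row learning table: the update from observer A to observed B
#' depends on whether A was affected, whether each contributed and who
#' contributed more, and whether the collaboration led to action or broke
#' down. Positive rows scale \code{positive_association}, negative rows
#' \code{negative_association}; the result is clamped to \[-1, 1\].
#'
#' @param strength current strength (0 for a link created on the spot).
#' @param a_affected was observer A affected by the event?
#' @param contrib_a,contrib_b contributions of A and B.
#' @param action did the collaboration lead to action (TRUE) or break down?
#' @param positive_association,negative_association learning parameters.
#' @return The updated strength in \[-1, 1\].
#' @export
update_link_strength <- function(strength, a_affected, contrib_a, contrib_b,
                                 action, positive_association,
                                 negative_association) {
  pos <- positive_association
  neg <- negative_association
  delta <- if (contrib_b > contrib_a) {
    if (action) 0.25 * pos
    else if (a_affected) 1 * pos else 0.5 * pos
  } else if (contrib_b > 0) {           # 0 < contrib_b <= contrib_a
    if (a_affected) {
      if (action) -1 * neg else 0.5 * pos
    } else {
      if (action) -0.5 * neg else 0.25 * pos
    }
  } else if (contrib_a > 0) {           # contrib_b == 0
    if (a_affected) {
      if (action) -2 * neg else -0.5 * neg
    } else {
      if (action) -1 * neg else -0.25 * neg
    }
  } else {                              # both zero
    if (a_affected) {
      if (action) -1 * neg else -0.5 * neg
    } else {
      if (action) -0.5 * neg else -0.25 * neg
    }
  }
  clamp(strength + delta, -1, 1)
}

#' Charge a contribution to an operator
#'
#' Unallocated resources are spent first; a remainder comes out of the
#' savings allocation when it covers the rest, and otherwise out of weighted
#' unit reductions across the four categories. Resources and the remaining
#' action budget drop by the full amount.
#'
#' @param state model state.
#' @param i operator index.
#' @param amount contribution in units (must not exceed the operator's
#'   remaining \code{max_possible_contribution}).
#' @return The updated state.
#' @export
charge_contribution <- function(state, i, amount) {
  if (amount == 0) return(state)
  ops <- state$ops
  if (amount > ops$maxc[i] + 1e-9) {
    stop("contract violation: contribution exceeds max-possible-contribution")
  }
  alloc <- ops$alloc[i, ]
  unalloc <- ops$resources[i] - sum(alloc)
  remainder <- amount - min(max(unalloc, 0), amount)
  if (remainder > 0) {
    if (alloc[["s"]] >= remainder) {
      alloc[["s"]] <- alloc[["s"]] - remainder
    } else {
      while (remainder > 0 && any(alloc > 0)) {
        alloc <- weighted_unit_adjust(alloc, ops$wneg[i, ], -1)
        remainder <- remainder - 1
      }
    }
  }
  ops$alloc[i, ] <- alloc
  ops$resources[i] <- ops$resources[i] - amount
  ops$maxc[i] <- ops$maxc[i] - amount
  state$ops <- ops
  state
}

#' Apply the environmental effect of a funded action
#'
#' Pollution: the cell's pollution is split into 0.1 chunks (a remainder
#' counts as one final chunk); each chunk is removed with probability 0.75 on
#' land and 0.50 in the water. Sudden event: degradation resolves to 0 with
#' probability 0.5. Sea-level rise: the cell is elevated by
#' \code{increased_elevation} and becomes elevated beach space (code 59);
#' maintenance obligations of land-based operators on or next to the cell
#' rise by 2 (water-based operators based there: by 1) and each neighbouring
#' beach cell gains 0.3 pollution.
#'
#' @param state model state.
#' @param cell cell index.
#' @param event event kind.
#' @return The updated state.
#' @export
apply_action_effect <- function(state, cell, event) {
  event <- match.arg(event, .EVENTS)
  grid <- state$grid
  if (event == "pollution") {
    p <- grid$pollution[cell]
    if (p > 0) {
      n_full <- floor(p / 0.1 + 1e-9)
      sizes <- rep(0.1, n_full)
      rest <- p - n_full * 0.1
      if (rest > 1e-9) sizes <- c(sizes, rest)
      p_remove <- if (is_water_code(grid$geo[cell])) 0.50 else 0.75
      keep <- stats::runif(length(sizes)) >= p_remove
      grid$pollution[cell] <- sum(sizes[keep])
    }
  } else if (event == "sudden_event") {
    if (stats::runif(1) < 0.5) {
      grid$degradation[cell] <- 0
      grid$event_age[cell] <- NA_real_
    }
  } else {
    grid$elevation[cell] <- grid$elevation[cell] + state$params$increased_elevation
    grid$geo[cell] <- 59L
    ops <- state$ops
    nbs <- grid$nb[cell, ]
    nbs <- nbs[!is.na(nbs)]
    on_or_next <- ops$alive & !ops$mobile &
      (ops$loc == cell | ops$loc %in% nbs)
    based_here <- ops$alive & ops$mobile & ops$base == cell
    for (set in list(list(which(on_or_next), 2L), list(which(based_here), 1L))) {
      idx <- set[[1]]; inc <- set[[2]]
      if (length(idx)) {
        ops$needed[idx, "m"] <- ops$needed[idx, "m"] + inc
        ops$default[idx, "m"] <- ops$default[idx, "m"] + inc
        ops$maxa[idx, "m"] <- ops$maxa[idx, "m"] + inc
      }
    }
    state$ops <- ops
    beach_nb <- nbs[grid$geo[nbs] %in% .BEACH_CODES]
    grid$pollution[beach_nb] <- grid$pollution[beach_nb] + 0.3
  }
  state$grid <- grid
  state
}

#' Attempt a collaborative action on a vulnerable cell
#'
#' Operators join with probability given by their willingness; with fewer
#' than two willing operators nothing happens. Willing operators raise their
#' contributions one unit per round (fresh random order each round) up to
#' their individual caps, stopping exactly when the event cost Ce is covered.
#' A funded action is charged and applied and counted; otherwise the attempt
#' breaks down with nothing spent. Either way (given a quorum), every ordered
#' pair of willing operators updates its link, creating missing links at
#' strength 0.
#'
#' @param state model state.
#' @param cell cell index.
#' @param event event kind.
#' @return \code{list(state, outcome)} with outcome one of
#'   \code{"no_quorum"}, \code{"breakdown"}, \code{"action"}.
#' @export
resolve_collaborative <- function(state, cell, event) {
  W <- willingness_all(state, cell, event, "collab")
  cand <- which(W > 0)
  willing <- cand[stats::runif(length(cand)) < W[cand]]
  if (length(willing) <= 1L) {
    return(list(state = state, outcome = "no_quorum"))
  }
  Ce <- event_cost(state$grid, cell, event, state$params)
  Cp <- vapply(willing, function(i) {
    contribution_caps(state, i, cell, event, "collab")$Cp
  }, numeric(1))
  contrib <- numeric(length(willing))
  total <- 0
  repeat {
    raised <- FALSE
    for (k in shuffled(length(willing))) {
      if (total >= Ce) break
      if (contrib[k] < Cp[k]) {
        contrib[k] <- contrib[k] + 1
        total <- total + 1
        raised <- TRUE
      }
    }
    if (total >= Ce || !raised) break
  }
  funded <- total >= Ce
  if (funded) {
    for (k in seq_along(willing)) {
      state <- charge_contribution(state, willing[k], contrib[k])
    }
    state <- apply_action_effect(state, cell, event)
    state$globals$total_num_collaborations <-
      state$globals$total_num_collaborations + 1L
  }
  affected <- affect_degree(state, cell) > 0L
  for (ka in seq_along(willing)) {
    for (kb in seq_along(willing)) {
      if (ka == kb) next
      a <- willing[ka]; b <- willing[kb]
      s <- state$links[a, b]
      if (is.na(s)) s <- 0
      state$links[a, b] <- update_link_strength(
        s, affected[a], contrib[ka], contrib[kb], funded,
        state$params$positive_association, state$params$negative_association)
    }
  }
  list(state = state, outcome = if (funded) "action" else "breakdown")
}

#' Attempt an individual action on a vulnerable cell
#'
#' Operators are polled in random order; each draws its individual
#' willingness, and the first willing operator whose potential contribution
#' covers the full event cost pays it, applies the effect and ends the pass.
#' Individual actions leave links untouched.
#'
#' @param state model state.
#' @param cell cell index.
#' @param event event kind.
#' @return \code{list(state, outcome)} with outcome \code{"action"} or
#'   \code{"none"}.
#' @export
resolve_individual <- function(state, cell, event) {
  idx <- which(state$ops$alive)
  Wv <- willingness_all(state, cell, event, "individual")
  for (i in idx[shuffled(length(idx))]) {
    W <- Wv[i]
    if (W <= 0) next
    if (stats::runif(1) >= W) next
    caps <- contribution_caps(state, i, cell, event, "individual")
    if (caps$Cp >= caps$Ce) {
      state <- charge_contribution(state, i, caps$Ce)
      state <- apply_action_effect(state, cell, event)
      state$globals$total_num_indiv_actions <-
        state$globals$total_num_indiv_actions + 1L
      return(list(state = state, outcome = "action"))
    }
  }
  list(state = state, outcome = "none")
}
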