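# Environmental dynamics: pollution diffusion, sudden events and degradation,
# sea-level rise and erosion, marine-life health, demography and movement,
# operator-driven pollution change.

new_globals <- function() {
  list(slr_in_m = 0, last_event_tick = NA_real_,
       total_num_collaborations = 0L, total_num_indiv_actions = 0L,
       lost_ops_slr_land = 0L, lost_ops_slr_water = 0L)
}

#' Diffuse pollution over the grid
#'
#' All updates are computed from a snapshot so the step conserves total
#' pollution mass exactly. Each cell exports \code{rate} times its pollution:
#' on land the exported mass is split equally among neighbours at the same or
#' lower elevation (pollution never moves uphill; with no eligible neighbour
#' nothing moves); at the coastline the whole exported fraction moves to one
#' random coastline neighbour; at sea it is split equally among neighbours
#' excluding land cells at least one meter above the current sea level.
#'
#' @param grid a \code{coast_grid} with elevations assigned.
#' @param rate pollution diffusion rate in \[0.01, 0.25\].
#' @param slr_in_m current sea level in meters above the initial level.
#' @return The grid with updated pollution.
#' @export
diffuse_pollution <- function(grid, rate, slr_in_m = 0) {
  p <- grid$pollution
  if (all(p == 0)) return(grid)
  n <- grid$n
  nb <- grid$nb
  water <- is_water_code(grid$geo)
  coastline <- grid$geo == 50L
  land_plain <- !water & !coastline

  elev_nb <- matrix(grid$elevation[nb], n, 8L)
  water_nb <- matrix(water[nb], n, 8L)
  exists_nb <- !is.na(nb)

  elig <- matrix(FALSE, n, 8L)
  # land: same-or-lower elevation neighbours only
  elig[land_plain, ] <- exists_nb[land_plain, , drop = FALSE] &
    !is.na(elev_nb[land_plain, , drop = FALSE]) &
    elev_nb[land_plain, , drop = FALSE] <= grid$elevation[land_plain]
  # sea: all neighbours except land >= 1 m above current sea level
  high_land_nb <- !water_nb & !is.na(elev_nb) & elev_nb >= slr_in_m + 1
  elig[water, ] <- exists_nb[water, , drop = FALSE] &
    !high_land_nb[water, , drop = FALSE]

  cnt <- rowSums(elig)
  movers <- which(p > 0 & cnt > 0 & !coastline)
  out <- numeric(n)
  inc <- numeric(n)
  if (length(movers)) {
    out[movers] <- rate * p[movers]
    share <- out / pmax(cnt, 1L)
    for (k in 1:8) {
      src <- movers[elig[movers, k]]
      if (length(src)) {
        dst <- nb[src, k]
        inc[dst] <- inc[dst] + share[src]
      }
    }
  }
  # coastline: whole exported fraction to one random coastline neighbour
  for (i in which(coastline & p > 0)) {
    cn <- nb[i, ]
    cn <- cn[!is.na(cn)]
    cn <- cn[grid$geo[cn] == 50L]
    if (length(cn)) {
      out[i] <- rate * p[i]
      j <- pick_one(cn)
      inc[j] <- inc[j] + out[i]
    }
  }
  grid$pollution <- p - out + inc
  grid
}

#' Trigger a sudden event when its interval has elapsed
#'
#' When \code{sudden_event_interval} ticks have passed since the previous
#' event (or since the start of the run), each cell is independently affected
#' with probability \code{patches_affected_sudden_event}/100; affected cells
#' gain \code{enviro_deg_from_sudden_event} degradation (capped at 1) and
#' their per-cell event clock restarts.
#'
#' @param grid a \code{coast_grid}.
#' @param globals global state list (see \code{coast_setup}).
#' @param params a \code{coast_params} list.
#' @param tick current tick (1-based).
#' @return \code{list(grid, globals)}.
#' @export
trigger_sudden_event <- function(grid, globals, params, tick) {
  since <- if (is.na(globals$last_event_tick)) tick else
    tick - globals$last_event_tick
  if (since >= params$sudden_event_interval) {
    hit <- stats::runif(grid$n) < params$patches_affected_sudden_event / 100
    if (any(hit)) {
      grid$degradation[hit] <-
        pmin(1, grid$degradation[hit] + params$enviro_deg_from_sudden_event)
      grid$event_age[hit] <- 0
    }
    globals$last_event_tick <- tick
  }
  list(grid = grid, globals = globals)
}

#' Evolve existing environmental degradation
#'
#' Ages every degraded cell by one tick. Cells degraded for longer than
#' \code{persistence} ticks then either spread their degradation to one
#' random neighbour (probability 1/3; additive, capped at 1), stay unchanged
#' (1/3), or clear autonomously (1/3).
#'
#' @param grid a \code{coast_grid}.
#' @param persistence sudden-event persistence in ticks (1-10).
#' @return The updated grid.
#' @export
evolve_degradation <- function(grid, persistence) {
  degraded <- grid$degradation > 0
  if (!any(degraded)) return(grid)
  age <- grid$event_age
  age[degraded & is.na(age)] <- 0
  age[degraded] <- age[degraded] + 1
  grid$event_age <- age
  due <- which(degraded & age > persistence)
  if (length(due)) {
    u <- stats::runif(length(due))
    clear <- due[u >= 2 / 3]
    if (length(clear)) {
      grid$degradation[clear] <- 0
      grid$event_age[clear] <- NA_real_
    }
    for (i in due[u < 1 / 3]) {
      cn <- grid$nb[i, ]
      cn <- cn[!is.na(cn)]
      j <- pick_one(cn)
      grid$degradation[j] <- min(1, grid$degradation[j] + grid$degradation[i])
      grid$event_age[j] <- 0
    }
  }
  grid
}

#' Advance the sea level and erode low coastal land
#'
#' The per-tick rise is \code{SLR_increase} (mm/year) converted to meters and
#' divided by the 35 ticks of a simulated year; in non-linear mode the rate
#' is multiplied by 1.25 from tick 200, 1.5 from 400, 1.75 from 800 and 2.0
#' from 1200. Land cells bordering the sea whose elevation (plus a 0.2 m
#' mangrove buffer where mangroves stand) is below the current sea level plus
#' \code{erosion_loss} convert to nearshore coastal waters.
#'
#' @param grid a \code{coast_grid}.
#' @param globals global state list.
#' @param params a \code{coast_params} list.
#' @param tick current tick (1-based).
#' @param mangrove_cells indices of cells currently holding mangroves.
#' @return \code{list(grid, globals, inundated)} where \code{inundated} are
#'   the converted cell indices.
#' @export
advance_sea_level <- function(grid, globals, params, tick,
                              mangrove_cells = integer(0)) {
  if (params$SLR_increase > 0) {
    mult <- if (params$linear_SLR) 1 else
      if (tick >= 1200) 2.0 else if (tick >= 800) 1.75 else
      if (tick >= 400) 1.5 else if (tick >= 200) 1.25 else 1
    globals$slr_in_m <- globals$slr_in_m +
      (params$SLR_increase / 1000) / 35 * mult
  }
  water <- is_water_code(grid$geo)
  borders_sea <- rowSums(matrix(water[grid$nb], grid$n, 8L),
                         na.rm = TRUE) > 0
  eff <- grid$elevation
  mg <- intersect(mangrove_cells, which(!water))
  eff[mg] <- eff[mg] + 0.2
  inundated <- which(!water & borders_sea &
                     eff < globals$slr_in_m + params$erosion_loss)
  if (length(inundated)) {
    grid$geo[inundated] <- 20L
    grid$init_mangrove[inundated] <- FALSE
  }
  list(grid = grid, globals = globals, inundated = inundated)
}

#' Update health, mortality and reproduction of environmental resources
#'
#' Health loses 0.01 where cell pollution exceeds 0.25 or the sensitivity,
#' a further 0.05 where degradation exceeds 0.10 or the sensitivity, and
#' gains 0.01 in clean cells (no degradation, pollution below 0.02); health
#' is clamped to \[0, 1\]. Agents below health 0.25 die with probability 0.5;
#' agents above 0.95 reproduce into their cell with probability 0.01, subject
#' to per-cell caps (2 fish, 2 turtles, 3 coral, 1 mangrove), with parent and
#' offspring health reset to 0.5.
#'
#' @param res resource block.
#' @param grid a \code{coast_grid}.
#' @param sensitivity marine-life sensitivity in \[0.10, 0.50\].
#' @return The updated resource block.
#' @export
update_env_resources <- function(res, grid, sensitivity) {
  alive <- which(res$alive)
  if (length(alive) == 0L) return(res)
  cell <- res$cell[alive]
  p <- grid$pollution[cell]
  d <- grid$degradation[cell]
  h <- res$health[alive]
  h <- h - 0.01 * (p > 0.25 | p > sensitivity)
  h <- h - 0.05 * (d > 0.10 | d > sensitivity)
  h <- h + 0.01 * (d == 0 & p < 0.02)
  h <- clamp(h, 0, 1)
  res$health[alive] <- h

  frail <- alive[h < 0.25]
  if (length(frail)) {
    res$alive[frail[stats::runif(length(frail)) < 0.5]] <- FALSE
  }

  caps <- c(fish = 2L, turtle = 2L, coral = 3L, mangrove = 1L)
  fit <- alive[res$health[alive] > 0.95 & res$alive[alive]]
  fit <- fit[stats::runif(length(fit)) < 0.01]
  for (i in fit) {
    kind <- res$kind[i]
    here <- res$cell[i]
    n_here <- sum(res$alive & res$kind == kind & res$cell == here)
    if (n_here + 1L <= caps[[kind]]) {
      res$kind <- c(res$kind, kind)
      res$health <- c(res$health, 0.5)
      res$cell <- c(res$cell, here)
      res$alive <- c(res$alive, TRUE)
      res$mobile <- c(res$mobile, res$mobile[i])
      res$health[i] <- 0.5
    }
  }
  res
}

#' Relocate mobile marine life away from poor conditions
#'
#' Fish and turtles whose cell exceeds the sensitivity in pollution or
#' degradation look for a new nearshore-water cell: ideal cells hold at least
#' one coral unit; alternative cells have pollution or degradation below the
#' sensitivity (any nearshore-water cell if none qualifies). If an ideal cell
#' exists the agent moves there with probability 0.95, otherwise to an
#' alternative cell. Destinations already holding the per-cell cap of the
#' agent's kind (2 fish, 2 turtles) are not considered, so movement cannot
#' overcrowd a cell; with no admissible destination the agent stays put.
#'
#' @param res resource block.
#' @param grid a \code{coast_grid}.
#' @param sensitivity marine-life sensitivity.
#' @return The updated resource block.
#' @export
move_marine_life <- function(res, grid, sensitivity) {
  movers <- which(res$alive & res$mobile &
                  (grid$pollution[res$cell] > sensitivity |
                   grid$degradation[res$cell] > sensitivity))
  if (length(movers) == 0L) return(res)
  counts <- resource_counts(res, grid$n)
  near <- grid$geo == 20L
  ideal <- which(near & counts$coral >= 1L)
  altern <- which(near & (grid$pollution < sensitivity |
                          grid$degradation < sensitivity))
  if (length(altern) == 0L) altern <- which(near)
  occ <- list(fish = counts$fish, turtle = counts$turtle)
  cap <- c(fish = 2L, turtle = 2L)
  for (i in movers) {
    kind <- res$kind[i]
    room_ideal <- ideal[occ[[kind]][ideal] < cap[[kind]]]
    room_alt <- altern[occ[[kind]][altern] < cap[[kind]]]
    dest <- if (length(room_ideal) && stats::runif(1) < 0.95) {
      pick_one(room_ideal)
    } else if (length(room_alt)) {
      pick_one(room_alt)
    } else {
      NA_integer_
    }
    if (!is.na(dest)) {
      occ[[kind]][res$cell[i]] <- occ[[kind]][res$cell[i]] - 1L
      occ[[kind]][dest] <- occ[[kind]][dest] + 1L
      res$cell[i] <- dest
    }
  }
  res
}

#' Raw pollution effect of an operator's allocation balance
#'
#' The balance D = max(At - Nt, -1) - (Ae - Ne) between over-investment in
#' tourism and in the environment maps to a raw pollution effect: D - 2 when
#' D > 2, D when D < 0, else 0. Nearshore operators follow a gentler
#' piecewise map of At and Ae.
#'
#' @param At,Nt allocated and needed tourism units.
#' @param Ae,Ne allocated and needed environment units.
#' @param nearshore logical; use the nearshore-operator special cases.
#' @return The raw pollution effect (positive pollutes, negative may clean).
#' @export
pollution_effect_rate <- function(At, Nt, Ae, Ne, nearshore = FALSE) {
  D <- max(At - Nt, -1) - (Ae - Ne)
  if (!nearshore) {
    if (D > 2) return(D - 2)
    if (D < 0) return(D)
    return(0)
  }
  if (Ae == 0) return(D / 2)
  if (At >= 2 && Ae >= 1 && At > 2 * Ae) return(1 - Ae)
  if (At >= 2 && Ae >= 1 && At <= 2 * Ae) return(At / 2 - Ae)
  if (At == 1 && Ae == 1) return(-0.5)
  0
}

#' Apply operators' pollution changes to their cells
#'
#' In random order, each living operator applies its raw pollution effect to
#' its current cell: a positive effect adds \code{pollution_change} per unit;
#' a negative effect removes \code{pollution_clean_up} per unit with
#' probability 0.5 (pollution floored at 0), otherwise nothing happens.
#'
#' @param ops operator block.
#' @param grid a \code{coast_grid}.
#' @param params a \code{coast_params} list.
#' @return The updated grid.
#' @export
update_operator_pollution <- function(ops, grid, params) {
  idx <- which(ops$alive)
  idx <- idx[shuffled(length(idx))]
  for (i in idx) {
    pr <- pollution_effect_rate(ops$alloc[i, "t"], ops$needed[i, "t"],
                                ops$alloc[i, "e"], ops$needed[i, "e"],
                                nearshore = ops$type[i] == "nearshore")
    cell <- ops$loc[i]
    if (pr > 0) {
      grid$pollution[cell] <- grid$pollution[cell] + params$pollution_change * pr
    } else if (pr < 0 && stats::runif(1) < 0.5) {
      grid$pollution[cell] <-
        max(0, grid$pollution[cell] - params$pollution_clean_up * (-pr))
    }
  }
  grid
}
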