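# Engine: set-up, the per-tick scheduler, metric collection and time-series
# output. One global RNG stream, seeded from seed_for_random, drives every
# draw, so runs are bit-identical for identical (params, map, seed).

.METRIC_GROUPS <- c(hotel = "hotelops", beach = "beachops", dive = "diveops",
                    boat = "boatops", nearshore = "waterops")
.REGIONS <- c("beach", "coast", "nearshore", "area")

#' Set up a model state
#'
#' Seeds the RNG, parses the map and draws elevations, initialises the
#' operator population, links, water placements and environmental resources,
#' and computes the initial attractiveness. The tick-0 metrics record is
#' appended as baseline.
#'
#' @param params a \code{coast_params} list.
#' @param map_text map-file content (see \code{parse_map_text}).
#' @return A model state (list with \code{grid}, \code{ops}, \code{links},
#'   \code{res}, \code{globals}, \code{params}, \code{tick},
#'   \code{metrics}).
#' @export
coast_setup <- function(params, map_text) {
  validate_params(params)
  set.seed(params$seed_for_random)
  grid <- parse_map_text(map_text)
  grid$elevation <- sample_elevation(grid$geo)
  ops <- initialize_operators(grid)
  links <- initialize_links(ops, grid, params$link_chance,
                            params$links_to_my_base)
  ops <- place_water_operators(ops, grid)
  res <- initialize_env_resources(grid)
  grid <- recompute_attractiveness(grid, resource_counts(res, grid$n), params)
  state <- list(grid = grid, ops = ops, links = links, res = res,
                globals = new_globals(), params = params, tick = 0L,
                metrics = list(),
                attr_sum = stats::setNames(numeric(4), .REGIONS),
                attr_n = 0L)
  class(state) <- "coast_state"
  record_metrics(state)
}

# Mean current attractiveness and pollution per reporting region.
region_means <- function(grid) {
  reg <- region_of(grid$geo)
  in_area <- reg != "other"
  means <- function(v) {
    out <- stats::setNames(numeric(4), .REGIONS)
    for (r in c("beach", "coast", "nearshore")) {
      out[r] <- if (any(reg == r)) mean(v[reg == r]) else NA_real_
    }
    out["area"] <- if (any(in_area)) mean(v[in_area]) else NA_real_
    out
  }
  list(attr = means(grid$attractiveness), poll = means(grid$pollution))
}

metrics_row <- function(state, rm) {
  ops <- state$ops
  res <- state$res
  row <- list(tick = state$tick)
  total_needed <- rowSums(ops$needed)
  enough <- ops$alive & ops$resources >= total_needed
  short <- ops$alive & !enough
  for (ty in names(.METRIC_GROUPS)) {
    g <- .METRIC_GROUPS[[ty]]
    sel <- ops$type == ty
    liv <- sel & ops$alive
    row[[paste0("m-", g)]] <- sum(liv)
    row[[paste0("m-", g, "-enough")]] <- sum(enough[sel])
    row[[paste0("m-", g, "-short")]] <- sum(short[sel])
    row[[paste0("m-", g, "-bankrupted")]] <- sum(ops$bankrupted[sel])
    row[[paste0("m-", g, "-delayed-maint")]] <- sum(liv & ops$delay > 0)
    row[[paste0("m-", g, "-av-time-enough")]] <-
      if (any(liv)) mean(ops$t_enough[liv]) else NA_real_
    row[[paste0("m-", g, "-av-time-short")]] <-
      if (any(liv)) mean(ops$t_short[liv]) else NA_real_
  }
  row[["m-all-ops"]] <- sum(ops$alive)
  row[["m-all-ops-enough"]] <- sum(enough)
  row[["m-all-ops-short"]] <- sum(short)
  row[["m-all-ops-bankrupted"]] <- sum(ops$bankrupted)
  row[["m-all-ops-delayed-maint"]] <- sum(ops$alive & ops$delay > 0)
  row[["m-all-ops-av-time-enough"]] <-
    if (any(ops$alive)) mean(ops$t_enough[ops$alive]) else NA_real_
  row[["m-all-ops-av-time-short"]] <-
    if (any(ops$alive)) mean(ops$t_short[ops$alive]) else NA_real_
  row[["m-av-time-before-bankrupt"]] <-
    if (any(ops$bankrupted)) mean(ops$bankrupt_tick[ops$bankrupted]) else
      NA_real_
  row[["lost-ops-due-to-SLR-land-based"]] <- state$globals$lost_ops_slr_land
  row[["lost-ops-due-to-SLR-water-based"]] <- state$globals$lost_ops_slr_water
  row[["m-corals"]] <- sum(res$alive & res$kind == "coral")
  row[["m-fishes"]] <- sum(res$alive & res$kind == "fish")
  row[["m-seaturtles"]] <- sum(res$alive & res$kind == "turtle")
  row[["m-mangroves"]] <- sum(res$alive & res$kind == "mangrove")
  total_links <- sum(!is.na(state$links))
  pos_links <- sum(state$links > 0, na.rm = TRUE)
  neg_links <- sum(state$links < 0, na.rm = TRUE)
  row[["m-total-links"]] <- total_links
  row[["m-neutral-links"]] <- total_links - pos_links - neg_links
  row[["m-positive-links"]] <- pos_links
  row[["m-negative-links"]] <- neg_links
  row[["total-num-collaborations"]] <- state$globals$total_num_collaborations
  row[["total-num-indiv-actions"]] <- state$globals$total_num_indiv_actions
  for (r in .REGIONS) row[[paste0("m-av-now-attr-", r)]] <- rm$attr[[r]]
  avav <- (state$attr_sum + rm$attr) / (state$attr_n + 1L)
  for (r in .REGIONS) row[[paste0("m-av-av-attr-", r)]] <- avav[[r]]
  for (r in .REGIONS) row[[paste0("m-av-pollution-", r)]] <- rm$poll[[r]]
  row
}

record_metrics <- function(state) {
  rm <- region_means(state$grid)
  row <- metrics_row(state, rm)
  state$attr_sum <- state$attr_sum + rm$attr
  state$attr_n <- state$attr_n + 1L
  state$metrics[[length(state$metrics) + 1L]] <- row
  state
}

#' Current metrics of a model state
#'
#' Computes the full output record (operator counts and vulnerability
#' indicators, resource and link counts, action counters, regional
#' attractiveness and pollution) for the state as it stands.
#'
#' @param state model state.
#' @return Named list of outputs, using the model-code output names.
#' @export
collect_metrics <- function(state) {
  metrics_row(state, region_means(state$grid))
}

remove_operators <- function(state, idx, slr = FALSE) {
  if (length(idx) == 0L) return(state)
  state$ops$alive[idx] <- FALSE
  if (slr) {
    state$ops$lost_slr[idx] <- TRUE
    state$globals$lost_ops_slr_land <- state$globals$lost_ops_slr_land +
      sum(!state$ops$mobile[idx])
    state$globals$lost_ops_slr_water <- state$globals$lost_ops_slr_water +
      sum(state$ops$mobile[idx])
  }
  state$links[idx, ] <- NA_real_
  state$links[, idx] <- NA_real_
  state
}

#' Advance the model by one tick
#'
#' Executes the scheduler: (1) environmental change (pollution diffusion,
#' degradation evolution, marine-life movement, attractiveness recompute);
#' (2) resource allocation and action budgets; (3) sudden-event check, then
#' sea-level rise with erosion; (4-6) per event kind — sudden events, SLR,
#' pollution — a collaborative pass over vulnerable cells in random order
#' followed by an individual pass, effects applied immediately; (7) revenue
#' settlement; (8) operator pollution updates; (9) movement of mobile
#' operators; (10) bankruptcy; (11) environmental-resource health and
#' demography. The tick counter advances and a metrics record is appended.
#'
#' @param state model state.
#' @return The updated state.
#' @export
coast_step <- function(state) {
  params <- state$params
  state$tick <- state$tick + 1L
  tick <- state$tick

  # (1) environment changes
  state$grid <- diffuse_pollution(state$grid, params$pollution_diffusion_rate,
                                  state$globals$slr_in_m)
  state$grid <- evolve_degradation(state$grid,
                                   params$sudden_event_persistence)
  state$res <- move_marine_life(state$res, state$grid,
                                params$marine_life_sensitivity)
  counts <- resource_counts(state$res, state$grid$n)
  state$grid <- recompute_attractiveness(state$grid, counts, params)

  # (2) allocations and action budgets
  ops <- state$ops
  idx <- which(ops$alive)
  for (i in idx[shuffled(length(idx))]) {
    ops$alloc[i, ] <- allocate_resources(ops$resources[i], ops$default[i, ],
                                         ops$maxa[i, ], ops$wpos[i, ],
                                         ops$wneg[i, ])
    ops$maxc[i] <- compute_max_possible_contribution(
      ops$resources[i], ops$alloc[i, ], ops$needed[i, ], ops$wpos[i, "s"])
  }
  state$ops <- ops

  # (3) environmental events: sudden-event check, then sea-level rise
  se <- trigger_sudden_event(state$grid, state$globals, params, tick)
  state$grid <- se$grid
  state$globals <- se$globals
  mangrove_cells <- state$res$cell[state$res$alive &
                                   state$res$kind == "mangrove"]
  sl <- advance_sea_level(state$grid, state$globals, params, tick,
                          mangrove_cells)
  state$grid <- sl$grid
  state$globals <- sl$globals
  if (length(sl$inundated)) {
    drown <- which(state$ops$alive &
                   ((!state$ops$mobile & state$ops$loc %in% sl$inundated) |
                    (state$ops$mobile & state$ops$base %in% sl$inundated)))
    state <- remove_operators(state, drown, slr = TRUE)
    state$res$alive[state$res$alive & state$res$kind == "mangrove" &
                    state$res$cell %in% sl$inundated] <- FALSE
  }

  # (4-6) environmental actions: collaborative then individual, per event
  for (event in .EVENTS) {
    for (pass in c("collab", "individual")) {
      vul <- which(is_vulnerable(state$grid, seq_len(state$grid$n), event,
                                 params, state$globals$slr_in_m))
      if (length(vul) == 0L) next
      for (cell in vul[shuffled(length(vul))]) {
        if (!is_vulnerable(state$grid, cell, event, params,
                           state$globals$slr_in_m)) next
        out <- if (pass == "collab") {
          resolve_collaborative(state, cell, event)
        } else {
          resolve_individual(state, cell, event)
        }
        state <- out$state
      }
    }
  }

  # (7) revenues, (8) pollution from operations, (9) movement,
  # (10) bankruptcy, (11) environmental resources
  state <- settle_all_revenues(state)
  state$grid <- update_operator_pollution(state$ops, state$grid, params)
  state <- move_operators(state)
  state <- remove_bankrupt(state)
  state$res <- update_env_resources(state$res, state$grid,
                                    params$marine_life_sensitivity)

  # duration bookkeeping, then the tick's metrics record
  alive <- state$ops$alive
  state$ops$ticks_alive[alive] <- state$ops$ticks_alive[alive] + 1
  enough <- alive & state$ops$resources >= rowSums(state$ops$needed)
  state$ops$t_enough[enough] <- state$ops$t_enough[enough] + 1
  state$ops$t_short[alive & !enough] <- state$ops$t_short[alive & !enough] + 1
  record_metrics(state)
}

#' Run the model
#'
#' Sets up a state from the parameters and map and advances it
#' \code{n_ticks} ticks (35 ticks represent one simulated year; the standard
#' horizon of 30 years is 1050 ticks).
#'
#' @param params a \code{coast_params} list.
#' @param map_text map-file content.
#' @param n_ticks number of ticks to simulate (>= 1).
#' @return A \code{coast_run}: list with \code{series} (data frame of one
#'   metrics row per tick, including the tick-0 baseline) and \code{state}
#'   (the final model state).
#' @export
coast_run <- function(params, map_text, n_ticks) {
  stopifnot(n_ticks >= 1)
  state <- coast_setup(params, map_text)
  for (k in seq_len(n_ticks)) state <- coast_step(state)
  out <- list(series = metrics_to_df(state$metrics), state = state)
  class(out) <- "coast_run"
  out
}

metrics_to_df <- function(metrics) {
  cols <- names(metrics[[1]])
  df <- as.data.frame(lapply(cols, function(cn) {
    vapply(metrics, function(row) as.numeric(row[[cn]]), numeric(1))
  }), col.names = cols, check.names = FALSE, optional = TRUE)
  names(df) <- cols
  df
}

#' Write a metrics time series to CSV
#'
#' One row per tick, one column per model output, using the model-code
#' output names verbatim in a stable order.
#'
#' @param series data frame as returned in \code{coast_run()$series}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(nrow(series) >= 1)
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read back a metrics time series
#'
#' @param path CSV path written by \code{write_timeseries}.
#' @return Data frame with the original column names.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @export
print.coast_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("<coast_run %d ticks>\n", x$state$tick))
  cat(sprintf("  operators: %d of %d; collaborations: %d; individual actions: %d\n",
              last[["m-all-ops"]], x$series[["m-all-ops"]][1],
              last[["total-num-collaborations"]],
              last[["total-num-indiv-actions"]]))
  cat(sprintf("  area attractiveness: %.3f (tick 0: %.3f)\n",
              last[["m-av-now-attr-area"]],
              x$series[["m-av-now-attr-area"]][1]))
  invisible(x)
}

#' @export
print.coast_state <- function(x, ...) {
  cat(sprintf("<coast_state tick %d, %d operators alive>\n",
              x$tick, sum(x$ops$alive)))
  invisible(x)
}
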