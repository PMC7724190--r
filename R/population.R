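# Population: operator agents, directed links, environmental-resource agents
# and their initialisation.

.OP_TYPES <- c("hotel", "beach", "dive", "boat", "nearshore")
.CATS <- c("m", "t", "e", "s")  # maintenance, tourism, environment, savings

#' Operator type specification
#'
#' Counts, initial resources and needed allocations per operator type, plus
#' the fixed offsets defining the maximum allocations
#' (needed + 2 / + 5 / + 3 / + 5 for maintenance/tourism/environment/savings).
#'
#' @return Data frame with one row per type.
#' @export
operator_type_spec <- function() {
  data.frame(
    type = .OP_TYPES,
    count = c(30L, 10L, 20L, 5L, 10L),
    resources = c(12L, 7L, 7L, 7L, 3L),
    needed_m = c(4L, 1L, 2L, 2L, 1L),
    needed_t = c(5L, 2L, 2L, 2L, 1L),
    needed_e = c(2L, 1L, 1L, 1L, 0L),
    needed_s = c(0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

.MAX_OFFSETS <- c(m = 2L, t = 5L, e = 3L, s = 5L)

cat_matrix <- function(n, values = 0L) {
  matrix(values, nrow = n, ncol = 4L, dimnames = list(NULL, .CATS))
}

#' Initialise the operator population on a grid
#'
#' Hotels pick an unoccupied beach/beachfront cell first, then beach
#' operators; land-based operators never share a cell. Dive, boat and
#' nearshore operators are then assigned a land base (dive and boat prefer
#' cells hosting a hotel or beach operator, opting for an alternative
#' location with probability 0.1 and 0.2 respectively; nearshore operators
#' base at any beachfront cell); same-type operators never share a base, and
#' a water-based operator that finds no base leaves immediately. Individual
#' preferences (defaults within one unit of the needed level, weights 1-3,
#' maxima at fixed offsets) are drawn per operator.
#'
#' @param grid a \code{coast_grid}.
#' @return Operator block: a list of parallel per-operator vectors/matrices.
#' @export
initialize_operators <- function(grid) {
  spec <- operator_type_spec()
  n <- sum(spec$count)
  type <- rep(spec$type, spec$count)
  needed <- cat_matrix(n)
  for (k in seq_len(nrow(spec))) {
    rows <- type == spec$type[k]
    needed[rows, ] <- matrix(c(spec$needed_m[k], spec$needed_t[k],
                               spec$needed_e[k], spec$needed_s[k]),
                             sum(rows), 4L, byrow = TRUE)
  }
  ops <- list(
    id = seq_len(n), type = type, alive = rep(TRUE, n),
    resources = as.numeric(rep(spec$resources, spec$count)),
    needed = needed,
    default = {
      d <- needed + matrix(d_uniform(4L * n, -1L, 1L), n, 4L)
      d[d < 0L] <- 0L
      d
    },
    maxa = sweep(needed, 2L, .MAX_OFFSETS, `+`),
    alloc = cat_matrix(n),
    wpos = matrix(d_uniform(4L * n, 1L, 3L), n, 4L,
                  dimnames = list(NULL, .CATS)),
    wneg = matrix(d_uniform(4L * n, 1L, 3L), n, 4L,
                  dimnames = list(NULL, .CATS)),
    delay = numeric(n),
    mobile = type %in% c("dive", "boat", "nearshore"),
    loc = rep(NA_integer_, n), base = rep(NA_integer_, n),
    sites = vector("list", n),
    maxc = numeric(n), contrib = numeric(n),
    t_enough = numeric(n), t_short = numeric(n), ticks_alive = numeric(n),
    bankrupt_tick = rep(NA_real_, n),
    lost_slr = rep(FALSE, n), bankrupted = rep(FALSE, n)
  )

  beach_cells <- which(grid$geo %in% .BEACH_CODES)
  front_cells <- which(grid$geo %in% .BEACHFRONT_CODES)

  # Land-based placement: hotels first, then beach operators.
  free <- beach_cells
  for (i in which(type %in% c("hotel", "beach"))) {
    if (length(free) == 0L) {
      stop("initialisation error: not enough vacant beach cells for ",
           "land-based operators")
    }
    cell <- pick_one(free)
    ops$loc[i] <- cell
    ops$base[i] <- cell
    free <- setdiff(free, cell)
  }
  hosted <- ops$loc[!is.na(ops$loc)]

  # Water-based land bases.
  for (ty in c("dive", "boat", "nearshore")) {
    members <- which(type == ty)
    members <- members[shuffled(length(members))]
    for (i in members) {
      taken <- ops$base[ops$type == ty & !is.na(ops$base)]
      if (ty == "dive") {
        preferred <- intersect(hosted, beach_cells)
        alternative <- beach_cells
        p_alt <- 0.1
      } else if (ty == "boat") {
        preferred <- intersect(hosted, front_cells)
        alternative <- front_cells
        p_alt <- 0.2
      } else {
        preferred <- front_cells
        alternative <- front_cells
        p_alt <- 0
      }
      preferred <- setdiff(preferred, taken)
      alternative <- setdiff(alternative, taken)
      pool <- if (p_alt > 0 && stats::runif(1) < p_alt) alternative else preferred
      if (length(pool) == 0L) pool <- alternative
      if (length(pool) == 0L) {
        ops$alive[i] <- FALSE  # no land base: leaves immediately
        next
      }
      cell <- pick_one(pool)
      ops$base[i] <- cell
      ops$loc[i] <- cell
    }
  }
  ops
}

#' Initialise directed links between operators
#'
#' Operators sharing a base get mutual links iff \code{links_to_my_base} is
#' TRUE; operators with neighbouring bases (or a shared base while the flag
#' is FALSE) get each directed link independently with probability
#' \code{link_chance}/100. Initial strengths are -0.10 between operators of
#' the same type and 0 otherwise.
#'
#' @param ops operator block.
#' @param grid a \code{coast_grid} (for base adjacency).
#' @param link_chance probability percentage in \[0, 10\].
#' @param links_to_my_base logical flag.
#' @return Square strength matrix (NA = no link), rows = observer.
#' @export
initialize_links <- function(ops, grid, link_chance, links_to_my_base) {
  n <- length(ops$id)
  lm <- matrix(NA_real_, n, n)
  alive <- which(ops$alive & !is.na(ops$base))
  pr <- link_chance / 100
  for (a in alive) {
    nb_a <- grid$nb[ops$base[a], ]
    for (b in alive) {
      if (a == b) next
      shared <- ops$base[a] == ops$base[b]
      make <- if (shared && links_to_my_base) {
        TRUE
      } else if (shared || ops$base[b] %in% nb_a) {
        stats::runif(1) < pr
      } else {
        FALSE
      }
      if (make) {
        lm[a, b] <- if (ops$type[a] == ops$type[b]) -0.10 else 0
      }
    }
  }
  lm
}

#' Move water-based operators to their initial water cell
#'
#' Dive operators prefer nearshore coastal or water's-edge cells with fish
#' and at least medium coral, then fish with some coral, then the water's
#' edge; boat operators take any nearshore coastal waters cell; nearshore
#' operators start at the water's edge of the coastline. Choice is uniform
#' within the best non-empty tier.
#'
#' @param ops operator block (bases assigned).
#' @param grid a \code{coast_grid}.
#' @return Updated operator block.
#' @export
place_water_operators <- function(ops, grid) {
  sea_near <- grid$geo %in% c(20L, 40L)
  dive_t1 <- which(sea_near & grid$init_fish & grid$init_coral >= 2L)
  dive_t2 <- which(sea_near & grid$init_fish & grid$init_coral >= 1L)
  edge <- which(grid$geo == 40L)
  nearshore_water <- which(grid$geo == 20L)
  for (i in which(ops$alive & ops$mobile)) {
    pool <- switch(ops$type[i],
      dive = if (length(dive_t1)) dive_t1 else
             if (length(dive_t2)) dive_t2 else edge,
      boat = nearshore_water,
      nearshore = edge)
    if (length(pool) == 0L) {
      stop("initialisation error: no candidate water cell for ", ops$type[i],
           " operator")
    }
    ops$loc[i] <- pick_one(pool)
    ops$sites[[i]] <- ops$loc[i]
  }
  ops
}

#' Initialise environmental-resource agents from map flags
#'
#' One fish/turtle/mangrove agent per flagged cell and one coral unit per
#' level of initial coral cover (capped at 3). All healths start at 0.50.
#'
#' @param grid a parsed \code{coast_grid}.
#' @return Resource block: list of parallel vectors \code{kind},
#'   \code{health}, \code{cell}, \code{alive}, \code{mobile}.
#' @export
initialize_env_resources <- function(grid) {
  fish <- which(grid$init_fish)
  turtle <- which(grid$init_turtle)
  mangrove <- which(grid$init_mangrove)
  cover <- pmin(grid$init_coral, 3L)
  coral <- rep(which(cover > 0L), cover[cover > 0L])
  kind <- c(rep("fish", length(fish)), rep("turtle", length(turtle)),
            rep("coral", length(coral)), rep("mangrove", length(mangrove)))
  res <- list(
    kind = kind,
    health = rep(0.5, length(kind)),
    cell = c(fish, turtle, coral, mangrove),
    alive = rep(TRUE, length(kind)),
    mobile = kind %in% c("fish", "turtle")
  )
  res
}

# Per-cell counts of living resources by kind.
resource_counts <- function(res, n_cells) {
  cnt <- function(kind) {
    tabulate(res$cell[res$alive & res$kind == kind], nbins = n_cells)
  }
  list(fish = cnt("fish"), turtle = cnt("turtle"),
       coral = cnt("coral"), mangrove = cnt("mangrove"))
}
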