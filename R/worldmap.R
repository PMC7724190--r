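# World map: the coded coastal grid, geospatial/biodiversity value tables,
# attractiveness, and the synthetic map generator.

# Geospatial catalogue. Elevation bounds are stored sorted (lo <= hi);
# negative elevations are depths below the initial sea level.
.GEO_CATALOG <- data.frame(
  code      = c(99L, 75L, 70L, 66L, 65L, 61L, 60L, 59L, 50L, 40L, 20L, 10L),
  name      = c("inland",
                "faraway sub-par beach", "faraway beach",
                "sub-par beach", "sub-par beachfront",
                "beach", "beachfront",
                "elevated beach space",
                "coastline", "water's edge",
                "nearshore coastal waters", "deep sea"),
  elev_lo   = c(10, 1.5, 1.5, 5, 1, 5, 1, 0, 0.25, 0, -15, -50),
  elev_hi   = c(100, 3.5, 3.5, 5, 3, 5, 3, 5, 1, 0, -5, -50),
  geo_value = c(0.00, 0.15, 0.20, 0.35, 0.55, 0.60, 0.80, 0.75, 1.00, 1.00,
                0.75, 0.00),
  stringsAsFactors = FALSE
)

.WATER_CODES     <- c(10L, 20L, 40L)
.BEACH_CODES     <- c(60L, 61L, 65L, 66L)
.COAST_CODES     <- c(40L, 50L, 59L)
.NEARSHORE_CODE  <- 20L
.BEACHFRONT_CODES <- c(60L, 65L)

#' Geospatial-type catalogue
#'
#' Returns the table of the twelve geospatial codes used in map files, with
#' the elevation interval (in meters, sorted so that \code{elev_lo <= elev_hi};
#' negative values are depths) and the geospatial attractiveness value
#' \code{geo_value} of each type.
#'
#' @return A data frame with columns \code{code}, \code{name}, \code{elev_lo},
#'   \code{elev_hi}, \code{geo_value}.
#' @export
geo_catalog <- function() .GEO_CATALOG

#' Geospatial attractiveness value of a code
#'
#' @param geo_code integer vector of 2-digit geospatial codes.
#' @return Numeric vector of Geo values in \[0, 1\].
#' @export
geo_value <- function(geo_code) {
  i <- match(geo_code, .GEO_CATALOG$code)
  if (anyNA(i)) {
    stop("unknown geospatial code(s): ",
         paste(unique(geo_code[is.na(i)]), collapse = ", "))
  }
  .GEO_CATALOG$geo_value[i]
}

#' Draw cell elevations for geospatial codes
#'
#' Elevation is uniform within the code-specific interval; codes with a
#' degenerate interval (deep sea, water's edge) always return the bound.
#'
#' @param geo_code integer vector of geospatial codes.
#' @return Numeric vector of elevations in meters (negative = depth).
#' @export
sample_elevation <- function(geo_code) {
  i <- match(geo_code, .GEO_CATALOG$code)
  if (anyNA(i)) {
    stop("unknown geospatial code(s): ",
         paste(unique(geo_code[is.na(i)]), collapse = ", "))
  }
  lo <- .GEO_CATALOG$elev_lo[i]
  hi <- .GEO_CATALOG$elev_hi[i]
  stats::runif(length(i), lo, hi)
}

#' Region of a geospatial code
#'
#' Partitions codes into the three reporting regions plus \code{"other"}:
#' beach (60, 61, 65, 66), coast (40, 50, 59), nearshore waters (20).
#'
#' @param geo_code integer vector of geospatial codes.
#' @return Character vector in \code{c("beach", "coast", "nearshore", "other")}.
#' @export
region_of <- function(geo_code) {
  out <- rep("other", length(geo_code))
  out[geo_code %in% .BEACH_CODES] <- "beach"
  out[geo_code %in% .COAST_CODES] <- "coast"
  out[geo_code == .NEARSHORE_CODE] <- "nearshore"
  out
}

is_water_code <- function(geo_code) geo_code %in% .WATER_CODES

# 8-neighbourhood (Moore) index matrix for a width x height row-major grid.
# Row i of the result lists the up-to-8 neighbours of cell i; NA off-grid.
neighbour_matrix <- function(width, height) {
  n <- width * height
  x <- (seq_len(n) - 1L) %% width
  y <- (seq_len(n) - 1L) %/% width
  offs <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  nb <- matrix(NA_integer_, n, 8L)
  for (k in 1:8) {
    nx <- x + offs[k, 1L]
    ny <- y + offs[k, 2L]
    ok <- nx >= 0L & nx < width & ny >= 0L & ny < height
    nb[ok, k] <- ny[ok] * width + nx[ok] + 1L
  }
  nb
}

#' Parse a map file
#'
#' The map dialect is a rectangle of whitespace-separated six-digit tokens,
#' one per cell, first text row at the top of the grid. Digits 1-2 are the
#' geospatial code, digit 3 encodes mangroves/fauna (8 mangroves, 3 fish and
#' turtles, 2 turtles only, 1 fish only, 0 none), digit 4 the coral cover
#' (0-3), digits 5-6 are reserved and ignored.
#'
#' @param text map-file content (single string or character vector of lines).
#' @return A \code{coast_grid}: a list with dimensions, per-cell vectors
#'   (geospatial code, initial fauna/coral flags, pollution, degradation,
#'   attractiveness, elevation) and the precomputed 8-neighbour index matrix.
#' @export
parse_map_text <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty map text")
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  width <- length(rows[[1]])
  toks <- character(0)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != width) {
      stop(sprintf("map format error: row %d has %d tokens, expected %d",
                   r, length(rows[[r]]), width))
    }
    bad <- !grepl("^[0-9]{6}$", rows[[r]])
    if (any(bad)) {
      c1 <- which(bad)[1]
      stop(sprintf("map format error: malformed token '%s' at row %d, column %d",
                   rows[[r]][c1], r, c1))
    }
    toks <- c(toks, rows[[r]])
  }
  height <- length(rows)
  geo <- as.integer(substr(toks, 1L, 2L))
  if (!all(geo %in% .GEO_CATALOG$code)) {
    bad <- which(!(geo %in% .GEO_CATALOG$code))[1]
    stop(sprintf("map catalogue error: unknown geospatial code %02d at row %d, column %d",
                 geo[bad], (bad - 1L) %/% width + 1L, (bad - 1L) %% width + 1L))
  }
  d3 <- as.integer(substr(toks, 3L, 3L))
  if (!all(d3 %in% c(0L, 1L, 2L, 3L, 8L))) {
    bad <- which(!(d3 %in% c(0L, 1L, 2L, 3L, 8L)))[1]
    stop(sprintf("map format error: invalid resource digit %d at row %d, column %d",
                 d3[bad], (bad - 1L) %/% width + 1L, (bad - 1L) %% width + 1L))
  }
  d4 <- as.integer(substr(toks, 4L, 4L))
  n <- width * height
  grid <- list(
    width = width, height = height, n = n,
    geo = geo,
    init_mangrove = d3 == 8L,
    init_fish = d3 %in% c(1L, 3L),
    init_turtle = d3 %in% c(2L, 3L),
    init_coral = d4,
    elevation = rep(NA_real_, n),
    pollution = numeric(n),
    degradation = numeric(n),
    attractiveness = numeric(n),
    event_age = rep(NA_real_, n),
    nb = neighbour_matrix(width, height)
  )
  class(grid) <- "coast_grid"
  grid
}

#' Generate a synthetic coastal map
#'
#' Produces a banded coastal layout in the map-file dialect: deep sea at the
#' top, then nearshore coastal waters, the water's edge, the coastline, a
#' beachfront row, a beach row, a faraway-beach row and inland. Fauna and
#' coral codes are sprinkled over the nearshore band and mangroves over parts
#' of the beachfront. The text is deterministic for a given seed and always
#' contains at least 45 beach/beachfront cells so that the full operator
#' population can be seated.
#'
#' @param width,height grid dimensions in cells (width >= 23, height >= 10).
#' @param seed integer seed controlling the sprinkled features.
#' @return A single string of map text; parseable by \code{parse_map_text}.
#' @export
generate_synthetic_map <- function(width = 30, height = 30, seed = 1) {
  if (width < 23 || height < 10) {
    stop(sprintf(paste0("map sizing error: need width >= 23 and height >= 10 ",
                        "for the banded layout (got %d x %d)"), width, height))
  }
  with_preserved_rng(seed, {
    n_deep <- max(1L, round(height * 0.2))
    n_fixed <- 5L  # water's edge, coastline, beachfront, beach, faraway rows
    n_inland <- max(1L, round(height * 0.25))
    n_near <- height - n_deep - n_fixed - n_inland
    if (n_near < 3L) {
      n_near <- 3L
      n_inland <- height - n_deep - n_fixed - n_near
    }
    row_geo <- c(rep(10L, n_deep), rep(20L, n_near), 40L, 50L, 0L, 0L, 0L,
                 rep(99L, n_inland))
    lines <- character(height)
    for (r in seq_len(height)) {
      g <- row_geo[r]
      if (g == 20L) {
        fauna <- sample(c(0L, 1L, 2L, 3L), width, replace = TRUE,
                        prob = c(0.55, 0.20, 0.10, 0.15))
        coral <- sample(0L:3L, width, replace = TRUE,
                        prob = c(0.50, 0.20, 0.15, 0.15))
        codes <- sprintf("%02d%d%d00", g, fauna, coral)
      } else if (g == 0L) {
        band <- r - (n_deep + n_near + 2L)  # 1 beachfront, 2 beach, 3 faraway
        base <- switch(band,
                       ifelse(stats::runif(width) < 0.8, 60L, 65L),
                       ifelse(stats::runif(width) < 0.8, 61L, 66L),
                       ifelse(stats::runif(width) < 0.8, 70L, 75L))
        fauna <- rep(0L, width)
        if (band == 1L) fauna[stats::runif(width) < 0.15] <- 8L
        codes <- sprintf("%02d%d000", base, fauna)
      } else {
        codes <- rep(sprintf("%02d0000", g), width)
      }
      lines[r] <- paste(codes, collapse = " ")
    }
    paste(lines, collapse = "\n")
  })
}

#' Perceived biodiversity value of a cell
#'
#' The Bio component of attractiveness, looked up from the land/sea context
#' and the resources present: on land only mangroves count; at sea the value
#' depends on coral abundance (3+ units abundant, 1-2 some, 0 none) and the
#' presence of fish and sea turtles.
#'
#' @param sea logical; is the cell a water cell?
#' @param mangrove logical; mangroves present (land context).
#' @param coral integer count of coral units present.
#' @param fish,turtle logical; fauna present (sea context).
#' @return Numeric vector of Bio values in \[0, 1\]. All arguments recycle.
#' @export
bio_value <- function(sea, mangrove = FALSE, coral = 0L, fish = FALSE,
                      turtle = FALSE) {
  k <- max(length(sea), length(mangrove), length(coral), length(fish),
           length(turtle))
  sea <- rep_len(sea, k); mangrove <- rep_len(mangrove, k)
  coral <- rep_len(coral, k); fish <- rep_len(fish, k)
  turtle <- rep_len(turtle, k)
  # rows: abundant / some / no coral; cols: fish+turtle, fish, turtle, neither
  sea_tab <- rbind(c(1.00, 0.85, 0.90, 0.70),
                   c(0.85, 0.75, 0.80, 0.30),
                   c(0.60, 0.30, 0.50, 0.00))
  lvl <- ifelse(coral >= 3L, 1L, ifelse(coral >= 1L, 2L, 3L))
  col <- ifelse(fish & turtle, 1L, ifelse(fish, 2L, ifelse(turtle, 3L, 4L)))
  out <- ifelse(mangrove, 0.20, 0.00)
  out[sea] <- sea_tab[cbind(lvl[sea], col[sea])]
  out
}

#' Environmental attractiveness of a cell
#'
#' Att = 0.5 + Wgeo * Geo + Wbio * Bio - Wpol * Pol - Wenv * Env, where Pol is
#' the pollution level capped at 1 and Env the environmental degradation. The
#' result is clamped to \[0, 1\].
#'
#' @param geo Geo value of the cell (see \code{geo_value}).
#' @param bio Bio value of the cell (see \code{bio_value}).
#' @param pollution pollution level (>= 0; capped at 1 inside the formula).
#' @param degradation environmental degradation in \[0, 1\].
#' @param Wgeo,Wbio,Wpol,Wenv attractiveness weights.
#' @return Numeric vector of attractiveness values in \[0, 1\].
#' @export
compute_attractiveness <- function(geo, bio, pollution, degradation,
                                   Wgeo, Wbio, Wpol, Wenv) {
  att <- 0.5 + Wgeo * geo + Wbio * bio -
    Wpol * pmin(pollution, 1) - Wenv * degradation
  pmin(1, pmax(0, att))
}

# Recompute attractiveness for every cell of a grid, with resource presence
# supplied as per-cell counts (fish, turtle, coral, mangrove).
recompute_attractiveness <- function(grid, counts, params) {
  bio <- bio_value(sea = is_water_code(grid$geo),
                   mangrove = counts$mangrove > 0L,
                   coral = counts$coral,
                   fish = counts$fish > 0L,
                   turtle = counts$turtle > 0L)
  grid$attractiveness <- compute_attractiveness(
    geo_value(grid$geo), bio, grid$pollution, grid$degradation,
    Wgeo = params$geospatial_weight, Wbio = params$biodiversity_weight,
    Wpol = params$pollution_weight, Wenv = params$enviro_degradation_weight)
  grid
}

#' @export
print.coast_grid <- function(x, ...) {
  cat(sprintf("<coast_grid %d x %d cells>\n", x$width, x$height))
  tab <- table(factor(region_of(x$geo),
                      levels = c("beach", "coast", "nearshore", "other")))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
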