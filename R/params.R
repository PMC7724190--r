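# Model parameters: canonical table of names, types and ranges; defaults;
# YAML configuration support. Config files and experiment designs use the
# hyphenated model-code names; inside R the same parameters are addressed
# with underscores.

.PARAM_TABLE <- data.frame(
  name = c("tourism-returns", "revenue-limited?",
           "enviro-degradation-income-penalty", "maintenance-penalty",
           "pollution-penalty", "neighbor-pollution-penalty",
           "neighbor-pollution-threshold", "link-chance", "links-to-my-base?",
           "negative-association", "positive-association",
           "geospatial-weight", "biodiversity-weight", "pollution-weight",
           "enviro-degradation-weight", "marine-life-sensitivity",
           "pollution-change", "pollution-diffusion-rate",
           "pollution-clean-up", "pollution-threshold", "cost-pollution",
           "SLR-increase", "linear-SLR?", "min-acceptable-elevation-above-SL",
           "increased-elevation", "erosion-loss", "cost-SLR",
           "sudden-event-interval", "patches-affected-sudden-event",
           "enviro-deg-from-sudden-event", "acceptable-enviro-degradation",
           "cost-extreme-event", "sudden-event-persistence",
           "seed-for-random"),
  type = c("float", "boolean", "integer", "float", "float", "float",
           "integer", "float", "boolean", "float", "float", "float", "float",
           "float", "float", "float", "float", "float", "float", "float",
           "integer", "float", "boolean", "float", "float", "float",
           "integer", "integer", "float", "float", "float", "integer",
           "integer", "integer"),
  lo = c(2, 0, 0, 0, 0, 0, 4, 0, 0, 0.01, 0.01, 0, 0, 0, 0, 0.10, 0.01, 0.01,
         0.01, 0, 1, 0, 0, 0.20, 0.2, 0, 5, 35, 0, 0, 0, 5, 1, 0),
  hi = c(5, 1, 5, 3, 10, 5, 8, 10, 1, 0.25, 0.20, 0.5, 0.5, 1, 1, 0.50, 0.50,
         0.25, 0.10, 0.5, 20, 50, 1, 1.00, 1.0, 0.25, 50, 350, 10, 1, 0.50,
         50, 10, 2147483646),
  stringsAsFactors = FALSE
)

config_to_r_name <- function(x) gsub("\\?$", "", gsub("-", "_", x))

#' Parameter space of the model
#'
#' The 34 model parameters with their types (float, integer, boolean) and
#' ranges, including the technical \code{seed-for-random} parameter used to
#' treat stochasticity as a sampled dimension in sensitivity analysis.
#'
#' @param include_seed keep the \code{seed-for-random} row (default TRUE).
#' @return Data frame with columns \code{name} (model-code spelling),
#'   \code{r_name}, \code{type}, \code{lo}, \code{hi}.
#' @export
parameter_space <- function(include_seed = TRUE) {
  tab <- .PARAM_TABLE
  tab$r_name <- config_to_r_name(tab$name)
  if (!include_seed) tab <- tab[tab$name != "seed-for-random", ]
  tab[, c("name", "r_name", "type", "lo", "hi")]
}

#' Model parameter set
#'
#' Builds a validated parameter list. Defaults are the midpoints of the
#' parameter ranges (booleans: revenue unlimited, links to shared bases on,
#' linear sea-level rise), a neutral baseline for exploration.
#'
#' @param ... overrides by R name (underscores) or model-code name (hyphens),
#'   e.g. \code{tourism_returns = 4} or \code{`SLR-increase` = 35}.
#' @param .list optional list of overrides, same naming rules.
#' @return Named list of class \code{coast_params}.
#' @export
coast_params <- function(..., .list = NULL) {
  defaults <- list(
    tourism_returns = 3.5, revenue_limited = FALSE,
    enviro_degradation_income_penalty = 2L, maintenance_penalty = 1.5,
    pollution_penalty = 5, neighbor_pollution_penalty = 2.5,
    neighbor_pollution_threshold = 6L, link_chance = 5,
    links_to_my_base = TRUE, negative_association = 0.13,
    positive_association = 0.10, geospatial_weight = 0.25,
    biodiversity_weight = 0.25, pollution_weight = 0.5,
    enviro_degradation_weight = 0.5, marine_life_sensitivity = 0.30,
    pollution_change = 0.25, pollution_diffusion_rate = 0.13,
    pollution_clean_up = 0.05, pollution_threshold = 0.25,
    cost_pollution = 10L, SLR_increase = 25, linear_SLR = TRUE,
    min_acceptable_elevation_above_SL = 0.60, increased_elevation = 0.6,
    erosion_loss = 0.12, cost_SLR = 27L, sudden_event_interval = 192L,
    patches_affected_sudden_event = 5, enviro_deg_from_sudden_event = 0.5,
    acceptable_enviro_degradation = 0.25, cost_extreme_event = 27L,
    sudden_event_persistence = 5L, seed_for_random = 42L
  )
  overrides <- c(list(...), .list)
  if (length(overrides)) {
    names(overrides) <- config_to_r_name(names(overrides))
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  validate_params(p)
  class(p) <- "coast_params"
  p
}

validate_params <- function(p) {
  tab <- parameter_space()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$r_name[i]
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' missing or not a scalar")
    }
    if (tab$type[i] == "boolean") {
      if (!is.logical(v)) stop("parameter '", nm, "' must be TRUE/FALSE")
    } else {
      if (v < tab$lo[i] || v > tab$hi[i]) {
        stop(sprintf("parameter '%s' = %s outside its range [%s, %s]",
                     nm, format(v), format(tab$lo[i]), format(tab$hi[i])))
      }
      if (tab$type[i] == "integer" && v != floor(v)) {
        stop("parameter '", nm, "' must be an integer")
      }
    }
  }
  invisible(TRUE)
}

#' Read model parameters from a YAML configuration file
#'
#' Keys use the model-code parameter names (e.g. \code{tourism-returns},
#' \code{revenue-limited?}); unspecified parameters take their defaults.
#'
#' @param path path to the YAML file.
#' @return A \code{coast_params} list.
#' @export
params_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must be a YAML mapping")
  coast_params(.list = cfg)
}

#' @export
print.coast_params <- function(x, ...) {
  cat("<coast_params>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}
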