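# Experiment harness: Saltelli sampling with Sobol variance-based
# sensitivity indices, Latin hypercube designs, a restartable batch runner,
# failure-scenario classification, and PRIM scenario discovery.

decode_unit_matrix <- function(u, space) {
  out <- as.data.frame(matrix(NA_real_, nrow(u), nrow(space)))
  names(out) <- space$name
  for (j in seq_len(nrow(space))) {
    lo <- space$lo[j]; hi <- space$hi[j]
    out[[j]] <- switch(space$type[j],
      float = lo + u[, j] * (hi - lo),
      integer = pmin(hi, floor(lo + u[, j] * (hi - lo + 1))),
      boolean = as.numeric(u[, j] >= 0.5),
      stop("unknown parameter type: ", space$type[j]))
  }
  out
}

#' Saltelli sample design for Sobol sensitivity analysis
#'
#' Builds the cross-sampled block design of the Saltelli scheme: base
#' matrices A and B plus the AB_i (and, with second-order indices, BA_i)
#' matrices, 2n(p+1) rows in total with second order and n(p+2) without.
#' Boolean parameters are sampled on \[0, 1\] and thresholded at 0.5; integer
#' parameters are sampled continuously and floored.
#'
#' @param space parameter space as from \code{parameter_space()} (columns
#'   \code{name}, \code{type}, \code{lo}, \code{hi}).
#' @param n sampling rate (number of base samples; powers of two
#'   recommended).
#' @param second_order generate the matrices needed for second-order
#'   indices (default TRUE).
#' @param seed RNG seed for the design.
#' @return A \code{saltelli_design}: list with \code{design} (decoded data
#'   frame), \code{n}, \code{p}, \code{second_order}, \code{space}.
#' @export
saltelli_design <- function(space, n, second_order = TRUE, seed = 1) {
  p <- nrow(space)
  if (p == 0L) stop("empty parameter space")
  u <- with_preserved_rng(seed, {
    A <- matrix(stats::runif(n * p), n, p)
    B <- matrix(stats::runif(n * p), n, p)
    blocks <- list(A)
    for (i in seq_len(p)) {
      ABi <- A; ABi[, i] <- B[, i]
      blocks[[length(blocks) + 1L]] <- ABi
    }
    if (second_order) {
      for (i in seq_len(p)) {
        BAi <- B; BAi[, i] <- A[, i]
        blocks[[length(blocks) + 1L]] <- BAi
      }
    }
    blocks[[length(blocks) + 1L]] <- B
    do.call(rbind, blocks)
  })
  out <- list(design = decode_unit_matrix(u, space), n = n, p = p,
              second_order = second_order, space = space)
  class(out) <- "saltelli_design"
  out
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat(sprintf("<saltelli_design: %d rows (n=%d, p=%d, second_order=%s)>\n",
              nrow(x$design), x$n, x$p, x$second_order))
  invisible(x)
}

#' Sobol sensitivity indices from a Saltelli design
#'
#' Variance-based first-order (S1), total-order (ST) and — when the design
#' carries the BA blocks — second-order (S2) indices, using the Saltelli
#' first-order estimator, the Jansen total-order estimator, and bootstrap
#' confidence intervals over the base samples. A constant model output has
#' no variance to decompose; all indices are reported as 0 with a warning
#' (useful as a wiring check: a parameter that cannot move the output at all
#' usually indicates a coding error).
#'
#' @param design a \code{saltelli_design}.
#' @param y numeric model outputs, one per design row, in design order.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param conf confidence level.
#' @return List with \code{S1}, \code{S1_conf}, \code{ST}, \code{ST_conf},
#'   \code{S2} (matrix or NULL), named by parameter.
#' @export
sobol_analyze <- function(design, y, n_boot = 100, conf = 0.95) {
  stopifnot(inherits(design, "saltelli_design"))
  n <- design$n; p <- design$p
  expected <- if (design$second_order) n * (2 * p + 2) else n * (p + 2)
  if (length(y) != expected) {
    stop(sprintf("output length %d does not match design rows %d",
                 length(y), expected))
  }
  nms <- design$space$name
  fA <- y[seq_len(n)]
  fAB <- matrix(y[n + seq_len(n * p)], n, p)
  off <- n * (p + 1L)
  fBA <- NULL
  if (design$second_order) {
    fBA <- matrix(y[off + seq_len(n * p)], n, p)
    off <- off + n * p
  }
  fB <- y[off + seq_len(n)]

  est <- function(idx) {
    V <- stats::var(c(fA[idx], fB[idx]))
    if (!is.finite(V) || V <= .Machine$double.eps) return(NULL)
    S1 <- colMeans(fB[idx] * (fAB[idx, , drop = FALSE] - fA[idx])) / V
    ST <- 0.5 * colMeans((fA[idx] - fAB[idx, , drop = FALSE])^2) / V
    list(S1 = S1, ST = ST, V = V)
  }
  full <- est(seq_len(n))
  if (is.null(full)) {
    warning("constant model output: all sensitivity indices reported as 0")
    z <- stats::setNames(numeric(p), nms)
    return(list(S1 = z, S1_conf = z, ST = z, ST_conf = z,
                S2 = if (design$second_order)
                  matrix(0, p, p, dimnames = list(nms, nms)) else NULL))
  }
  boots1 <- matrix(NA_real_, n_boot, p)
  bootst <- matrix(NA_real_, n_boot, p)
  for (b in seq_len(n_boot)) {
    e <- est(sample.int(n, replace = TRUE))
    if (!is.null(e)) {
      boots1[b, ] <- e$S1
      bootst[b, ] <- e$ST
    }
  }
  zq <- stats::qnorm(0.5 + conf / 2)
  S2 <- NULL
  if (design$second_order) {
    S2 <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        Vij <- mean(fBA[, i] * fAB[, j] - fA * fB) / full$V
        S2[i, j] <- S2[j, i] <- Vij - full$S1[i] - full$S1[j]
      }
    }
  }
  list(S1 = stats::setNames(full$S1, nms),
       S1_conf = stats::setNames(zq * apply(boots1, 2, stats::sd,
                                            na.rm = TRUE), nms),
       ST = stats::setNames(full$ST, nms),
       ST_conf = stats::setNames(zq * apply(bootst, 2, stats::sd,
                                            na.rm = TRUE), nms),
       S2 = S2)
}

#' Latin hypercube design over a parameter space
#'
#' One sample per equal-probability stratum per column, decoded to the
#' parameter types like \code{saltelli_design}.
#'
#' @param space parameter space (see \code{parameter_space}).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return Data frame with one decoded column per parameter.
#' @export
lhs_design <- function(space, n, seed = 1) {
  u <- with_preserved_rng(seed, lhs::randomLHS(n, nrow(space)))
  decode_unit_matrix(u, space)
}

#' Run a design of simulation experiments, restartably
#'
#' Executes the model once per design row and replication (averaging
#' outcomes over replications), recording every model output at the
#' requested ticks plus the failure-scenario flags. With an output file
#' each completed row is flushed immediately, and an interrupted batch
#' resumes by skipping the rows already present in the file.
#'
#' @param design data frame of parameter values (model-code column names;
#'   columns not naming parameters are ignored) or a
#'   \code{saltelli_design}.
#' @param map_text map-file content used for every run.
#' @param ticks simulation length per run.
#' @param replications runs per design row (seeds derived from
#'   \code{base_seed} unless the design has a \code{seed-for-random}
#'   column).
#' @param base_seed base for derived per-run seeds.
#' @param out_file optional CSV path for incremental results.
#' @param record_at ticks at which to record outputs (default: final tick).
#' @return Data frame with one result row per design row.
#' @export
run_batch <- function(design, map_text, ticks, replications = 1,
                      base_seed = 1, out_file = NULL,
                      record_at = ticks) {
  if (inherits(design, "saltelli_design")) design <- design$design
  space <- parameter_space()
  par_cols <- intersect(names(design), space$name)
  done <- integer(0)
  results <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    results <- utils::read.csv(out_file, check.names = FALSE)
    done <- results$row
  }
  rows <- setdiff(seq_len(nrow(design)), done)
  for (r in rows) {
    overrides <- as.list(design[r, par_cols, drop = FALSE])
    has_seed <- "seed-for-random" %in% par_cols
    int_pars <- space$name[space$type == "integer"]
    bool_pars <- space$name[space$type == "boolean"]
    for (nm in intersect(par_cols, int_pars)) {
      overrides[[nm]] <- as.integer(floor(overrides[[nm]]))
    }
    for (nm in intersect(par_cols, bool_pars)) {
      overrides[[nm]] <- overrides[[nm]] >= 0.5
    }
    rep_rows <- vector("list", replications)
    for (k in seq_len(replications)) {
      seed <- if (has_seed) {
        (as.integer(overrides[["seed-for-random"]]) + k - 1L) %% 2147483647L
      } else {
        (base_seed + (r - 1L) * replications + (k - 1L)) %% 2147483647L
      }
      overrides[["seed-for-random"]] <- seed
      rep_rows[[k]] <- tryCatch({
        run <- coast_run(coast_params(.list = overrides), map_text, ticks)
        s <- run$series
        vals <- list(`m-all-ops-first` = s[["m-all-ops"]][1],
                     `m-av-now-attr-area-first` = s[["m-av-now-attr-area"]][1])
        for (t in record_at) {
          sr <- s[s$tick == t, , drop = FALSE]
          sfx <- if (length(record_at) > 1L) paste0("@", t) else ""
          for (cn in setdiff(names(sr), "tick")) {
            vals[[paste0(cn, sfx)]] <- sr[[cn]][1]
          }
        }
        vals
      }, error = function(e) NULL)
    }
    ok <- !vapply(rep_rows, is.null, logical(1))
    if (any(ok)) {
      keep <- rep_rows[ok]
      avg <- lapply(names(keep[[1]]), function(cn) {
        mean(vapply(keep, function(v) as.numeric(v[[cn]]), numeric(1)))
      })
      names(avg) <- names(keep[[1]])
      last_sfx <- if (length(record_at) > 1L) {
        paste0("@", record_at[length(record_at)])
      } else ""
      mini <- data.frame(check.names = FALSE,
        `m-av-now-attr-area` = c(avg[["m-av-now-attr-area-first"]],
                                 avg[[paste0("m-av-now-attr-area", last_sfx)]]),
        `m-all-ops` = c(avg[["m-all-ops-first"]],
                        avg[[paste0("m-all-ops", last_sfx)]]))
      fl <- classify_failure(mini)
      row_out <- c(list(row = r, status = "ok", replications = sum(ok)),
                   as.list(design[r, par_cols, drop = FALSE]), avg,
                   list(`ecological-failure` = as.integer(fl$ecological),
                        `economic-failure` = as.integer(fl$economic),
                        `combined-failure` = as.integer(fl$combined)))
    } else {
      row_out <- c(list(row = r, status = "error", replications = 0),
                   as.list(design[r, par_cols, drop = FALSE]))
    }
    row_df <- as.data.frame(row_out, check.names = FALSE, optional = TRUE)
    names(row_df) <- names(row_out)
    if (!is.null(out_file)) {
      utils::write.table(row_df, out_file, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_file), append =
                           file.exists(out_file), qmethod = "double")
      results <- if (is.null(results)) row_df else
        merge_result_rows(results, row_df)
    } else {
      results <- if (is.null(results)) row_df else
        merge_result_rows(results, row_df)
    }
  }
  if (!is.null(results)) results <- results[order(results$row), ]
  results
}

merge_result_rows <- function(a, b) {
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
  rbind(a, b[names(a)])
}

#' Classify a run as ecological and/or economic failure
#'
#' Compares the first and last values of the series: ecological failure is
#' a relative drop of more than 25\% in area attractiveness
#' (\code{m-av-now-attr-area}); economic failure a drop of at least 75\% in
#' operators in business (\code{m-all-ops}); combined failure is both.
#'
#' @param series data frame holding at least the two output columns.
#' @return \code{list(ecological, economic, combined)} of logicals.
#' @export
classify_failure <- function(series) {
  need <- c("m-av-now-attr-area", "m-all-ops")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("series lacks column(s): ", paste(miss, collapse = ", "))
  }
  attr0 <- series[["m-av-now-attr-area"]][1]
  attr1 <- series[["m-av-now-attr-area"]][nrow(series)]
  ops0 <- series[["m-all-ops"]][1]
  ops1 <- series[["m-all-ops"]][nrow(series)]
  ecological <- (attr0 - attr1) / attr0 > 0.25
  economic <- (ops0 - ops1) / ops0 >= 0.75
  list(ecological = ecological, economic = economic,
       combined = ecological && economic)
}

points_in_limits <- function(X, lo, hi) {
  inb <- rep(TRUE, nrow(X))
  for (j in seq_along(lo)) {
    inb <- inb & X[[j]] >= lo[j] & X[[j]] <= hi[j]
  }
  inb
}

#' Scenario discovery with the Patient Rule Induction Method
#'
#' Iteratively peels small fractions of the data from one face of the box at
#' a time, maximising — by default — a lenient objective (density gain per
#' fraction of points peeled, which does not require a monotone density
#' improvement), selects the densest box on the peeling trajectory, and
#' pastes faces back while doing so does not reduce density. Further boxes
#' are induced on the points outside earlier boxes until positives are
#' exhausted or a box no better than the base rate appears.
#'
#' @param inputs data frame of numeric inputs (one column per dimension).
#' @param labels logical vector of cases of interest.
#' @param peel_alpha fraction peeled per step (default 0.05).
#' @param mass_min minimum fraction of points a box may hold.
#' @param lenient_objective use the lenient gain-per-peel objective
#'   (default TRUE); otherwise greedy density.
#' @param max_boxes maximum number of boxes to induce.
#' @return List of \code{prim_box} objects, each with \code{limits} (the
#'   restricted dimensions with their bounds), \code{coverage} (positives in
#'   box / all positives), \code{density} (positives in box / points in box)
#'   and \code{mass}.
#' @export
prim_discover <- function(inputs, labels, peel_alpha = 0.05,
                          mass_min = 0.05, lenient_objective = TRUE,
                          max_boxes = 5) {
  stopifnot(nrow(inputs) == length(labels))
  X <- as.data.frame(lapply(inputs, as.numeric))
  names(X) <- names(inputs)
  y <- as.logical(labels)
  total_pos <- sum(y)
  if (total_pos == 0L) return(list())
  remaining <- seq_len(nrow(X))
  boxes <- list()
  while (length(boxes) < max_boxes) {
    Xr <- X[remaining, , drop = FALSE]
    yr <- y[remaining]
    if (!any(yr)) break
    base_rate <- mean(yr)
    box <- peel_box(Xr, yr, peel_alpha, mass_min, lenient_objective)
    box <- paste_box(Xr, yr, box, peel_alpha)
    inb <- points_in_limits(Xr, box$lo, box$hi)
    n_pos <- sum(yr[inb])
    density <- n_pos / sum(inb)
    if (n_pos == 0L || density <= base_rate) break
    glob_lo <- vapply(X, min, numeric(1))
    glob_hi <- vapply(X, max, numeric(1))
    restricted <- which(box$lo > glob_lo | box$hi < glob_hi)
    limits <- data.frame(dim = names(X)[restricted],
                         lo = box$lo[restricted], hi = box$hi[restricted],
                         stringsAsFactors = FALSE)
    pb <- list(limits = limits, lo = box$lo, hi = box$hi,
               coverage = n_pos / total_pos, density = density,
               mass = sum(inb) / nrow(X), n_in = sum(inb), n_pos = n_pos)
    class(pb) <- "prim_box"
    boxes[[length(boxes) + 1L]] <- pb
    remaining <- remaining[!inb]
    if (length(remaining) == 0L) break
  }
  boxes
}

peel_box <- function(X, y, alpha, mass_min, lenient) {
  p <- ncol(X)
  lo <- vapply(X, min, numeric(1))
  hi <- vapply(X, max, numeric(1))
  inb <- rep(TRUE, nrow(X))
  n_total <- nrow(X)
  best <- list(lo = lo, hi = hi, density = mean(y), mass = 1)
  repeat {
    n_in <- sum(inb)
    if (n_in <= max(2, ceiling(mass_min * n_total))) break
    cur_mean <- mean(y[inb])
    cand <- NULL
    for (j in seq_len(p)) {
      xj <- X[[j]][inb]
      for (side in c("lo", "hi")) {
        q <- if (side == "lo") stats::quantile(xj, alpha, names = FALSE) else
          stats::quantile(xj, 1 - alpha, names = FALSE)
        keep <- if (side == "lo") X[[j]] >= q else X[[j]] <= q
        new_in <- inb & keep
        removed <- n_in - sum(new_in)
        if (removed == 0L || sum(new_in) == 0L) next
        new_mean <- mean(y[new_in])
        obj <- if (lenient) (new_mean - cur_mean) / (removed / n_in) else
          new_mean
        if (is.null(cand) || obj > cand$obj) {
          cand <- list(obj = obj, j = j, side = side, q = q, new_in = new_in)
        }
      }
    }
    if (is.null(cand)) break
    if (cand$side == "lo") lo[cand$j] <- cand$q else hi[cand$j] <- cand$q
    inb <- cand$new_in
    d <- mean(y[inb])
    m <- sum(inb) / n_total
    if (m < mass_min) break
    if (d > best$density || (d == best$density && m > best$mass)) {
      best <- list(lo = lo, hi = hi, density = d, mass = m)
    }
  }
  best
}

paste_box <- function(X, y, box, alpha) {
  lo <- box$lo; hi <- box$hi
  repeat {
    inb <- points_in_limits(X, lo, hi)
    n_in <- sum(inb)
    cur <- mean(y[inb])
    improved <- FALSE
    for (j in seq_len(ncol(X))) {
      step <- max(1L, ceiling(alpha * n_in))
      below <- sort(unique(X[[j]][X[[j]] < lo[j]]), decreasing = TRUE)
      if (length(below)) {
        new_lo <- below[min(step, length(below))]
        cand <- inb | (points_in_limits(X, replace(lo, j, new_lo), hi))
        if (mean(y[cand]) >= cur && sum(cand) > n_in) {
          lo[j] <- new_lo
          improved <- TRUE
          next
        }
      }
      above <- sort(unique(X[[j]][X[[j]] > hi[j]]))
      if (length(above)) {
        new_hi <- above[min(step, length(above))]
        cand <- inb | (points_in_limits(X, lo, replace(hi, j, new_hi)))
        if (mean(y[cand]) >= cur && sum(cand) > n_in) {
          hi[j] <- new_hi
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(lo = lo, hi = hi)
}

#' @export
print.prim_box <- function(x, ...) {
  cat(sprintf("<prim_box coverage %.1f%%, density %.1f%%, mass %.1f%%>\n",
              100 * x$coverage, 100 * x$density, 100 * x$mass))
  if (nrow(x$limits)) {
    for (k in seq_len(nrow(x$limits))) {
      cat(sprintf("  %s in [%.4g, %.4g]\n", x$limits$dim[k],
                  x$limits$lo[k], x$limits$hi[k]))
    }
  } else {
    cat("  (no restricted dimensions)\n")
  }
  invisible(x)
}
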