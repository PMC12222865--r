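# Producibility metric (PM): robustness of a metabolite's biosynthesis to
# environmental composition. Exchangeable metabolites are supplied
# independently with probability P_in; P_out is the probability that the
# target can carry flux through a demand reaction. PM = 1 - P_in,0.5,
# where P_in,0.5 is the inclusion probability at which P_out crosses 0.5.

# Append an unbounded demand (sink) reaction for the target metabolite.
.with_demand <- function(model, target) {
  if (!target %in% model$metabolites$id)
    stop("unknown target metabolite: ", target)
  did <- paste0("DM__", target)
  if (!did %in% names(model$reactions)) {
    model$reactions[[did]] <- list(id = did,
                                   stoich = stats::setNames(-1, target),
                                   lb = 0, ub = 1000)
  }
  list(model = model, demand = did)
}

#' Sample a random environment
#'
#' Each exchangeable (environmental) metabolite of the model is included
#' independently with probability `p_in`, using the caller's RNG state, so
#' results are reproducible after `set.seed()`.
#'
#' @param model a `metabolic_model`.
#' @param p_in inclusion probability in `[0, 1]`.
#' @return character vector of included metabolite ids.
#' @export
sample_environment <- function(model, p_in) {
  stopifnot(p_in >= 0, p_in <= 1)
  env <- names(exchange_reactions(model))
  env[stats::runif(length(env)) < p_in]
}

#' Can a model produce a target metabolite in a given environment?
#'
#' Appends a demand reaction for the target if absent, opens uptake for
#' exactly the listed medium components, and asks FBA whether the demand
#' can carry flux above the feasibility tolerance.
#'
#' @param model a `metabolic_model`.
#' @param target metabolite id.
#' @param medium character vector of supplied environmental metabolites.
#' @param uptake_bound uptake capacity per supplied metabolite.
#' @param tol feasibility tolerance on the demand flux.
#' @return `TRUE` or `FALSE`.
#' @export
producible <- function(model, target, medium, uptake_bound = 10,
                       tol = 1e-6) {
  wd <- .with_demand(model, target)
  m <- set_medium(wd$model, intersect(medium,
                                      names(exchange_reactions(wd$model))),
                  uptake_bound = uptake_bound)
  sol <- fba(m, maximize = wd$demand)
  sol$status == "optimal" && sol$objective_value > tol
}

#' Monte-Carlo producibility curve of a target metabolite
#'
#' Estimates P_out over a grid of P_in values by sampling `n_samples`
#' random environments per grid point and testing producibility with FBA.
#' Environments are drawn from per-point seeds derived from `seed`, so the
#' curve is fully deterministic; repeated environments are solved once and
#' memoized.
#'
#' @param model a `metabolic_model`.
#' @param target metabolite id.
#' @param grid strictly increasing P_in values in `[0, 1]` (default 21
#'   evenly spaced points).
#' @param n_samples Monte-Carlo draws per grid point (default 500).
#' @param seed master seed.
#' @param uptake_bound uptake capacity per supplied metabolite.
#' @return a `producibility_curve`: `metabolite_id`, `model_id`,
#'   `p_in_grid`, `p_out_hat`, `n_samples`, `seed`.
#' @export
producibility_curve <- function(model, target, grid = seq(0, 1, by = 0.05),
                                n_samples = 500, seed = 1,
                                uptake_bound = 10) {
  stopifnot(n_samples >= 1, all(diff(grid) > 0),
            grid[1] >= 0, grid[length(grid)] <= 1)
  wd <- .with_demand(model, target)
  env <- names(exchange_reactions(wd$model))
  cache <- new.env(parent = emptyenv())
  test_medium <- function(inc) {
    key <- paste0("k", paste(inc, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- producible(wd$model, target, env[inc],
                      uptake_bound = uptake_bound)
    cache[[key]] <- val
    val
  }
  p_out <- vapply(seq_along(grid), function(gi) {
    with_seed(derive_seed(seed, gi), {
      hits <- vapply(seq_len(n_samples), function(s) {
        inc <- which(stats::runif(length(env)) < grid[gi])
        test_medium(inc)
      }, NA)
      mean(hits)
    })
  }, 0)
  structure(list(metabolite_id = target, model_id = model$id,
                 p_in_grid = grid, p_out_hat = p_out,
                 n_samples = n_samples, seed = seed),
            class = "producibility_curve")
}

#' @export
print.producibility_curve <- function(x, ...) {
  cat("<producibility_curve> ", x$metabolite_id, " in ", x$model_id,
      " (", length(x$p_in_grid), " grid points x ", x$n_samples,
      " samples, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.producibility_curve <- function(x, ...) {
  iso <- stats::isoreg(x$p_in_grid, x$p_out_hat)
  graphics::plot(x$p_in_grid, x$p_out_hat, xlab = "P_in", ylab = "P_out",
                 ylim = c(0, 1), main = paste(x$metabolite_id, "in",
                                              x$model_id), ...)
  graphics::lines(x$p_in_grid, iso$yf, col = "red3")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Producibility metric from a curve
#'
#' Applies isotonic regression to the Monte-Carlo estimates (P_out is
#' non-decreasing in P_in in expectation), locates the half-production
#' point P_in,0.5 by linear interpolation of the monotone curve, and
#' returns PM = 1 - P_in,0.5. A curve entirely at or above 0.5 gives
#' P_in,0.5 = 0 (PM 1); entirely below, P_in,0.5 = 1 (PM 0).
#'
#' @param curve a `producibility_curve` covering `[0, 1]`.
#' @return a `pm_result`: `metabolite_id`, `model_id`, `p_in_half`, `pm`.
#' @export
pm_score <- function(curve) {
  x <- curve$p_in_grid
  y <- curve$p_out_hat
  if (length(x) == 0) stop("empty producibility curve")
  yf <- stats::isoreg(x, y)$yf
  p_half <- if (yf[1] >= 0.5) {
    0
  } else if (yf[length(yf)] < 0.5) {
    1
  } else {
    i <- which(yf >= 0.5)[1]
    x[i - 1] + (0.5 - yf[i - 1]) / (yf[i] - yf[i - 1]) * (x[i] - x[i - 1])
  }
  structure(list(metabolite_id = curve$metabolite_id,
                 model_id = curve$model_id,
                 p_in_half = p_half, pm = 1 - p_half),
            class = "pm_result")
}

#' @export
print.pm_result <- function(x, ...) {
  cat("<pm_result> ", x$metabolite_id, " in ", x$model_id,
      ": PM = ", format(x$pm, digits = 4),
      " (P_in,0.5 = ", format(x$p_in_half, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Producibility panel across models and targets
#'
#' Computes PM for every model x target cell. Per-cell seeds are derived
#' from the master seed and a cell counter, so any sub-panel is
#' reproducible independently. Targets absent from a model are recorded as
#' `NA`, not 0.
#'
#' @param models named list of `metabolic_model`s.
#' @param targets character vector of metabolite ids.
#' @inheritParams producibility_curve
#' @return numeric matrix (models x targets) of PM values in `[0, 1]`.
#' @export
pm_panel <- function(models, targets, grid = seq(0, 1, by = 0.05),
                     n_samples = 500, seed = 1, uptake_bound = 10) {
  ids <- vapply(models, `[[`, "", "id")
  names(models) <- ids
  out <- matrix(NA_real_, length(ids), length(targets),
                dimnames = list(ids, targets))
  cell <- 0L
  for (mi in seq_along(ids)) {
    for (ti in seq_along(targets)) {
      cell <- cell + 1L
      if (!targets[ti] %in% models[[mi]]$metabolites$id) next
      cur <- producibility_curve(models[[mi]], targets[ti], grid = grid,
                                 n_samples = n_samples,
                                 seed = derive_seed(seed, cell),
                                 uptake_bound = uptake_bound)
      out[mi, ti] <- pm_score(cur)$pm
    }
  }
  out
}
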