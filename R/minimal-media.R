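# Minimal growth media by mixed-integer optimization.
#
# The MILP attaches one binary indicator y_g per candidate environmental
# metabolite g and couples it to every uptake it gates via
#   v_e >= -U * y_g        (y_g = 0  =>  uptake closed)
# then minimizes sum(y) subject to steady state, flux bounds and the growth
# constraint(s). Solved by depth-first branch and bound on the LP
# relaxation; the y = 0 branch is explored first and branching is on the
# most fractional indicator (lowest index on ties), so the search is
# deterministic. Alternate optima are enumerated with integer cuts.

# gates: named list, gate id -> integer vector of gated reaction columns.
# growth: list(idx = reaction columns, thr = per-column minimum flux).
# cuts: list of character vectors of gate ids to exclude (sum y <= |cut|-1).
# card: if not NA, restrict to sum(y) == card (used during enumeration).
.milp_minimal_gates <- function(S, lb, ub, gates, growth, U,
                                cuts = list(), card = NA, best_cap = Inf,
                                tol = 1e-6) {
  n <- ncol(S)
  E <- length(gates)
  gid <- names(gates)
  nv <- n + E

  obj <- c(rep(0, n), rep(1, E))
  Aeq <- cbind(S, matrix(0, nrow(S), E))
  beq <- rep(0, nrow(S))
  if (!is.na(card)) {
    Aeq <- rbind(Aeq, c(rep(0, n), rep(1, E)))
    beq <- c(beq, card)
  }

  rows <- list(); rhs <- numeric(0)
  for (g in seq_len(E)) {
    for (e in gates[[g]]) {
      r <- rep(0, nv); r[e] <- -1; r[n + g] <- -U
      rows[[length(rows) + 1]] <- r; rhs <- c(rhs, 0)
    }
  }
  for (k in seq_along(growth$idx)) {
    r <- rep(0, nv); r[growth$idx[k]] <- -1
    rows[[length(rows) + 1]] <- r; rhs <- c(rhs, -growth$thr[k])
  }
  for (cut in cuts) {
    r <- rep(0, nv); r[n + match(cut, gid)] <- 1
    rows[[length(rows) + 1]] <- r; rhs <- c(rhs, length(cut) - 1)
  }
  Ale <- do.call(rbind, rows)

  base_lb <- c(lb, rep(0, E))
  base_ub <- c(ub, rep(1, E))

  best_val <- best_cap
  best_y <- NULL
  # DFS stack of (ylb, yub) bound pairs for the indicator block.
  stack <- list(list(ylb = rep(0, E), yub = rep(1, E)))
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    vlb <- base_lb; vub <- base_ub
    vlb[n + seq_len(E)] <- node$ylb
    vub[n + seq_len(E)] <- node$yub
    sol <- solve_lp(obj, Aeq = Aeq, beq = beq, Ale = Ale, ble = rhs,
                    lb = vlb, ub = vub)
    if (sol$status != "optimal") next
    if (sol$objective > best_val - 1 + tol && is.null(best_y) == FALSE) next
    if (sol$objective > best_val + tol) next
    y <- sol$x[n + seq_len(E)]
    frac <- abs(y - round(y))
    if (max(frac, 0) < tol) {
      val <- sum(round(y))
      if (val < best_val - tol || is.null(best_y)) {
        best_val <- val
        best_y <- round(y)
      }
      next
    }
    j <- which.max(frac)                 # most fractional, lowest index wins
    up <- node; up$ylb[j] <- 1
    dn <- node; dn$yub[j] <- 0
    stack[[length(stack) + 1]] <- up     # pushed first, popped second
    stack[[length(stack) + 1]] <- dn     # y = 0 branch explored first
  }
  if (is.null(best_y)) return(NULL)
  list(gates = gid[best_y > 0.5], size = sum(best_y > 0.5))
}

.enumerate_gate_media <- function(S, lb, ub, gates, growth, U,
                                  max_solutions = 32) {
  first <- .milp_minimal_gates(S, lb, ub, gates, growth, U)
  if (is.null(first)) return(NULL)
  k <- first$size
  media <- list(sort(first$gates))
  cuts <- list(first$gates)
  while (length(media) < max_solutions) {
    nxt <- .milp_minimal_gates(S, lb, ub, gates, growth, U,
                               cuts = cuts, card = k)
    if (is.null(nxt)) break
    media[[length(media) + 1]] <- sort(nxt$gates)
    cuts[[length(cuts) + 1]] <- nxt$gates
  }
  keys <- vapply(media, paste, "", collapse = "\r")
  media[order(keys)]
}

# Build the gated-LP ingredients for a single model: candidate gates are all
# exchanged metabolites not on the free list; free exchanges stay open.
.model_gate_problem <- function(model, uptake_bound, free) {
  ex <- exchange_reactions(model)
  rxns <- names(model$reactions)
  cand <- setdiff(names(ex), free)
  model <- set_medium(model, intersect(free, names(ex)),
                      uptake_bound = uptake_bound)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  lb[match(ex[cand], rxns)] <- -abs(uptake_bound)
  gates <- lapply(cand, function(m) match(ex[[m]], rxns))
  names(gates) <- cand
  list(S = stoich_matrix(model), lb = lb, ub = ub, gates = gates[order(cand)])
}

.growth_threshold <- function(model, growth_threshold, threshold_frac,
                              uptake_bound) {
  full <- set_medium(model, names(exchange_reactions(model)),
                     uptake_bound = uptake_bound)
  sol <- fba(full)
  gmax <- if (sol$status == "optimal") sol$objective_value else 0
  thr <- growth_threshold %||% (threshold_frac * gmax)
  if (gmax < max(thr, 1e-9))
    stop("model ", model$id, " cannot grow on the full medium ",
         "(max growth ", format(gmax, digits = 4), ", threshold ",
         format(thr, digits = 4), ")")
  thr
}

#' Minimal growth medium of a metabolic model
#'
#' Finds a minimum-cardinality set of environmental metabolites whose
#' uptake supports growth at or above a threshold, via branch-and-bound
#' mixed-integer optimization with one binary indicator per exchange.
#' Among equally sized optima the lexicographically smallest metabolite
#' set (by sorted id) is returned; the others are listed as alternates.
#'
#' @param model a `metabolic_model` that grows on the full medium.
#' @param growth_threshold absolute minimum biomass flux; if `NULL`,
#'   `threshold_frac` times the maximum growth on the full medium.
#' @param threshold_frac fraction of full-medium growth used when
#'   `growth_threshold` is `NULL` (default 0.1).
#' @param uptake_bound uptake capacity per opened exchange (default 10).
#' @param free metabolite ids always open and excluded from the
#'   cardinality count (e.g. water, protons, metal ions); default none.
#' @param max_alternates cap on enumerated equal-size media.
#' @return a `minimal_medium` object: `metabolite_ids`, `size`,
#'   `growth_value` (maximum growth on the returned medium) and
#'   `alternates`.
#' @examples
#' m <- toy_chain_model()
#' minimal_medium(m)$metabolite_ids
#' @export
minimal_medium <- function(model, growth_threshold = NULL,
                           threshold_frac = 0.1, uptake_bound = 10,
                           free = character(0), max_alternates = 32) {
  media <- enumerate_minimal_media(model, growth_threshold, threshold_frac,
                                   uptake_bound, free,
                                   max_solutions = max_alternates)
  chosen <- media[[1]]
  opened <- union(chosen, intersect(free,
                                    names(exchange_reactions(model))))
  sol <- fba(set_medium(model, opened, uptake_bound = uptake_bound))
  structure(list(metabolite_ids = chosen, size = length(chosen),
                 growth_value = sol$objective_value,
                 alternates = media[-1]),
            class = "minimal_medium")
}

#' Enumerate alternate minimal media
#'
#' Integer-cut enumeration of minimum-cardinality growth media, in
#' deterministic (lexicographic) order.
#'
#' @inheritParams minimal_medium
#' @param max_solutions maximum number of media returned.
#' @return list of character vectors (sorted metabolite ids), all of the
#'   same minimal size.
#' @export
enumerate_minimal_media <- function(model, growth_threshold = NULL,
                                    threshold_frac = 0.1, uptake_bound = 10,
                                    free = character(0), max_solutions = 32) {
  thr <- .growth_threshold(model, growth_threshold, threshold_frac,
                           uptake_bound)
  prob <- .model_gate_problem(model, uptake_bound, free)
  bio <- match(model$objective, colnames(prob$S))
  media <- .enumerate_gate_media(prob$S, prob$lb, prob$ub, prob$gates,
                                 growth = list(idx = bio, thr = thr),
                                 U = abs(uptake_bound),
                                 max_solutions = max_solutions)
  if (is.null(media))
    stop("no feasible medium for model ", model$id,
         " at growth threshold ", format(thr, digits = 4))
  media
}

#' @export
print.minimal_medium <- function(x, ...) {
  cat("<minimal_medium> size ", x$size, ": ",
      paste(x$metabolite_ids, collapse = ", "), "\n", sep = "")
  cat("  growth on medium: ", format(x$growth_value, digits = 6), sep = "")
  if (length(x$alternates) > 0)
    cat("  (", length(x$alternates), " alternate optima)", sep = "")
  cat("\n")
  invisible(x)
}
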