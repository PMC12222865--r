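# Fixtures built in code, plus independent oracles used across tests.

# --- toy models ------------------------------------------------------------

# Growth requires metabolites a AND b simultaneously.
two_essential_model <- function(id = "joint2") {
  mets <- data.frame(
    id = c("a_e", "b_e", "a_c", "b_c", "t_c"),
    name = NA_character_,
    compartment = c("e", "e", "c", "c", "c"),
    formula = c("C4H8O2", "C3H7NO2", "C4H8O2", "C3H7NO2", "C5H9NO4"),
    stringsAsFactors = FALSE)
  rx <- list(
    list(id = "EX_a", stoich = c(a_e = -1), lb = -10, ub = 1000),
    list(id = "EX_b", stoich = c(b_e = -1), lb = -10, ub = 1000),
    list(id = "TR_a", stoich = c(a_e = -1, a_c = 1), lb = 0, ub = 1000),
    list(id = "TR_b", stoich = c(b_e = -1, b_c = 1), lb = 0, ub = 1000),
    list(id = "MK_t", stoich = c(a_c = -1, b_c = -1, t_c = 1),
         lb = 0, ub = 1000),
    list(id = "biomass", stoich = c(t_c = -1), lb = 0, ub = 1000))
  metabolic_model(id, mets, rx, "biomass")
}

# Growth on carbon source c OR d (two interchangeable nutrients).
alt_carbon_model <- function(id = "altc", n_alternatives = 2) {
  carb <- paste0("c", seq_len(n_alternatives))
  mets <- data.frame(
    id = c(paste0(carb, "_e"), "m_c"),
    name = NA_character_,
    compartment = c(rep("e", n_alternatives), "c"),
    formula = NA_character_, stringsAsFactors = FALSE)
  rx <- list()
  for (cc in carb) {
    rx[[length(rx) + 1]] <- list(id = paste0("EX_", cc),
                                 stoich = stats::setNames(-1, paste0(cc, "_e")),
                                 lb = -10, ub = 1000)
    rx[[length(rx) + 1]] <- list(id = paste0("TR_", cc),
                                 stoich = stats::setNames(c(-1, 1),
                                                          c(paste0(cc, "_e"), "m_c")),
                                 lb = 0, ub = 1000)
  }
  rx[[length(rx) + 1]] <- list(id = "biomass", stoich = c(m_c = -1),
                               lb = 0, ub = 1000)
  metabolic_model(id, mets, rx, "biomass")
}

# Biomass producible without any environmental input.
no_requirement_model <- function(id = "selfmade") {
  mets <- data.frame(id = c("x_e", "m_c"), name = NA_character_,
                     compartment = c("e", "c"), formula = NA_character_,
                     stringsAsFactors = FALSE)
  rx <- list(
    list(id = "EX_x", stoich = c(x_e = -1), lb = -10, ub = 1000),
    list(id = "GEN", stoich = c(m_c = 1), lb = 0, ub = 1000),
    list(id = "biomass", stoich = c(m_c = -1), lb = 0, ub = 1000))
  metabolic_model(id, mets, rx, "biomass")
}

# Single-carbon model with a distinct sole carbon source (disjoint media).
sole_carbon_model <- function(carbon, id = paste0("on_", carbon)) {
  ce <- paste0(carbon, "_e")
  mets <- data.frame(id = c(ce, "m_c"), name = NA_character_,
                     compartment = c("e", "c"), formula = NA_character_,
                     stringsAsFactors = FALSE)
  rx <- list(
    list(id = paste0("EX_", carbon), stoich = stats::setNames(-1, ce),
         lb = -10, ub = 1000),
    list(id = "TR", stoich = stats::setNames(c(-1, 1), c(ce, "m_c")),
         lb = 0, ub = 1000),
    list(id = "biomass", stoich = c(m_c = -1), lb = 0, ub = 1000))
  metabolic_model(id, mets, rx, "biomass")
}

# --- independent oracles ---------------------------------------------------

# LP oracle on an independent formulation: boot::simplex on the shifted
# non-negative problem. Same contract as solve_lp().
lp_oracle <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                      lb, ub, maximize = FALSE) {
  n <- length(obj)
  # x = v - lb >= 0; upper bounds become <= rows.
  A1 <- diag(n); b1 <- ub - lb
  if (!is.null(Ale)) {
    A1 <- rbind(Ale, A1)
    b1 <- c(ble - as.vector(Ale %*% lb), ub - lb)
  }
  A3 <- Aeq; b3 <- if (is.null(Aeq)) NULL else beq - as.vector(Aeq %*% lb)
  # boot::simplex needs non-negative right-hand sides
  move <- which(b1 < 0)
  A2 <- NULL; b2 <- NULL
  if (length(move) > 0) {
    A2 <- -A1[move, , drop = FALSE]; b2 <- -b1[move]
    A1 <- A1[-move, , drop = FALSE]; b1 <- b1[-move]
  }
  if (!is.null(b3)) {
    neg <- which(b3 < 0)
    if (length(neg) > 0) {
      A3[neg, ] <- -A3[neg, , drop = FALSE]; b3[neg] <- -b3[neg]
    }
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = maximize, n.iter = 1000)
  if (res$solved != 1)
    return(list(status = if (res$solved == 0) "unsolved" else "infeasible",
                objective = NA_real_))
  list(status = "optimal", objective = unname(res$value) + sum(obj * lb),
       x = lb + unname(res$soln))
}

# FBA oracle by exhaustive vertex (basic-solution) enumeration: every
# optimum of a box-bounded LP sits at a vertex where the non-basic
# variables are at a bound and the basic ones solve S_B v_B = -S_N v_N.
# Independent of any simplex code; only viable for tiny fixtures.
fba_oracle <- function(model, maximize = model$objective) {
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  n <- ncol(S)
  qS <- qr(t(S))
  r <- qS$rank
  rows <- sort(qS$pivot[seq_len(r)])   # independent rows of S
  Sr <- S[rows, , drop = FALSE]
  best <- -Inf
  oi <- match(maximize, colnames(S))
  for (B in utils::combn(n, r, simplify = FALSE)) {
    SB <- Sr[, B, drop = FALSE]
    if (abs(det(SB)) < 1e-9) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(unlist(grid[g, ]), ub[N], lb[N])
      vB <- as.vector(solve(SB, -Sr[, N, drop = FALSE] %*% vN))
      if (all(vB >= lb[B] - 1e-7) && all(vB <= ub[B] + 1e-7)) {
        v <- numeric(n); v[B] <- vB; v[N] <- vN
        best <- max(best, v[oi])
      }
    }
  }
  list(status = if (is.finite(best)) "optimal" else "infeasible",
       objective = best)
}

# Brute-force minimal media: exhaustive search over all subsets of
# candidate environmental metabolites, smallest cardinality first.
brute_force_minimal_media <- function(model, growth_threshold = NULL,
                                      threshold_frac = 0.1,
                                      uptake_bound = 10,
                                      free = character(0)) {
  ex <- exchange_reactions(model)
  cand <- sort(setdiff(names(ex), free))
  full <- set_medium(model, names(ex), uptake_bound = uptake_bound)
  gmax <- fba(full)$objective_value
  thr <- if (is.null(growth_threshold)) threshold_frac * gmax
         else growth_threshold
  grows <- function(open) {
    m <- set_medium(model, c(open, intersect(free, names(ex))),
                    uptake_bound = uptake_bound)
    s <- fba(m)
    s$status == "optimal" && s$objective_value >= thr - 1e-7
  }
  for (k in 0:length(cand)) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(cand, k, simplify = FALSE)
    hits <- Filter(grows, sets)
    if (length(hits) > 0) return(hits)
  }
  NULL
}

# Ground-truth pairwise community media by brute force: minimal number of
# distinct environmental metabolites under a regime, enumerating subsets of
# the union of member exchange metabolites.
brute_force_community_medium_size <- function(models, regime,
                                              threshold_frac = 0.1,
                                              uptake_bound = 10) {
  cm <- merge_community(models, regime)
  thr <- vapply(models, function(m) {
    full <- set_medium(m, names(exchange_reactions(m)),
                       uptake_bound = uptake_bound)
    threshold_frac * fba(full)$objective_value
  }, 0)
  names(thr) <- vapply(models, `[[`, "", "id")
  env <- sort(names(cm$env_map))
  merged <- cm$merged
  rxn_ids <- names(merged$reactions)
  S <- stoich_matrix(merged)
  base_lb <- vapply(merged$reactions, `[[`, 0, "lb")
  ub <- vapply(merged$reactions, `[[`, 0, "ub")
  for (met in env) base_lb[match(cm$env_map[[met]], rxn_ids)] <- 0
  bio <- match(cm$biomass[cm$member_ids], rxn_ids)
  feasible <- function(open) {
    lb <- base_lb
    for (met in open) lb[match(cm$env_map[[met]], rxn_ids)] <- -uptake_bound
    Ale <- matrix(0, length(bio), ncol(S))
    Ale[cbind(seq_along(bio), bio)] <- -1
    sol <- nichecom:::solve_lp(rep(0, ncol(S)), Aeq = S, beq = rep(0, nrow(S)),
                    Ale = Ale, ble = -unname(thr[cm$member_ids]),
                    lb = lb, ub = ub)
    sol$status == "optimal"
  }
  for (k in 0:length(env)) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(env, k, simplify = FALSE)
    if (any(vapply(sets, feasible, NA))) return(k)
  }
  NA_integer_
}

# Random bounded-feasible LP instances for property tests.
random_lp_case <- function() {
  n <- sample(3:6, 1)
  m <- sample(1:3, 1)
  lb <- runif(n, -5, 0); ub <- runif(n, 0.5, 5)
  x0 <- runif(n, lb, ub)
  Aeq <- matrix(round(runif(m * n, -2, 2), 2), m, n)
  beq <- as.vector(Aeq %*% x0)
  obj <- round(runif(n, -3, 3), 2)
  list(obj = obj, Aeq = Aeq, beq = beq, lb = lb, ub = ub)
}
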