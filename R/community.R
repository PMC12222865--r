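# Community construction and SMETANA-style scoring.
#
# MIP (metabolic interaction potential) is the number of environmental
# metabolites a community can spare through interspecies exchange: the size
# of its minimal medium when members cannot exchange metabolites (private
# environments) minus the size when they share one extracellular pool.
# MRO (metabolic resource overlap) is the mean pairwise intersection of the
# members' individual minimal media divided by the mean individual medium
# size, ranging from 0 (disjoint requirements) to 1 (identical).

#' Merge member models into a community model
#'
#' Member metabolites and reactions are namespaced with `<member>__`. In
#' the `interacting` regime extracellular metabolites are pooled: one
#' community exchange reaction per environmental metabolite, and anything a
#' member secretes becomes available to the others. In the
#' `non_interacting` regime each member keeps a private copy of its
#' environment, so no secreted metabolite can reach another member; the
#' environment is still counted per distinct metabolite.
#'
#' @param models list of `metabolic_model`s with unique ids (>= 2).
#' @param regime `"interacting"` or `"non_interacting"`.
#' @return a `community_model`: `member_ids`, the `merged` model, `regime`,
#'   `biomass` (member id -> namespaced biomass reaction) and `env_map`
#'   (environmental metabolite -> exchange reaction ids gating it).
#' @export
merge_community <- function(models, regime = c("interacting",
                                               "non_interacting")) {
  regime <- match.arg(regime)
  if (length(models) < 2) stop("a community needs at least 2 members")
  ids <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("member id collision after prefixing: ", ids[duplicated(ids)][1])
  names(models) <- ids

  mets <- list(); rxns <- list(); biomass <- character(0)
  env_map <- list()
  shared <- regime == "interacting"

  for (id in ids) {
    m <- models[[id]]
    pre <- paste0(id, "__")
    ex <- exchange_reactions(m)
    is_env <- stats::setNames(m$metabolites$compartment == m$extracellular,
                              m$metabolites$id)
    rename <- function(met) {
      if (shared && is_env[[met]]) met else paste0(pre, met)
    }
    for (i in seq_len(nrow(m$metabolites))) {
      mm <- m$metabolites[i, ]
      nid <- rename(mm$id)
      if (!nid %in% names(mets))
        mets[[nid]] <- data.frame(id = nid, name = mm$name,
                                  compartment = mm$compartment,
                                  formula = mm$formula,
                                  stringsAsFactors = FALSE)
    }
    for (r in m$reactions) {
      if (r$id %in% ex) {
        met <- names(r$stoich)
        if (shared) {
          # one pooled exchange per environmental metabolite
          eid <- paste0("EX_", met, "_pool")
          if (!eid %in% names(rxns)) {
            rxns[[eid]] <- list(id = eid,
                                stoich = stats::setNames(-1, met),
                                lb = r$lb, ub = r$ub)
            env_map[[met]] <- eid
          } else {
            rxns[[eid]]$lb <- min(rxns[[eid]]$lb, r$lb)
            rxns[[eid]]$ub <- max(rxns[[eid]]$ub, r$ub)
          }
        } else {
          eid <- paste0(pre, r$id)
          rxns[[eid]] <- list(id = eid,
                              stoich = stats::setNames(-1, rename(met)),
                              lb = r$lb, ub = r$ub)
          env_map[[met]] <- c(env_map[[met]], eid)
        }
      } else {
        nid <- paste0(pre, r$id)
        if (nid %in% names(rxns)) stop("reaction id collision: ", nid)
        st <- r$stoich
        names(st) <- vapply(names(st), rename, "")
        rxns[[nid]] <- list(id = nid, stoich = st, lb = r$lb, ub = r$ub)
      }
    }
    biomass[[id]] <- paste0(pre, m$objective)
  }

  merged <- metabolic_model(
    id = paste0("community_", paste(ids, collapse = "+")),
    metabolites = do.call(rbind, unname(mets)),
    reactions = unname(rxns),
    objective = biomass[[1]],
    extracellular = models[[1]]$extracellular)
  structure(list(member_ids = ids, merged = merged, regime = regime,
                 biomass = biomass, env_map = env_map),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", paste(x$member_ids, collapse = " + "),
      "  [", x$regime, "]\n", sep = "")
  cat("  merged reactions: ", length(x$merged$reactions),
      "  environmental metabolites: ", length(x$env_map), "\n", sep = "")
  invisible(x)
}

# Minimal community medium (distinct environmental metabolites) under one
# regime: one indicator per metabolite gates all member exchanges for it,
# so the non-interacting union is counted once per compound.
.community_minimal_medium <- function(cm, thresholds, uptake_bound, free) {
  merged <- cm$merged
  rxn_ids <- names(merged$reactions)
  cand <- setdiff(names(cm$env_map), free)
  cand <- cand[order(cand)]

  lb <- vapply(merged$reactions, `[[`, 0, "lb")
  ub <- vapply(merged$reactions, `[[`, 0, "ub")
  for (met in names(cm$env_map)) {
    idx <- match(cm$env_map[[met]], rxn_ids)
    lb[idx] <- if (met %in% free) -abs(uptake_bound) else -abs(uptake_bound)
  }
  # gated exchanges are re-closed by their indicators; free ones stay open
  gates <- lapply(cand, function(m) match(cm$env_map[[m]], rxn_ids))
  names(gates) <- cand

  growth <- list(idx = match(cm$biomass[cm$member_ids], rxn_ids),
                 thr = unname(thresholds[cm$member_ids]))
  sol <- .milp_minimal_gates(stoich_matrix(merged), lb, ub, gates, growth,
                             U = abs(uptake_bound))
  if (is.null(sol))
    stop("community ", merged$id, " has no feasible medium in the ",
         cm$regime, " regime")
  sort(sol$gates)
}

.member_thresholds <- function(models, growth_threshold, threshold_frac,
                               uptake_bound) {
  vapply(models, function(m) {
    .growth_threshold(m, growth_threshold, threshold_frac, uptake_bound)
  }, 0)
}

#' Score a community: MIP, MRO and the media behind them
#'
#' Computes the minimal community media in the non-interacting and
#' interacting regimes (MIP is their size difference, clamped at 0 if
#' solver noise inverts it) and the members' individual minimal media
#' (MRO is mean pairwise intersection over mean individual size).
#'
#' @param models list of member `metabolic_model`s (unique ids, >= 2).
#' @param growth_threshold absolute per-member growth requirement; default
#'   `threshold_frac` of each member's own full-medium maximum.
#' @param threshold_frac fraction-of-maximum growth threshold (default 0.1).
#' @param uptake_bound uptake capacity per opened exchange.
#' @param free always-open metabolite ids excluded from all counts.
#' @param average_alternates if `TRUE`, MRO is averaged over enumerated
#'   alternate individual media instead of using the single deterministic
#'   optimum per member.
#' @param individual_media optional precomputed list of per-member media
#'   (as returned by [enumerate_minimal_media()]), keyed by model id; used
#'   to avoid recomputation when scoring many communities.
#' @return a `community_scores` object: `members`, `mip`, `mro`,
#'   `media_detail` (interacting, non-interacting and individual media).
#' @export
community_scores <- function(models, growth_threshold = NULL,
                             threshold_frac = 0.1, uptake_bound = 10,
                             free = character(0),
                             average_alternates = FALSE,
                             individual_media = NULL) {
  ids <- vapply(models, `[[`, "", "id")
  names(models) <- ids
  thresholds <- .member_thresholds(models, growth_threshold, threshold_frac,
                                   uptake_bound)

  m_non <- .community_minimal_medium(
    merge_community(models, "non_interacting"), thresholds, uptake_bound, free)
  m_int <- .community_minimal_medium(
    merge_community(models, "interacting"), thresholds, uptake_bound, free)
  mip <- length(m_non) - length(m_int)
  if (mip < 0) {
    warning("negative MIP (", mip, ") clamped to 0 for community ",
            paste(ids, collapse = "+"))
    mip <- 0L
  }

  if (is.null(individual_media)) {
    individual_media <- lapply(ids, function(id) {
      enumerate_minimal_media(models[[id]], growth_threshold, threshold_frac,
                              uptake_bound, free,
                              max_solutions = if (average_alternates) 32 else 1)
    })
    names(individual_media) <- ids
  }
  mro <- .mro_from_media(individual_media[ids], average_alternates)

  structure(list(members = ids, mip = as.integer(mip), mro = mro,
                 media_detail = list(non_interacting = m_non,
                                     interacting = m_int,
                                     individual = individual_media[ids])),
            class = "community_scores")
}

.mro_from_media <- function(media_list, average_alternates = FALSE) {
  ids <- names(media_list)
  if (!average_alternates) media_list <- lapply(media_list, `[`, 1)
  sizes <- vapply(media_list, function(ms) mean(lengths(ms)), 0)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  inter <- vapply(pairs, function(p) {
    mean(outer(seq_along(media_list[[p[1]]]), seq_along(media_list[[p[2]]]),
               Vectorize(function(i, j) {
                 length(intersect(media_list[[p[1]]][[i]],
                                  media_list[[p[2]]][[j]]))
               })))
  }, 0)
  denom <- mean(sizes)
  if (denom == 0) return(0)
  mean(inter) / denom
}

#' @rdname community_scores
#' @export
mip_score <- function(models, ...) community_scores(models, ...)$mip

#' @rdname community_scores
#' @export
mro_score <- function(models, ...) community_scores(models, ...)$mro

#' @export
print.community_scores <- function(x, ...) {
  cat("<community_scores> ", paste(x$members, collapse = " + "), "\n",
      "  MIP = ", x$mip, "   MRO = ", format(x$mro, digits = 4), "\n",
      "  media sizes: non-interacting ",
      length(x$media_detail$non_interacting), ", interacting ",
      length(x$media_detail$interacting), "\n", sep = "")
  invisible(x)
}

#' Enumerate candidate communities
#'
#' All subsets of the strain list with sizes in `[min_size, max_size]`, in
#' deterministic lexicographic order (by size, then member order).
#'
#' @param strain_ids character vector of strain identifiers.
#' @param min_size smallest community size (>= 2).
#' @param max_size largest community size (<= number of strains).
#' @return list of character vectors.
#' @examples
#' length(enumerate_communities(letters[1:6], 2, 6))  # 57
#' @export
enumerate_communities <- function(strain_ids, min_size = 2,
                                  max_size = length(strain_ids)) {
  if (min_size > max_size) stop("min_size must not exceed max_size")
  if (min_size < 2) stop("communities need at least 2 members")
  if (max_size > length(strain_ids))
    stop("max_size exceeds the number of strains")
  out <- list()
  for (k in min_size:max_size)
    out <- c(out, utils::combn(strain_ids, k, simplify = FALSE))
  out
}

#' Score a list of candidate communities
#'
#' Runs [community_scores()] for every subset, reusing each member's
#' individual minimal media and growth threshold across subsets.
#'
#' @param models named list of `metabolic_model`s covering every member.
#' @param subsets list of member-id vectors (e.g. from
#'   [enumerate_communities()]).
#' @inheritParams community_scores
#' @return data.frame with columns `members` (semicolon-joined), `size`,
#'   `mip`, `mro`, `media_non_interacting`, `media_interacting`.
#' @export
score_all <- function(models, subsets, growth_threshold = NULL,
                      threshold_frac = 0.1, uptake_bound = 10,
                      free = character(0), average_alternates = FALSE) {
  ids <- vapply(models, `[[`, "", "id")
  names(models) <- ids
  missing <- setdiff(unique(unlist(subsets)), ids)
  if (length(missing) > 0)
    stop("no model for member(s): ", paste(missing, collapse = ", "))

  used <- unique(unlist(subsets))
  media <- lapply(used, function(id) {
    enumerate_minimal_media(models[[id]], growth_threshold, threshold_frac,
                            uptake_bound, free,
                            max_solutions = if (average_alternates) 32 else 1)
  })
  names(media) <- used

  rows <- lapply(subsets, function(s) {
    sc <- community_scores(models[s], growth_threshold, threshold_frac,
                           uptake_bound, free, average_alternates,
                           individual_media = media)
    data.frame(members = paste(s, collapse = ";"), size = length(s),
               mip = sc$mip, mro = sc$mro,
               media_non_interacting =
                 length(sc$media_detail$non_interacting),
               media_interacting = length(sc$media_detail$interacting),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-out dropout scan of a community
#'
#' Scores the full member set and every leave-one-out subset, reporting
#' the change in MIP and MRO attributable to each dropped member.
#'
#' @param models named list of `metabolic_model`s.
#' @param community character vector of member ids (>= 3).
#' @inheritParams community_scores
#' @return data.frame with one row for the full community (`dropped = ""`)
#'   and one per dropped member, with `mip`, `mro`, `delta_mip`,
#'   `delta_mro`.
#' @export
dropout_scan <- function(models, community, growth_threshold = NULL,
                         threshold_frac = 0.1, uptake_bound = 10,
                         free = character(0)) {
  if (length(community) < 3)
    stop("dropout scan needs a community of at least 3 members")
  subsets <- c(list(community),
               lapply(community, function(d) setdiff(community, d)))
  tab <- score_all(models, subsets, growth_threshold, threshold_frac,
                   uptake_bound, free)
  tab$dropped <- c("", community)
  tab$delta_mip <- tab$mip - tab$mip[1]
  tab$delta_mro <- tab$mro - tab$mro[1]
  tab[, c("dropped", "members", "size", "mip", "mro",
          "delta_mip", "delta_mro")]
}

#' Rank scored communities
#'
#' Orders a score table by MIP (descending), then MRO (ascending), then
#' lexicographically by the member set, so the ranking is deterministic.
#'
#' @param scores data.frame as returned by [score_all()].
#' @param size_range optional length-2 integer vector restricting the
#'   community sizes retained before ranking.
#' @return the reordered (and possibly filtered) data.frame.
#' @export
rank_communities <- function(scores, size_range = NULL) {
  if (nrow(scores) == 0) stop("empty score table")
  if (!is.null(size_range))
    scores <- scores[scores$size >= size_range[1] &
                       scores$size <= size_range[2], , drop = FALSE]
  scores[order(-scores$mip, scores$mro, scores$members), , drop = FALSE]
}
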