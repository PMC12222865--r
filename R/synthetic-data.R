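# Synthetic fixtures with known ground truth: toy metabolic models with
# engineered cross-feeding (auxotrophy + secretion), utilization panels
# with prescribed niche widths, and width-distribution samples.

#' A minimal linear-chain toy model
#'
#' One carbon source taken up from the environment and converted through
#' `n_steps` internal metabolites into biomass; the canonical fixture for
#' flux balance checks (maximum growth equals the uptake bound).
#'
#' @param n_steps number of internal conversion steps (>= 1).
#' @param uptake_bound carbon uptake capacity (default 10).
#' @param id model id.
#' @return a `metabolic_model`.
#' @export
toy_chain_model <- function(n_steps = 1, uptake_bound = 10,
                            id = "toy_chain") {
  internal <- paste0("m", seq_len(n_steps))
  mets <- data.frame(
    id = c("carbon_e", internal),
    name = c("carbon source", internal),
    compartment = c("e", rep("c", n_steps)),
    formula = c("C6H12O6", rep(NA_character_, n_steps)),
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_carbon", stoich = c(carbon_e = -1),
         lb = -abs(uptake_bound), ub = 1000),
    list(id = "TR_carbon", stoich = c(carbon_e = -1, m1 = 1),
         lb = 0, ub = 1000))
  if (n_steps > 1) {
    for (i in seq_len(n_steps - 1)) {
      st <- stats::setNames(c(-1, 1), c(internal[i], internal[i + 1]))
      rxns[[length(rxns) + 1]] <- list(id = paste0("STEP_", i), stoich = st,
                                       lb = 0, ub = 1000)
    }
  }
  rxns[[length(rxns) + 1]] <- list(
    id = "biomass", stoich = stats::setNames(-1, internal[n_steps]),
    lb = 0, ub = 1000)
  metabolic_model(id, mets, rxns, "biomass")
}

#' Specify an engineered cross-feeding community
#'
#' A `crossfeed_spec` describes `n_strains` toy organisms that all grow on
#' one shared carbon source, plus directed exchanges: each
#' `(donor, recipient, metabolite)` triple makes the recipient auxotrophic
#' for the metabolite and gives the donor a carbon-costing synthesis and
#' secretion pathway for it. The number of engineered exchanges internal
#' to a member subset is the ground-truth MIP of that subset.
#'
#' @param n_strains number of strains.
#' @param strain_ids optional strain identifiers (default `S1`, `S2`, ...).
#' @param exchanges data.frame (or list of 3-element vectors) with columns
#'   `donor`, `recipient`, `metabolite`; donor != recipient, one distinct
#'   metabolite per triple.
#' @param shared_carbon id of the shared carbon source.
#' @param seed generator seed carried along for provenance.
#' @return a `crossfeed_spec`.
#' @export
crossfeed_spec <- function(n_strains, exchanges = NULL,
                           shared_carbon = "carbon", seed = 1,
                           strain_ids = NULL) {
  ids <- strain_ids %||% paste0("S", seq_len(n_strains))
  stopifnot(length(ids) == n_strains, !anyDuplicated(ids))
  if (is.null(exchanges)) {
    exchanges <- data.frame(donor = character(0), recipient = character(0),
                            metabolite = character(0),
                            stringsAsFactors = FALSE)
  }
  if (!is.data.frame(exchanges))
    exchanges <- do.call(rbind, lapply(exchanges, function(e) {
      data.frame(donor = e[[1]], recipient = e[[2]], metabolite = e[[3]],
                 stringsAsFactors = FALSE)
    }))
  bad <- setdiff(c(exchanges$donor, exchanges$recipient), ids)
  if (length(bad) > 0) stop("unknown strain in exchange: ", bad[1])
  if (any(exchanges$donor == exchanges$recipient))
    stop("donor and recipient must differ")
  if (anyDuplicated(exchanges$metabolite))
    stop("metabolite ids must be unique per exchange triple")
  if (shared_carbon %in% exchanges$metabolite)
    stop("impossible spec: the shared carbon source cannot also be an ",
         "exchanged auxotrophic metabolite")
  structure(list(n_strains = n_strains, strain_ids = ids,
                 exchanges = exchanges, shared_carbon = shared_carbon,
                 seed = seed),
            class = "crossfeed_spec")
}

#' Read/write a cross-feeding spec (JSON)
#'
#' @param spec a `crossfeed_spec`.
#' @param path JSON file path.
#' @return `read_crossfeed_spec` returns a `crossfeed_spec`;
#'   `write_crossfeed_spec` returns `path` invisibly.
#' @export
write_crossfeed_spec <- function(spec, path) {
  jsonlite::write_json(
    list(n_strains = spec$n_strains, shared_carbon = spec$shared_carbon,
         seed = spec$seed,
         exchanges = spec$exchanges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_crossfeed_spec
#' @export
read_crossfeed_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- j$exchanges
  if (length(ex) == 0) ex <- NULL
  crossfeed_spec(j$n_strains, ex, shared_carbon = j$shared_carbon,
                 seed = j$seed)
}

#' Build toy models with engineered cross-feeding
#'
#' Each strain takes up the shared carbon source, converts it to a biomass
#' precursor, and additionally requires one unit of each metabolite it is
#' auxotrophic for. Donors carry a synthesis reaction (consuming carbon,
#' so donating is feasible but not free) and a one-way secretion path.
#' In isolation every strain's minimal medium is the carbon source plus
#' its required metabolites; in an interacting community, any requirement
#' whose donor is present can be spared from the environment.
#'
#' @param spec a `crossfeed_spec`.
#' @param uptake_bound exchange uptake capacity (default 10).
#' @return list with `models` (named list of `metabolic_model`s) and
#'   `spec`.
#' @export
make_crossfeeding_panel <- function(spec, uptake_bound = 10) {
  stopifnot(inherits(spec, "crossfeed_spec"))
  carbon <- spec$shared_carbon
  ce <- paste0(carbon, "_e"); cc <- paste0(carbon, "_c")
  models <- lapply(spec$strain_ids, function(sid) {
    req <- spec$exchanges$metabolite[spec$exchanges$recipient == sid]
    don <- spec$exchanges$metabolite[spec$exchanges$donor == sid]
    overlap <- intersect(req, don)
    if (length(overlap) > 0)
      stop("impossible spec: strain ", sid, " both requires and donates ",
           overlap[1])
    side <- unique(c(req, don))
    mets <- data.frame(
      id = c(ce, cc, "precursor_c",
             paste0(side, "_e", recycle0 = TRUE),
             paste0(side, "_c", recycle0 = TRUE)),
      name = c(carbon, carbon, "biomass precursor", side, side),
      compartment = c("e", "c", "c",
                      rep("e", length(side)), rep("c", length(side))),
      formula = c("C6H12O6", "C6H12O6", "C3H6O3",
                  rep("C4H8N2O3", length(side)),
                  rep("C4H8N2O3", length(side))),
      stringsAsFactors = FALSE)
    rxns <- list(
      list(id = paste0("EX_", carbon), stoich = stats::setNames(-1, ce),
           lb = -abs(uptake_bound), ub = 1000),
      list(id = paste0("TR_", carbon),
           stoich = stats::setNames(c(-1, 1), c(ce, cc)), lb = 0, ub = 1000),
      list(id = "CONV", stoich = stats::setNames(c(-1, 1),
                                                 c(cc, "precursor_c")),
           lb = 0, ub = 1000))
    for (a in req) {
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("EX_", a), stoich = stats::setNames(-1, paste0(a, "_e")),
        lb = 0, ub = 1000)
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("TR_", a),
        stoich = stats::setNames(c(-1, 1), paste0(a, c("_e", "_c"))),
        lb = 0, ub = 1000)
    }
    for (d in don) {
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("EX_", d), stoich = stats::setNames(-1, paste0(d, "_e")),
        lb = 0, ub = 1000)
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("SYN_", d),
        stoich = stats::setNames(c(-1, 1), c(cc, paste0(d, "_c"))),
        lb = 0, ub = 1000)
      rxns[[length(rxns) + 1]] <- list(
        id = paste0("SEC_", d),
        stoich = stats::setNames(c(-1, 1), paste0(d, c("_c", "_e"))),
        lb = 0, ub = 1000)
    }
    bio <- stats::setNames(rep(-1, 1 + length(req)),
                           c("precursor_c",
                             paste0(req, "_c", recycle0 = TRUE)))
    rxns[[length(rxns) + 1]] <- list(id = "biomass", stoich = bio,
                                     lb = 0, ub = 1000)
    metabolic_model(sid, mets, rxns, "biomass")
  })
  names(models) <- spec$strain_ids
  list(models = models, spec = spec)
}

#' Ground-truth MIP of a member subset under a cross-feeding spec
#'
#' The number of distinct exchanged metabolites whose donor and recipient
#' are both in the subset: exactly the nutrients an interacting community
#' spares relative to private environments.
#'
#' @param spec a `crossfeed_spec`.
#' @param members character vector of strain ids.
#' @return non-negative integer.
#' @export
ground_truth_mip <- function(spec, members) {
  ex <- spec$exchanges
  hit <- ex$donor %in% members & ex$recipient %in% members
  length(unique(ex$metabolite[hit]))
}

#' Generate a utilization panel with prescribed niche widths
#'
#' For each strain, `ceiling(w)` resources are drawn at random and given
#' a two-level proportion profile solved analytically so that Levins'
#' width equals the target exactly; signals are scaled so every utilized
#' resource clears the threshold and sub-threshold cells are 0.
#'
#' @param n_strains,n_resources panel dimensions.
#' @param target_widths numeric vector (length `n_strains`) of target
#'   Levins widths, each in `[1, n_resources]`.
#' @param seed RNG seed controlling resource placement.
#' @param threshold utilization cutoff embedded in the panel (default 50).
#' @param strain_ids optional strain names (default `strain1`, ...).
#' @return a `profile_panel` whose `niche_width()` equals the targets to
#'   within 1e-9.
#' @export
make_profile_panel <- function(n_strains, n_resources, target_widths,
                               seed = 1, threshold = 50,
                               strain_ids = NULL) {
  stopifnot(length(target_widths) == n_strains)
  if (any(target_widths < 1 | target_widths > n_resources))
    stop("target widths must lie in [1, n_resources]")
  signal <- matrix(0, n_strains, n_resources,
                   dimnames = list(strain_ids %||%
                                     paste0("strain", seq_len(n_strains)),
                                   paste0("R", seq_len(n_resources))))
  with_seed(seed, {
    for (i in seq_len(n_strains)) {
      w <- target_widths[i]
      k <- ceiling(w)
      p <- if (abs(w - k) < 1e-12) {
        rep(1 / k, k)
      } else {
        # two-level profile: one resource at q, k-1 at (1-q)/(k-1), with
        # q solving q^2 + (1-q)^2/(k-1) = 1/w (root >= 1/k)
        a <- k / (k - 1); b <- -2 / (k - 1); cc <- 1 / (k - 1) - 1 / w
        q <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
        c(q, rep((1 - q) / (k - 1), k - 1))
      }
      cols <- sample(n_resources, k)
      scale <- (threshold * 1.2) / min(p)
      signal[i, cols] <- p * scale
    }
  })
  profile_panel(signal, threshold = threshold)
}

#' Generate a mixed narrow/broad synthetic community with coupled
#' phenotypes and models
#'
#' Emulates the empirical association the design strategy exploits: the
#' narrow-spectrum (NSR) strains are the cross-feeding hubs. Narrow
#' strains receive utilization widths drawn from the NSR tail and form a
#' directed exchange cycle (each donates one distinct metabolite to the
#' next), so any pair of adjacent-in-cycle narrow strains has positive
#' ground-truth MIP and carries a private auxotrophic requirement that
#' lowers its resource overlap. Broad strains receive widths from the BSR
#' tail and are metabolically self-sufficient (carbon only), so
#' broad-only pairs have MIP 0 and identical minimal media (MRO 1).
#'
#' @param n_narrow,n_broad numbers of narrow and broad strains.
#' @param n_resources panel width (default 58 carbon sources).
#' @param narrow_range,broad_range sampling ranges for the target
#'   utilization widths (defaults 3-7 and 29-36, the NSR/BSR tails).
#' @param seed RNG seed.
#' @return list with `models` (named list), `panel` (a `profile_panel`),
#'   `spec` (the `crossfeed_spec`) and `widths` (named target widths).
#' @export
make_mixed_panel <- function(n_narrow = 3, n_broad = 3, n_resources = 58,
                             narrow_range = c(3, 7),
                             broad_range = c(29, 36), seed = 1) {
  stopifnot(n_narrow >= 2)
  ids <- c(paste0("N", seq_len(n_narrow)), paste0("B", seq_len(n_broad)))
  widths <- with_seed(derive_seed(seed, 1), {
    c(stats::runif(n_narrow, narrow_range[1], narrow_range[2]),
      stats::runif(n_broad, broad_range[1], broad_range[2]))
  })
  names(widths) <- ids
  cyc <- lapply(seq_len(n_narrow), function(i) {
    c(paste0("N", i), paste0("N", i %% n_narrow + 1), paste0("xm", i))
  })
  spec <- crossfeed_spec(n_narrow + n_broad, cyc, seed = seed,
                         strain_ids = ids)
  models <- make_crossfeeding_panel(spec)$models
  panel <- make_profile_panel(length(ids), n_resources, unname(widths),
                              seed = derive_seed(seed, 2),
                              strain_ids = ids)
  list(models = models, panel = panel, spec = spec, widths = widths)
}

#' Sample a non-negative (truncated normal) width distribution
#'
#' Draws from N(mu, sigma^2) truncated at 0 by inverse-CDF sampling, so
#' identical seeds give identical samples.
#'
#' @param mu,sigma mean and standard deviation of the parent normal
#'   (`sigma > 0`).
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
sample_width_distribution <- function(mu, sigma, n, seed = 1) {
  stopifnot(sigma > 0, n >= 1)
  with_seed(seed, {
    lo <- stats::pnorm(0, mu, sigma)
    u <- stats::runif(n, lo, 1)
    stats::qnorm(u, mu, sigma)
  })
}
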