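# Resource-utilization phenotypes: Levins' niche width, Pianka's overlap,
# and the narrow-/broad-spectrum (NSR/BSR) classification.

#' Build a utilization panel from a signal matrix
#'
#' Converts a strains x resources signal matrix (phenotype-microarray
#' respiration values, or binary growth calls) into a `profile_panel`.
#' A resource counts as utilized when its signal strictly exceeds
#' `threshold`; utilization proportions P_i are the supra-threshold
#' signals renormalized to sum to 1 per strain (sub-threshold signals are
#' set to 0 first). For binary panels the proportions are uniform over the
#' utilized resources, so Levins' width equals the utilized count.
#'
#' @param signal numeric matrix with strain row names and resource column
#'   names; non-negative.
#' @param threshold utilization cutoff (strictly greater-than; default 50,
#'   the conventional respiration-signal cutoff).
#' @param binary treat any positive signal as a growth call with uniform
#'   proportions.
#' @param renormalize renormalize proportions over the supra-threshold
#'   signals (default); `FALSE` computes proportions over the raw row
#'   including sub-threshold signals, for sensitivity analysis.
#' @return a `profile_panel`: `strains`, `resources`, `signal`, `mask`,
#'   `proportions`, `threshold`, `binary`.
#' @export
profile_panel <- function(signal, threshold = 50, binary = FALSE,
                          renormalize = TRUE) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal matrix must be numeric")
  if (nrow(signal) == 0 || ncol(signal) == 0) stop("empty utilization table")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("signal matrix needs strain row names and resource column names")
  if (anyDuplicated(rownames(signal)))
    stop("duplicated strain name: ",
         rownames(signal)[duplicated(rownames(signal))][1])
  if (anyDuplicated(colnames(signal)))
    stop("duplicated resource name: ",
         colnames(signal)[duplicated(colnames(signal))][1])
  if (any(signal < 0)) stop("negative utilization signal")

  mask <- if (binary) signal > 0 else signal > threshold
  prop <- matrix(0, nrow(signal), ncol(signal), dimnames = dimnames(signal))
  for (i in seq_len(nrow(signal))) {
    if (!any(mask[i, ])) next
    w <- if (binary) as.numeric(mask[i, ]) else {
      if (renormalize) signal[i, ] * mask[i, ] else signal[i, ]
    }
    prop[i, ] <- w / sum(w)
  }
  zero <- rownames(signal)[rowSums(mask) == 0]
  if (length(zero) > 0)
    warning("strain(s) with no utilized resource retained but excluded ",
            "from width/overlap statistics: ", paste(zero, collapse = ", "))
  structure(list(strains = rownames(signal), resources = colnames(signal),
                 signal = signal, mask = mask, proportions = prop,
                 threshold = threshold, binary = binary),
            class = "profile_panel")
}

#' Load a utilization panel from a CSV/TSV matrix
#'
#' Expects a numeric strains x resources table with a header row of
#' resource names and a first column of strain names (UTF-8, decimal
#' point). Tab-separated files are detected from the `.tsv` extension.
#'
#' @param path file path.
#' @inheritParams profile_panel
#' @return a `profile_panel`.
#' @export
load_panel <- function(path, threshold = 50, binary = FALSE,
                       renormalize = TRUE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty utilization table: ", path)
  strains <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(strains, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at strain '", strains[bad[1]], "', resource '",
         colnames(vals)[bad[2]], "' in ", path)
  }
  profile_panel(num, threshold = threshold, binary = binary,
                renormalize = renormalize)
}

#' @export
print.profile_panel <- function(x, ...) {
  cat("<profile_panel> ", length(x$strains), " strains x ",
      length(x$resources), " resources (threshold ", x$threshold,
      if (x$binary) ", binary calls" else "", ")\n", sep = "")
  invisible(x)
}

#' Extract one strain's utilization profile
#'
#' @param panel a `profile_panel`.
#' @param strain strain identifier.
#' @return a `utilization_profile`: `strain_id`, `resource_ids`, `signal`,
#'   `mask`, `proportions`.
#' @export
utilization_profile <- function(panel, strain) {
  if (!strain %in% panel$strains) stop("unknown strain: ", strain)
  structure(list(strain_id = strain, resource_ids = panel$resources,
                 signal = panel$signal[strain, ],
                 mask = panel$mask[strain, ],
                 proportions = panel$proportions[strain, ]),
            class = "utilization_profile")
}

.prop_of <- function(x) {
  if (inherits(x, "utilization_profile")) x$proportions
  else if (is.numeric(x)) x
  else stop("expected a utilization_profile or a numeric proportion vector")
}

#' Levins' niche width
#'
#' W = 1 / sum(P_i^2) over a strain's resource-utilization proportions:
#' the effective number of resources used. W lies between 1 (single
#' resource) and the number of utilized resources (uniform use).
#'
#' @param x a `utilization_profile`, a numeric proportion vector, or a
#'   `profile_panel` (then all strains are returned as a named vector,
#'   `NA` for strains with no utilized resource).
#' @return numeric width(s).
#' @export
niche_width <- function(x) {
  if (inherits(x, "profile_panel")) {
    return(vapply(x$strains, function(s) {
      p <- x$proportions[s, ]
      if (sum(p) == 0) NA_real_ else 1 / sum(p^2)
    }, 0))
  }
  p <- .prop_of(x)
  if (sum(p) == 0)
    stop("niche width undefined: no utilized resource")
  1 / sum(p^2)
}

#' Simplified (count-based) utilization width
#'
#' The number of utilized resources, the simplification used for
#' binary-call validation panels.
#'
#' @param x a `utilization_profile` or a `profile_panel` (named vector).
#' @return integer count(s).
#' @export
simplified_width <- function(x) {
  if (inherits(x, "profile_panel")) return(rowSums(x$mask))
  if (!inherits(x, "utilization_profile"))
    stop("expected a utilization_profile or profile_panel")
  sum(x$mask)
}

#' Pianka's niche overlap index
#'
#' O_jk = sum(P_ij * P_ik) / sqrt(sum(P_ij^2) * sum(P_ik^2)), the
#' cosine-type similarity of two strains' utilization proportions, from 0
#' (disjoint resource use) to 1 (identical).
#'
#' @param a,b `utilization_profile`s or numeric proportion vectors over
#'   the same ordered resource list.
#' @return overlap in `[0, 1]`.
#' @export
pianka_overlap <- function(a, b) {
  pa <- .prop_of(a); pb <- .prop_of(b)
  if (length(pa) != length(pb))
    stop("profiles have different resource lists")
  na <- sum(pa^2); nb <- sum(pb^2)
  if (na == 0 || nb == 0)
    stop("overlap undefined for a zero-norm profile")
  o <- sum(pa * pb) / sqrt(na * nb)
  min(max(o, 0), 1)
}

#' Pairwise overlap matrix of a panel
#'
#' @param panel a `profile_panel`.
#' @return symmetric strains x strains matrix of Pianka overlaps, diagonal
#'   1; rows of strains with no utilized resource are `NA`.
#' @export
overlap_matrix <- function(panel) {
  n <- length(panel$strains)
  M <- matrix(NA_real_, n, n, dimnames = list(panel$strains, panel$strains))
  ok <- rowSums(panel$mask) > 0
  for (i in seq_len(n)) {
    if (!ok[i]) next
    M[i, i] <- 1
    for (j in seq_len(n)) {
      if (j <= i || !ok[j]) next
      M[i, j] <- M[j, i] <- pianka_overlap(panel$proportions[i, ],
                                           panel$proportions[j, ])
    }
  }
  M
}

#' Average overlap of one strain against all others
#'
#' @param panel a `profile_panel` with at least 2 strains.
#' @param strain focal strain id.
#' @return arithmetic mean of the focal strain's pairwise overlaps
#'   (diagonal excluded; partners with no utilized resource dropped).
#' @export
average_overlap <- function(panel, strain) {
  if (!strain %in% panel$strains) stop("unknown strain: ", strain)
  if (length(panel$strains) < 2) stop("panel has fewer than 2 strains")
  M <- overlap_matrix(panel)
  mean(M[strain, setdiff(panel$strains, strain)], na.rm = TRUE)
}

#' Classify strains as narrow- or broad-spectrum resource utilizers
#'
#' Strains with simplified width `<= low` are narrow-spectrum (NSR),
#' `>= high` broad-spectrum (BSR), the rest intermediate. Defaults are the
#' distribution-tail cutoffs of 7 and 29 utilizable compounds.
#'
#' @param widths non-negative integer widths (may be named).
#' @param low NSR cutoff (inclusive).
#' @param high BSR cutoff (inclusive); must exceed `low`.
#' @return factor with levels `NSR`, `intermediate`, `BSR`.
#' @export
classify_nsr_bsr <- function(widths, low = 7, high = 29) {
  if (low >= high) stop("low cutoff must be smaller than high cutoff")
  if (any(widths < 0)) stop("widths must be non-negative")
  out <- ifelse(widths <= low, "NSR",
                ifelse(widths >= high, "BSR", "intermediate"))
  factor(out, levels = c("NSR", "intermediate", "BSR"))
}

#' Siderophore production index from a CAS assay
#'
#' 1 - A_s / A_r, where A_s is the sample absorbance and A_r the
#' absorbance of the uninoculated reference.
#'
#' @param sample_abs non-negative sample absorbance(s).
#' @param reference_abs positive reference absorbance.
#' @return index value(s); 0 means no siderophore, 1 maximal chelation.
#' @export
cas_siderophore_index <- function(sample_abs, reference_abs) {
  if (any(reference_abs <= 0)) stop("reference absorbance must be positive")
  if (any(sample_abs < 0)) stop("sample absorbance must be non-negative")
  1 - sample_abs / reference_abs
}

#' Per-strain summary table of a panel
#'
#' @param panel a `profile_panel`.
#' @param low,high NSR/BSR cutoffs passed to [classify_nsr_bsr()].
#' @return data.frame with `strain_id`, `niche_width`, `simplified_width`,
#'   `average_overlap`, `class`.
#' @export
panel_stats <- function(panel, low = 7, high = 29) {
  W <- niche_width(panel)
  sw <- simplified_width(panel)
  ao <- vapply(panel$strains, function(s) {
    if (sum(panel$mask[s, ]) == 0) NA_real_ else average_overlap(panel, s)
  }, 0)
  data.frame(strain_id = panel$strains,
             niche_width = unname(W),
             simplified_width = unname(as.integer(sw)),
             average_overlap = unname(ao),
             class = classify_nsr_bsr(unname(sw), low, high),
             stringsAsFactors = FALSE, row.names = NULL)
}
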