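# Statistical layer: width-score regressions, Gaussian fits to width
# distributions, phylogenetic-distance-binned correlations, hierarchical
# clustering of producibility panels.

#' Ordinary least-squares regression with fit statistics
#'
#' Wraps `lm(y ~ x)` into a compact fit object carrying slope, intercept,
#' R-squared, the two-sided F-test p-value and the ingredients of the 95%
#' confidence band.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return an `nc_linreg` object.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate fit: x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- if (is.null(s$fstatistic)) NA_real_ else
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = s$r.squared, p_value = p, n = n,
                 sigma = s$sigma, x_mean = mean(x),
                 sxx = sum((x - mean(x))^2), lm = fit),
            class = "nc_linreg")
}

#' @export
print.nc_linreg <- function(x, digits = 4, ...) {
  cat("<linreg> y = ", format(x$intercept, digits = digits), " + ",
      format(x$slope, digits = digits), " x   (n = ", x$n, ")\n",
      "  R^2 = ", format(x$r2, digits = digits),
      ", p = ", format.pval(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
predict.nc_linreg <- function(object, newx, interval = c("none",
                                                         "confidence"),
                              level = 0.95, ...) {
  interval <- match.arg(interval)
  yhat <- object$intercept + object$slope * newx
  if (interval == "none") return(yhat)
  se <- object$sigma * sqrt(1 / object$n +
                              (newx - object$x_mean)^2 / object$sxx)
  tq <- stats::qt(1 - (1 - level) / 2, object$n - 2)
  cbind(fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se)
}

#' Gaussian fit to a width distribution
#'
#' Histograms the values (Freedman-Diaconis bins by default) and fits
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by
#' Levenberg-Marquardt nonlinear least squares. `goodness` is the
#' R-squared of the fitted curve against the counts; values well below 1
#' indicate a non-Gaussian (e.g. bimodal) distribution.
#'
#' @param values numeric sample, n >= 10.
#' @param bins number of histogram bins, or `NULL` for Freedman-Diaconis.
#' @return an `nc_gaussian_fit` object: `mu`, `sigma`, `amplitude`,
#'   `goodness`, `n`.
#' @export
gaussian_fit <- function(values, bins = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need at least 10 values")
  if (stats::sd(values) == 0)
    stop("degenerate input: all values identical (sigma -> 0)")
  h <- graphics::hist(values, breaks = bins %||% "FD", plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  start <- list(A = max(ys), mu = mean(values), sigma = stats::sd(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-(xs - mu)^2 / (2 * sigma^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed to converge (starts: A=",
                             format(start$A), ", mu=", format(start$mu),
                             ", sigma=", format(start$sigma), "): ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  resid <- ys - stats::predict(fit)
  goodness <- 1 - sum(resid^2) / sum((ys - mean(ys))^2)
  structure(list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
                 amplitude = unname(cf["A"]), goodness = goodness,
                 n = length(values),
                 se = tryCatch(summary(fit)$coefficients[, "Std. Error"],
                               error = function(e) NULL)),
            class = "nc_gaussian_fit")
}

#' @export
print.nc_gaussian_fit <- function(x, digits = 4, ...) {
  cat("<gaussian_fit> mu = ", format(x$mu, digits = digits),
      ", sigma = ", format(x$sigma, digits = digits),
      ", amplitude = ", format(x$amplitude, digits = digits),
      "\n  goodness (R^2 on histogram) = ",
      format(x$goodness, digits = digits),
      if (x$goodness < 0.8) "  [poor fit: distribution may not be Gaussian]"
      else "", "\n", sep = "")
  invisible(x)
}

#' Patristic distance matrix from a phylogenetic tree
#'
#' @param tree an `ape::phylo` object or path to a newick file.
#' @return symmetric matrix of summed branch lengths between tips.
#' @export
patristic_distances <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stats::cophenetic(tree)
}

#' Distance-binned width-score correlations
#'
#' Partitions scored pairs by the phylogenetic distance between their
#' members and regresses the community score on the pair's mean width
#' within each bin. Bins with fewer than 3 pairs are reported as empty
#' rather than silently dropped.
#'
#' @param pair_scores data.frame with columns `strain_a`, `strain_b`, a
#'   score column and a mean-width column.
#' @param distances symmetric non-negative distance matrix with strain
#'   dimnames (e.g. from [patristic_distances()]).
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @param score_col,width_col column names in `pair_scores`.
#' @return data.frame with one row per bin: `bin`, `n`, `slope`, `r2`,
#'   `p_value`, `empty`.
#' @export
binned_distance_correlation <- function(pair_scores, distances, bin_edges,
                                        score_col = "mip",
                                        width_col = "mean_width") {
  need <- c("strain_a", "strain_b", score_col, width_col)
  missing_cols <- setdiff(need, names(pair_scores))
  if (length(missing_cols) > 0)
    stop("pair_scores lacks column(s): ", paste(missing_cols, collapse = ", "))
  known <- rownames(distances)
  bad <- !(pair_scores$strain_a %in% known & pair_scores$strain_b %in% known)
  if (any(bad))
    stop("no distance for pair(s): ",
         paste(paste(pair_scores$strain_a[bad], pair_scores$strain_b[bad],
                     sep = "-"), collapse = ", "))
  d <- distances[cbind(pair_scores$strain_a, pair_scores$strain_b)]
  bin <- cut(d, breaks = bin_edges, include.lowest = TRUE)
  rows <- lapply(levels(bin), function(lv) {
    idx <- which(bin == lv)
    if (length(idx) < 3) {
      return(data.frame(bin = lv, n = length(idx), slope = NA_real_,
                        r2 = NA_real_, p_value = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    f <- linreg(pair_scores[[width_col]][idx], pair_scores[[score_col]][idx])
    data.frame(bin = lv, n = length(idx), slope = f$slope, r2 = f$r2,
               p_value = f$p_value, empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of a strains x metabolites matrix
#'
#' Average-linkage clustering on Euclidean distances, applied to both
#' axes. Rows and columns are sorted by label before clustering, so the
#' dendrogram is invariant to the input ordering and ties are broken
#' deterministically.
#'
#' @param mat numeric matrix with dimnames; all entries must be finite.
#' @return an `nc_hclust` object: `row`, `col` (`hclust` objects),
#'   `row_order`, `col_order` (leaf label orders).
#' @export
hier_cluster <- function(mat) {
  if (!all(is.finite(mat))) stop("non-finite entries; impute before clustering")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix needs row and column names")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  hr <- stats::hclust(stats::dist(mat), method = "average")
  hc <- stats::hclust(stats::dist(t(mat)), method = "average")
  structure(list(row = hr, col = hc,
                 row_order = rownames(mat)[hr$order],
                 col_order = colnames(mat)[hc$order]),
            class = "nc_hclust")
}

#' @export
print.nc_hclust <- function(x, ...) {
  cat("<hier_cluster> ", length(x$row_order), " rows x ",
      length(x$col_order), " cols (average linkage, Euclidean)\n", sep = "")
  invisible(x)
}
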