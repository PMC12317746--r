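check_label_pair <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) < 1L) stop("empty label vectors")
  if (anyNA(labels_a) || anyNA(labels_b)) stop("labels must not be missing")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same units: 0
#' is the expectation under random labeling, 1 is perfect agreement.
#' Invariant to renaming of categories and symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return A number (<= 1).
#' @export
ari <- function(labels_a, labels_b) {
  check_label_pair(labels_a, labels_b)
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies (other normalizations: `"min"`, `"max"`,
#' `"sqrt"`): 0 means no shared information, 1 perfect correspondence. If
#' either labeling is constant the result is 0 by convention.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @param variant Entropy normalization, default `"mean"`.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b,
                variant = c("mean", "min", "max", "sqrt")) {
  variant <- match.arg(variant)
  check_label_pair(labels_a, labels_b)
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  denom <- switch(variant, mean = (ha + hb) / 2, min = min(ha, hb),
                  max = max(ha, hb), sqrt = sqrt(ha * hb))
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' Landmark co-localization index per domain
#'
#' Measures how strongly each spatial domain co-localizes with point
#' landmarks (e.g. amyloid-plaque centroids): for every cell, the
#' landmarks strictly closer than `radius` are counted, and the index of a
#' domain is the mean count over its cells. Monotone non-decreasing in
#' `radius`.
#'
#' @param coords Units x 2 matrix of cell positions.
#' @param domains Domain label per unit.
#' @param landmarks Landmarks x 2 matrix, same length units as `coords`.
#' @param radius Distance cutoff, strictly applied (default 20, i.e.
#'   20 micrometres when coordinates are in micrometres).
#' @return Named numeric vector, one mean landmark count per domain
#'   present; domains given as empty factor levels are reported `NA`.
#' @export
colocalization_index <- function(coords, domains, landmarks, radius = 20) {
  coords <- as.matrix(coords)
  if (length(domains) != nrow(coords))
    stop("one domain label per unit required")
  lv <- if (is.factor(domains)) levels(domains) else
    as.character(sort(unique(domains)))
  counts <- if (is.null(landmarks) || NROW(landmarks) == 0L) {
    numeric(nrow(coords))
  } else {
    landmarks <- as.matrix(landmarks)
    d2 <- outer(rowSums(coords^2), rowSums(landmarks^2), `+`) -
      2 * tcrossprod(coords, landmarks)
    rowSums(d2 < radius^2)
  }
  out <- vapply(lv, function(d) {
    idx <- which(as.character(domains) == d)
    if (length(idx) == 0L) NA_real_ else mean(counts[idx])
  }, 0)
  out
}
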