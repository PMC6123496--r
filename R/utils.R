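#' Raw median absolute deviation
#'
#' Median of absolute deviations from the median, *without* the 1.4826
#' normal-consistency constant. All data-derived QC thresholds in this
#' package use this literal definition; pass `constant` to rescale.
#'
#' @param x numeric vector.
#' @param constant multiplier applied to the raw MAD (default 1).
#' @return scalar raw MAD.
#' @export
mad_raw <- function(x, constant = 1) {
  constant * stats::median(abs(x - stats::median(x)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used throughout the recovery tests to compare inferred cluster or
#' subclone labels with simulation ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type; NAs dropped
#'   pairwise).
#' @return scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Mean silhouette width of a labeling
#'
#' @param labels integer/character cluster labels.
#' @param dmat full symmetric distance matrix.
#' @return mean silhouette over all points; NA if fewer than 2 clusters.
#' @keywords internal
mean_silhouette <- function(labels, dmat) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  if (length(uniq) < 2) return(NA_real_)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a_i <- if (any(own)) mean(dmat[i, own]) else 0
    b_i <- min(vapply(setdiff(uniq, labels[i]),
                      function(g) mean(dmat[i, labels == g]), numeric(1)))
    denom <- max(a_i, b_i)
    s[i] <- if (denom == 0) 0 else (b_i - a_i) / denom
  }
  mean(s)
}

# Order chromosomes naturally: 1..22 (optionally "chr"-prefixed), then X, Y,
# then anything else alphabetically.
chromosome_rank <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(stripped))
  rank <- ifelse(!is.na(num), num,
                 ifelse(stripped == "X", 100L,
                        ifelse(stripped == "Y", 101L, NA_integer_)))
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 102L + match(stripped[other], sort(unique(stripped[other])))
  }
  rank
}

`%||%` <- function(x, y) if (is.null(x)) y else x
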