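#' @importFrom methods is as
#' @importFrom stats rnbinom rbinom rpois rnorm runif rlnorm median quantile
#'   dist hclust cutree prcomp wilcox.test p.adjust pnorm chisq.test sd
#'   complete.cases setNames aggregate
#' @importFrom utils head combn modifyList read.csv write.csv
NULL

# Extract a genes x cells count matrix from a SingleCellExperiment or matrix.
.get_counts <- function(x, assay = "counts") {
  if (is(x, "SummarizedExperiment")) {
    return(SummarizedExperiment::assay(x, assay))
  }
  if (is.matrix(x) || is(x, "Matrix")) return(x)
  stop("expected a SingleCellExperiment or a matrix, got ", class(x)[1])
}

.stopifnot_named <- function(x, what) {
  if (is.null(rownames(x))) stop(what, " must have rownames (gene/probe ids)")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells; 1 for
#' identical partitions (up to label names), ~0 for independent ones. Used
#' throughout to score recovery of planted group structure.
#'
#' @param a,b label vectors of equal length (any coding).
#' @return the adjusted Rand index (a scalar, at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# Round-half-up to `digits` decimals (printed-table convention; R's round()
# uses banker's rounding which would give 33.74 where tables print 33.75).
.round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

.is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
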