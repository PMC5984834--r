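# GCF presence/absence profiling: Dice similarity between strain profiles,
# UPGMA dendrogram, and sample-based rarefaction of family richness.

#' Build the GCF presence/absence matrix
#'
#' Rows are strains, columns are gene cluster families; entry (s, f) is 1
#' when family f has at least one member BGC in strain s (binary — multiple
#' copies still count once). Columns are ordered by family class (fixed
#' class order) and, within a class, by decreasing abundance (number of
#' strains), ties broken by family id.
#'
#' @param partition A `gcf_partition` (see [assign_gcfs()]).
#' @param strains Character vector of strain ids fixing row order; defaults
#'   to the strains present in the partition, sorted.
#' @return Binary matrix with attribute `family_class` (named character
#'   vector of column classes).
#' @export
presence_absence <- function(partition, strains = NULL) {
  a <- partition$assignments
  if (is.null(strains)) strains <- sort(unique(a$genome_id))
  fam <- partition$families
  ab <- fam$n_strains
  cls_rank <- match(fam$class, BGC_CLASSES)
  ord <- order(cls_rank, -ab, fam$family_id)
  fam <- fam[ord, , drop = FALSE]
  m <- matrix(0L, nrow = length(strains), ncol = nrow(fam),
              dimnames = list(strains, fam$family_id))
  has <- unique(a[, c("genome_id", "family_id")])
  has <- has[has$genome_id %in% strains, , drop = FALSE]
  m[cbind(match(has$genome_id, strains), match(has$family_id, fam$family_id))] <- 1L
  attr(m, "family_class") <- setNames(fam$class, fam$family_id)
  m
}

#' Dice similarity between two binary presence/absence profiles
#'
#' `2 * |A intersect B| / (|A| + |B|)` over the sets of present families.
#' Two all-zero profiles share nothing and score 0.
#'
#' @param row_a,row_b Equal-length binary vectors.
#' @return Similarity in \[0, 1\].
#' @export
dice_similarity <- function(row_a, row_b) {
  if (length(row_a) != length(row_b))
    stop("profiles differ in length")
  a <- row_a != 0; b <- row_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(0)
  2 * sum(a & b) / denom
}

#' Pairwise Dice distance matrix (1 - Dice) between strain profiles
#'
#' @param mat Binary strain-by-family matrix.
#' @return Symmetric zero-diagonal distance matrix.
#' @export
dice_distance_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d[i, j] <- d[j, i] <- 1 - dice_similarity(mat[i, ], mat[j, ])
  }
  d
}

#' UPGMA (average-linkage) clustering to a rooted ultrametric tree
#'
#' Classic unweighted pair-group agglomeration: repeatedly merge the
#' closest pair of clusters, with the distance between clusters equal to
#' the arithmetic mean of all between-member distances. Node height is half
#' the merge distance, so leaves sit at height 0 and the tree is
#' ultrametric. Ties are broken deterministically by the lowest (row-major)
#' index pair, which matters on binary-profile distances where exact ties
#' are common.
#'
#' @param d Symmetric zero-diagonal distance matrix with dimnames, or a
#'   `dist` object.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (anyNA(d)) stop("NaN/NA distance")
  if (n == 1L) return(ape::read.tree(text = paste0(rownames(d), ";")))
  labels <- rownames(d)
  newick <- labels           # current Newick fragment per active cluster
  height <- rep(0, n)        # height of each active cluster's root
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  D <- d
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        if (D[i, j] < bestd - 1e-15) {
          bestd <- D[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- bestd / 2
    bl_i <- h - height[i]; bl_j <- h - height[j]
    newick[i] <- sprintf("(%s:%s,%s:%s)", newick[i], format_bl(bl_i),
                         newick[j], format_bl(bl_j))
    height[i] <- h
    # unweighted average of member-wise distances
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  ape::read.tree(text = paste0(newick[which(active)], ";"))
}

format_bl <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' Cut an ultrametric tree into k groups
#'
#' Recovers the k-cluster partition implied by an UPGMA dendrogram (e.g. to
#' compare profile-based strain groupings with known clades).
#'
#' @param tree Ultrametric `phylo` object.
#' @param k Number of groups (1 <= k <= number of leaves).
#' @return Named integer vector of group memberships per leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) stop("k must lie in 1..number of leaves")
  if (k == n) return(setNames(seq_len(n), tree$tip.label))
  D <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  stats::cutree(hc, k = k)[tree$tip.label]
}

#' Sample-based rarefaction of family richness
#'
#' Analytic (Mao Tau) expectation of the number of distinct families seen in
#' a random subsample of k strains:
#' `S(k) = S_obs - sum_j choose(n - n_j, k) / choose(n, k)`, where `n_j` is
#' the number of strains carrying family j. Optionally a Monte-Carlo mode
#' averages the observed richness over random k-subsets, reporting mean and
#' standard error.
#'
#' @param mat Binary strain-by-family incidence matrix (rows already
#'   restricted to the strain group of interest).
#' @param k Subsample sizes (default `1:nrow(mat)`); all must be `<= n`.
#' @param method `"exact"` (analytic) or `"montecarlo"`.
#' @param n_draws Number of random subsets in Monte-Carlo mode.
#' @return `data.frame` with columns `k`, `richness`, and in Monte-Carlo
#'   mode also `se` (standard error of the resampling mean).
#' @export
rarefaction <- function(mat, k = seq_len(nrow(mat)), method = "exact",
                        n_draws = 1000L) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 1L) stop("need at least one strain")
  if (any(k < 1L) || any(k > n)) stop("k must lie in 1..n")
  nj <- colSums(mat != 0)
  nj <- nj[nj > 0]
  s_obs <- length(nj)
  if (method == "exact") {
    rich <- vapply(k, function(kk) {
      # choose(n - nj, kk) / choose(n, kk) via lchoose for stability
      absent <- exp(lchoose(n - nj, kk) - lchoose(n, kk))
      s_obs - sum(absent)
    }, 0)
    return(data.frame(k = k, richness = rich))
  }
  if (method != "montecarlo") stop("unknown method '", method, "'")
  inc <- mat != 0
  out <- lapply(k, function(kk) {
    draws <- vapply(seq_len(n_draws), function(...) {
      rows <- sample.int(n, kk)
      sum(colSums(inc[rows, , drop = FALSE]) > 0)
    }, 0)
    data.frame(k = kk, richness = mean(draws),
               se = stats::sd(draws) / sqrt(n_draws))
  })
  do.call(rbind, out)
}

#' Rarefaction curves per strain group
#'
#' @param mat Binary strain-by-family matrix over all strains.
#' @param groups Named vector mapping strain id -> group label.
#' @param ... Passed to [rarefaction()].
#' @return `data.frame` with a `group` column prepended.
#' @export
rarefaction_by_group <- function(mat, groups, ...) {
  groups <- groups[rownames(mat)]
  out <- lapply(sort(unique(groups)), function(g) {
    sub <- mat[names(groups)[groups == g], , drop = FALSE]
    sub <- sub[, colSums(sub != 0) > 0, drop = FALSE]
    cbind(group = g, rarefaction(sub, ...))
  })
  do.call(rbind, out)
}
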