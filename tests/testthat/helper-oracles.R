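# Independent brute-force oracles used to verify the package's metric and
# clustering implementations. These deliberately recompute everything from
# first principles (explicit enumeration, naive agglomeration) and share no
# code with the implementation.

oracle_jaccard <- function(a, b) {
  u <- unique(c(names(a), names(b)))
  if (length(u) == 0) return(0)
  inter <- 0
  for (d in u) if (d %in% names(a) && d %in% names(b)) inter <- inter + 1
  inter / length(u)
}

oracle_ddi <- function(a, b) {
  u <- unique(c(names(a), names(b)))
  if (length(u) == 0) return(0)
  num <- 0; den <- 0
  for (d in u) {
    ad <- if (d %in% names(a)) a[[d]] else 0
    bd <- if (d %in% names(b)) b[[d]] else 0
    num <- num + abs(ad - bd)
    den <- den + max(ad, bd)
  }
  1 - num / den
}

oracle_dice <- function(ra, rb) {
  A <- which(ra != 0); B <- which(rb != 0)
  if (length(A) + length(B) == 0) return(0)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# Naive UPGMA: keeps explicit member lists and recomputes every
# between-cluster average from the original matrix at every step; merges
# the minimum (lowest row-major index pair on ties). Returns the implied
# cophenetic distance matrix (merge distance between any two leaves of the
# merged clusters).
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1L) {
    best <- NULL; bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Exhaustive sample-based rarefaction: mean richness over all k-subsets.
oracle_rarefaction_exact <- function(mat, k) {
  n <- nrow(mat)
  subsets <- combn(n, k)
  mean(apply(subsets, 2, function(rows)
    sum(colSums(mat[rows, , drop = FALSE] != 0) > 0)))
}

# Rotate-the-array oracle for oriC-relative positions: builds the physical
# order of original integer coordinates after linearization at the dnaA
# anchor (mirrored for a minus-strand dnaA) and reads off the index of the
# cluster midpoint. Requires an integer midpoint (even-length interval).
oracle_relative_position <- function(L, dnaA_start, dnaA_strand, start, end) {
  m <- ((start + end) / 2) %% L
  stopifnot(m == floor(m))
  order <- if (dnaA_strand == "+") c(dnaA_start:(L - 1), seq_len(dnaA_start) - 1)
  else c(dnaA_start:0, if (dnaA_start < L - 1) (L - 1):(dnaA_start + 1))
  (which(order == m) - 1) / L
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Truth-label partition for a generated dataset, usable by downstream
# profiling functions.
truth_partition <- function(ds) {
  tr <- ds$truth$bgc_truth
  cls <- vapply(all_bgcs(ds$genomes), function(b) b$bgc_class, "")
  gcf_partition_from_labels(tr$bgc_id, tr$genome_id,
                            unname(cls[tr$bgc_id]), tr$gcf)
}

truth_labels_for <- function(ds, bgc_ids) {
  tr <- ds$truth$bgc_truth
  tr$gcf[match(bgc_ids, tr$bgc_id)]
}

# small random domain-count vector over a compact alphabet (collisions
# between draws are likely, exercising partial overlaps)
random_domains <- function(max_types = 8, alphabet = 30) {
  k <- sample(0:max_types, 1)
  if (k == 0) return(setNames(integer(), character()))
  acc <- sample(sprintf("PF%05d", seq_len(alphabet)), k)
  setNames(sample(1:4, k, replace = TRUE), acc)
}

# minimal BGC carrying only what the similarity metrics need
domain_bgc <- function(id, domains, class = "Other", genome = "G",
                       source = "own") {
  bgc_record(bgc_id = id, genome_id = genome, bgc_class = class,
             start = 0, end = 1000, domains = domains, source = source)
}

# small BGC with explicit genes/roles/proteins for the family criteria
gene_bgc <- function(id, roles, proteins, class = "Other", genome = "G",
                     modules = NULL) {
  n <- length(roles)
  genes <- data.frame(
    gene_id = paste0(id, "_g", seq_len(n)),
    start = (seq_len(n) - 1) * 1000 + 10,
    end = (seq_len(n) - 1) * 1000 + 900,
    strand = "+", role = roles, protein = proteins,
    stringsAsFactors = FALSE)
  if (!is.null(modules)) genes$modules <- I(modules)
  bgc_record(bgc_id = id, genome_id = genome, bgc_class = class,
             start = 0, end = n * 1000,
             domains = setNames(rep(1L, n), sprintf("PF%05d", seq_len(n))),
             genes = genes)
}

random_protein_seq <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","V","Y"), len, TRUE),
        collapse = "")
}
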