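# Assignment of BGCs to gene cluster families by the four explicit criteria:
#   I   similar architecture (same class, shared gene-role composition)
#   II  majority of genes with the same function, order-insensitive
#   III majority of genes with >= 50% identity over >= 80% coverage
#   IV  for modular PKS/NRPS/hybrids, KS and C domains compared at the same
#       modular position, majority >= 80% identity
# Families are the connected components of the pairwise same-family relation
# (single linkage), mirroring the network treatment of GCFs.

#' Parameters for the gene-cluster-family criteria
#'
#' @param gene_identity_min Criterion III minimum identity (default 0.50).
#' @param gene_coverage_min Criterion III minimum coverage of the shorter
#'   protein (default 0.80).
#' @param module_domain_identity_min Criterion IV minimum identity of
#'   position-matched KS/C domains (default 0.80).
#' @param majority_fraction "Majority" cutoff; fractions must be strictly
#'   greater than this (default 0.5).
#' @param architecture_role_jaccard_min Criterion I floor on the multiset
#'   Jaccard of gene-role composition (default 0.5).
#' @return A `gcf_params` list.
#' @export
gcf_params <- function(gene_identity_min = 0.50, gene_coverage_min = 0.80,
                       module_domain_identity_min = 0.80,
                       majority_fraction = 0.5,
                       architecture_role_jaccard_min = 0.5) {
  p <- list(gene_identity_min = gene_identity_min,
            gene_coverage_min = gene_coverage_min,
            module_domain_identity_min = module_domain_identity_min,
            majority_fraction = majority_fraction,
            architecture_role_jaccard_min = architecture_role_jaccard_min)
  if (any(unlist(p) < 0 | unlist(p) > 1))
    stop("all gcf_params must lie in [0,1]")
  structure(p, class = "gcf_params")
}

#' Pairwise protein identity and coverage
#'
#' Local (Smith-Waterman) alignment under BLOSUM62 with affine gaps
#' (opening 10, extension 0.5). The shorter sequence is always taken as the
#' query, which makes the result symmetric by construction. Identity is
#' matches / aligned columns (gaps included); coverage is the aligned span of
#' the shorter sequence divided by its length. A non-positive optimal score
#' (no local similarity) yields identity 0, coverage 0.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (character).
#' @return Named numeric vector `c(identity=, coverage=)`.
#' @export
align_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("empty protein sequence")
  if (nchar(seq_b) < nchar(seq_a)) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  r <- align_many(seq_a, seq_b)
  c(identity = r$identity, coverage = r$coverage)
}

# Vectorized core: local alignment of many (short) patterns vs one subject.
# Patterns must each be no longer than the subject for the coverage
# convention; callers enforce the shorter-as-query rule.
align_many <- function(patterns, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM62", type = "local",
    gapOpening = 10, gapExtension = 0.5)
  sc <- Biostrings::score(al)
  ncols <- Biostrings::nchar(al)
  ident <- ifelse(sc > 0 & ncols > 0, Biostrings::nmatch(al) / ncols, 0)
  p <- Biostrings::pattern(al)
  span <- Biostrings::end(p) - Biostrings::start(p) + 1L
  cov <- ifelse(sc > 0, span / nchar(patterns), 0)
  list(identity = as.numeric(ident), coverage = as.numeric(cov),
       score = sc)
}

# Deterministic smaller/larger orientation: fewer genes first, ties broken
# by bgc_id so every criterion is symmetric in its arguments.
smaller_larger <- function(a, b) {
  if (nrow(a$genes) < nrow(b$genes) ||
      (nrow(a$genes) == nrow(b$genes) && a$bgc_id <= b$bgc_id))
    list(small = a, large = b)
  else list(small = b, large = a)
}

# Multiset Jaccard: sum of min counts / sum of max counts.
multiset_jaccard <- function(a, b) {
  ta <- table(a); tb <- table(b)
  u <- union(names(ta), names(tb))
  if (!length(u)) return(0)
  av <- ifelse(is.na(ta[u]), 0, ta[u]); bv <- ifelse(is.na(tb[u]), 0, tb[u])
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

# Elementwise local alignment of sequence pairs (one call for many pairs).
# Each pair is aligned with its shorter sequence as the query, so identity
# and coverage follow the align_identity() conventions.
align_pairs <- function(a, b) {
  swap <- nchar(b) < nchar(a)
  pat <- ifelse(swap, b, a); sub <- ifelse(swap, a, b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pat), Biostrings::AAStringSet(sub),
    substitutionMatrix = "BLOSUM62", type = "local",
    gapOpening = 10, gapExtension = 0.5)
  sc <- Biostrings::score(al)
  ncols <- Biostrings::nchar(al)
  ident <- ifelse(sc > 0 & ncols > 0, Biostrings::nmatch(al) / ncols, 0)
  p <- Biostrings::pattern(al)
  span <- Biostrings::end(p) - Biostrings::start(p) + 1L
  cov <- ifelse(sc > 0, span / nchar(pat), 0)
  list(identity = as.numeric(ident), coverage = as.numeric(cov))
}

# Fraction of `small`'s genes with a qualifying match (identity and
# coverage both at threshold) among `large`'s genes, from proteins or a
# supplied hit table. Same-role candidates are aligned first; only genes
# still unmatched fall back to all-vs-all against the remaining genes —
# the result ("has a qualifying match") is identical to exhaustive search.
gene_pass_fraction <- function(small, large, params, hits = NULL) {
  m <- nrow(small$genes)
  if (!is.null(hits)) {
    ok <- vapply(seq_len(m), function(i) {
      q <- small$genes$gene_id[i]
      h <- hits[(hits$query_id == q &
                   hits$subject_id %in% large$genes$gene_id) |
                (hits$subject_id == q &
                   hits$query_id %in% large$genes$gene_id), , drop = FALSE]
      any(h$identity >= params$gene_identity_min &
            h$query_coverage >= params$gene_coverage_min)
    }, TRUE)
    return(mean(ok))
  }
  pa <- small$genes$protein
  pb <- large$genes$protein
  if (anyNA(pa) || anyNA(pb))
    stop("criterion III needs protein sequences or a hit table")
  passes <- function(r) r$identity >= params$gene_identity_min &
    r$coverage >= params$gene_coverage_min
  ok <- logical(m)
  cand_i <- integer(); cand_j <- integer()
  for (i in seq_len(m)) {
    js <- which(large$genes$role == small$genes$role[i])
    cand_i <- c(cand_i, rep(i, length(js))); cand_j <- c(cand_j, js)
  }
  if (length(cand_i)) {
    r <- align_pairs(pa[cand_i], pb[cand_j])
    hit <- passes(r)
    ok[unique(cand_i[hit])] <- TRUE
  }
  todo <- which(!ok)
  if (length(todo)) {
    n <- length(pb)
    ei <- rep(todo, each = n); ej <- rep(seq_len(n), length(todo))
    done <- paste(cand_i, cand_j) # skip pairs already aligned
    fresh <- !(paste(ei, ej) %in% done)
    if (any(fresh)) {
      r <- align_pairs(pa[ei[fresh]], pb[ej[fresh]])
      hit <- passes(r)
      ok[unique(ei[fresh][hit])] <- TRUE
    }
  }
  mean(ok)
}

module_table <- function(bgc) {
  gl <- bgc$genes
  rows <- list()
  for (i in seq_len(nrow(gl))) {
    m <- gl$modules[[i]]
    if (is.null(m) || nrow(m) == 0L) next
    rows[[length(rows) + 1L]] <-
      data.frame(kind = m$kind, index = m$index, protein = gl$protein[i],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(kind = character(), index = integer(),
                      protein = character()))
  do.call(rbind, rows)
}

#' Evaluate the four same-family criteria for a BGC pair
#'
#' Criterion I: same product class and multiset Jaccard of gene roles at or
#' above the floor. Criterion II: more than `majority_fraction` of the
#' smaller cluster's genes have a role present in the other cluster
#' (order-insensitive). Criterion III: more than `majority_fraction` of the
#' smaller cluster's genes have a qualifying match in the other cluster at
#' `gene_identity_min` identity and `gene_coverage_min` coverage.
#' Criterion IV (modular classes only): KS and C domains paired by modular
#' position up to the shorter module list; the majority of compared pairs
#' must reach `module_domain_identity_min` identity. Extra modules on the
#' longer side do not veto membership. A modular pair with no module
#' annotation on either side reports criterion IV as `NA` (not applicable)
#' with a warning.
#'
#' @param a,b [bgc_record] objects with gene roles and proteins (or supply
#'   `hits`).
#' @param params A [gcf_params()] list.
#' @param hits Optional precomputed hit table (columns `query_id`,
#'   `subject_id`, `identity`, `query_coverage`) used instead of alignment.
#' @return List with logical `criterion_i` .. `criterion_iv` (`criterion_iv`
#'   may be `NA`), and `same_gcf`.
#' @export
criteria_report <- function(a, b, params = gcf_params(), hits = NULL) {
  if (nrow(a$genes) == 0L || nrow(b$genes) == 0L)
    stop("both BGCs need gene annotations with roles")
  sl <- smaller_larger(a, b)
  small <- sl$small; large <- sl$large

  c1 <- a$bgc_class == b$bgc_class &&
    multiset_jaccard(a$genes$role, b$genes$role) >=
      params$architecture_role_jaccard_min
  c2 <- mean(small$genes$role %in% large$genes$role) >
    params$majority_fraction

  c3 <- gene_pass_fraction(small, large, params, hits) >
    params$majority_fraction

  c4 <- criterion_iv(a, b, params)

  same <- c1 && c2 && c3 && (is.na(c4) || c4)
  list(criterion_i = c1, criterion_ii = c2, criterion_iii = c3,
       criterion_iv = c4, same_gcf = same)
}

# Verdict-only evaluation: short-circuits after a failing cheap criterion so
# alignment work is spent only on pairs that can still qualify. Agrees with
# criteria_report()$same_gcf on every pair.
same_gcf_fast <- function(a, b, params, hits = NULL) {
  if (a$bgc_class != b$bgc_class) return(FALSE)
  if (multiset_jaccard(a$genes$role, b$genes$role) <
      params$architecture_role_jaccard_min) return(FALSE)
  sl <- smaller_larger(a, b)
  small <- sl$small; large <- sl$large
  if (mean(small$genes$role %in% large$genes$role) <=
      params$majority_fraction) return(FALSE)
  if (gene_pass_fraction(small, large, params, hits) <=
      params$majority_fraction) return(FALSE)
  c4 <- criterion_iv(a, b, params, warn = FALSE)
  is.na(c4) || c4
}

# Criterion IV: position-matched KS/C domain identity (modular classes).
# Returns NA when not applicable (non-modular class, or no module
# annotation on at least one side).
criterion_iv <- function(a, b, params, warn = TRUE) {
  if (!a$bgc_class %in% MODULAR_CLASSES) return(NA)
  ma <- module_table(a); mb <- module_table(b)
  if (nrow(ma) == 0L || nrow(mb) == 0L) {
    if (warn)
      warning("modular class but no module domains on at least one side; ",
              "criterion IV not applicable for pair ",
              a$bgc_id, " / ", b$bgc_id)
    return(NA)
  }
  left <- character(); right <- character()
  for (kind in intersect(unique(ma$kind), unique(mb$kind))) {
    ka <- ma[ma$kind == kind, ]; kb <- mb[mb$kind == kind, ]
    ka <- ka[order(ka$index), ]; kb <- kb[order(kb$index), ]
    k <- min(nrow(ka), nrow(kb))
    left <- c(left, ka$protein[seq_len(k)])
    right <- c(right, kb$protein[seq_len(k)])
  }
  if (!length(left)) return(NA)
  idents <- align_pairs(left, right)$identity
  mean(idents >= params$module_domain_identity_min) >
    params$majority_fraction
}

#' Group BGCs into gene cluster families
#'
#' Families are the connected components (single-linkage closure) of the
#' graph whose edges are the BGC pairs satisfying [criteria_report()].
#' Cross-class pairs fail criterion I by definition, so only within-class
#' pairs are candidates. Candidate pairs are examined in order of decreasing
#' domain-content similarity with a union-find structure, and a pair already
#' connected through previously accepted edges is skipped; the resulting
#' partition is identical to exhaustive all-vs-all evaluation, because a
#' skipped pair's verdict cannot alter connectivity.
#'
#' @param bgcs List of [bgc_record] (own-source).
#' @param params A [gcf_params()] list.
#' @param hits Optional hit table passed through to [criteria_report()].
#' @param sim_params [similarity_params()] used only to order candidate
#'   pairs (never to decide membership).
#' @return A `gcf_partition`: list with `assignments` (data.frame `bgc_id`,
#'   `genome_id`, `bgc_class`, `family_id`) and `families` (data.frame
#'   `family_id`, `n_members`, `n_strains`, `class`). Family ids are
#'   `"GCF:"` + the lexicographically smallest member id.
#' @export
assign_gcfs <- function(bgcs, params = gcf_params(), hits = NULL,
                        sim_params = similarity_params()) {
  if (length(bgcs) < 1L) stop("need at least one BGC")
  bgcs <- bgcs[order(vapply(bgcs, `[[`, "", "bgc_id"))]
  ids <- vapply(bgcs, `[[`, "", "bgc_id")
  classes <- vapply(bgcs, `[[`, "", "bgc_class")
  n <- length(bgcs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  S <- pairwise_domain_similarity(bgcs, sim_params)
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    if (length(idx) < 2L) next
    pairs <- t(combn(idx, 2L))
    sims <- S[pairs]
    ord <- order(-sims, pairs[, 1], pairs[, 2])
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      if (same_gcf_fast(bgcs[[i]], bgcs[[j]], params, hits))
        parent[min(ri, rj)] <- max(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  fam_id <- vapply(split(ids, roots), function(m) paste0("GCF:", min(m)), "")
  assignments <- data.frame(
    bgc_id = ids,
    genome_id = vapply(bgcs, `[[`, "", "genome_id"),
    bgc_class = classes,
    family_id = unname(fam_id[as.character(roots)]),
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 families = summarize_families(assignments)),
            class = "gcf_partition")
}

summarize_families <- function(assignments) {
  sp <- split(assignments, assignments$family_id)
  fam <- data.frame(
    family_id = names(sp),
    n_members = vapply(sp, nrow, 1L),
    n_strains = vapply(sp, function(d) length(unique(d$genome_id)), 1L),
    class = vapply(sp, function(d)
      names(sort(table(d$bgc_class), decreasing = TRUE))[1], ""),
    stringsAsFactors = FALSE, row.names = NULL)
  fam[order(fam$family_id), , drop = FALSE]
}

#' Build a partition object from known family labels
#'
#' Useful for profiling a manually curated (or simulated ground-truth)
#' family assignment with the same downstream machinery.
#'
#' @param bgc_id,genome_id,bgc_class,family_id Equal-length vectors.
#' @return A `gcf_partition`.
#' @export
gcf_partition_from_labels <- function(bgc_id, genome_id, bgc_class,
                                      family_id) {
  assignments <- data.frame(bgc_id = bgc_id, genome_id = genome_id,
                            bgc_class = bgc_class, family_id = family_id,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 families = summarize_families(assignments)),
            class = "gcf_partition")
}

#' @export
print.gcf_partition <- function(x, ...) {
  cat(sprintf("<gcf_partition> %d BGCs in %d families across %d strains\n",
              nrow(x$assignments), nrow(x$families),
              length(unique(x$assignments$genome_id))))
  invisible(x)
}

#' Categorize families by strain frequency
#'
#' A family present in four or more strains is `common`, in two or three
#' strains `rare`, and in exactly one strain `unique` (strain count, not BGC
#' count: two copies in one strain are still `unique`).
#'
#' @param partition A `gcf_partition`.
#' @return The partition with `families$category` added and a `frequency`
#'   data.frame (category, n_families, fraction) attached.
#' @export
categorize_gcfs <- function(partition) {
  fam <- partition$families
  if (any(fam$n_members < 1L)) stop("empty family encountered")
  fam$category <- ifelse(fam$n_strains >= 4L, "common",
                         ifelse(fam$n_strains >= 2L, "rare", "unique"))
  freq <- data.frame(category = c("common", "rare", "unique"))
  freq$n_families <- vapply(freq$category,
                            function(k) sum(fam$category == k), 1L)
  freq$fraction <- freq$n_families / nrow(fam)
  partition$families <- fam
  partition$frequency <- freq
  partition
}
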