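# Pfam-domain-content similarity between BGCs and the thresholded
# similarity network built from it.

#' Parameters for the combined domain-content similarity
#'
#' The combined score is `w_jaccard * J + w_ddi * DDI`, where `J` is the
#' Jaccard index over distinct Pfam domain types and `DDI` the domain
#' duplication index, a copy-number-aware similarity. An edge is drawn
#' between two BGCs when the combined score reaches `threshold`. The 0.65
#' threshold is the value that best reproduces manually curated families on
#' actinomycete cluster sets; the weights follow the customary
#' Jaccard/duplication combination and are fully configurable.
#'
#' @param w_jaccard,w_ddi Non-negative weights summing to 1.
#' @param threshold Edge threshold in \[0, 1\].
#' @return A `similarity_params` list.
#' @export
similarity_params <- function(w_jaccard = 0.36, w_ddi = 0.64,
                              threshold = 0.65) {
  if (w_jaccard < 0 || w_ddi < 0) stop("weights must be non-negative")
  if (abs(w_jaccard + w_ddi - 1) > 1e-9) stop("weights must sum to 1")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0,1]")
  structure(list(w_jaccard = w_jaccard, w_ddi = w_ddi,
                 threshold = threshold), class = "similarity_params")
}

domains_of <- function(x) {
  if (inherits(x, "bgc_record")) x$domains else x
}

#' Jaccard index over distinct Pfam domain types
#'
#' `J = |Da intersect Db| / |Da union Db|` over distinct domain accessions;
#' two clusters with no annotated domains share no evidence of relatedness,
#' so the empty-vs-empty case is defined as 0.
#'
#' @param a,b [bgc_record] objects or named integer domain-count vectors.
#' @return Similarity in \[0, 1\].
#' @export
domain_jaccard <- function(a, b) {
  da <- names(domains_of(a)); db <- names(domains_of(b))
  u <- length(union(da, db))
  if (u == 0L) return(0)
  length(intersect(da, db)) / u
}

#' Domain duplication index (copy-number-aware similarity)
#'
#' Over the union `U` of domain types with copy counts `a_d`, `b_d` (0 when
#' absent): `DDI = 1 - sum |a_d - b_d| / sum max(a_d, b_d)`. Identical count
#' vectors give 1, disjoint non-empty clusters give 0. Two clusters that are
#' both unannotated give 0 with a warning (no evidence).
#'
#' @inheritParams domain_jaccard
#' @return Similarity in \[0, 1\].
#' @export
domain_duplication_similarity <- function(a, b) {
  da <- domains_of(a); db <- domains_of(b)
  u <- union(names(da), names(db))
  if (length(u) == 0L) {
    warning("both clusters have empty domain annotation; DDI defined as 0")
    return(0)
  }
  av <- ifelse(is.na(da[u]), 0L, da[u])
  bv <- ifelse(is.na(db[u]), 0L, db[u])
  1 - sum(abs(av - bv)) / sum(pmax(av, bv))
}

#' Combined weighted domain-content similarity
#'
#' @inheritParams domain_jaccard
#' @param params A [similarity_params()] list.
#' @return `w_jaccard * J + w_ddi * DDI` in \[0, 1\].
#' @export
combined_similarity <- function(a, b, params = similarity_params()) {
  da <- domains_of(a); db <- domains_of(b)
  if (length(da) == 0L && length(db) == 0L) return(0)
  params$w_jaccard * domain_jaccard(da, db) +
    params$w_ddi * domain_duplication_similarity(da, db)
}

#' Build the thresholded BGC similarity network
#'
#' All-vs-all combined domain similarity; an undirected edge is kept when
#' the score reaches `params$threshold`. Nodes carry `source`, `class` and
#' `genome` attributes; connected components are the network's gene cluster
#' groupings.
#'
#' @param bgcs List of [bgc_record] (own and/or reference clusters).
#' @param params A [similarity_params()] list.
#' @return A `similarity_network`: list with `graph` (igraph),
#'   `components` (named membership vector), `n_components`, `n_singletons`.
#' @export
build_network <- function(bgcs, params = similarity_params()) {
  if (length(bgcs) < 1L) stop("need at least one BGC")
  ids <- vapply(bgcs, `[[`, "", "bgc_id")
  if (anyDuplicated(ids)) stop("duplicated bgc_id in input")
  n <- length(bgcs)
  edges <- integer(); weights <- numeric()
  if (n > 1L) {
    S <- pairwise_domain_similarity(bgcs, params)
    keep <- which(upper.tri(S) & S >= params$threshold, arr.ind = TRUE)
    keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
    edges <- rbind(keep[, 1], keep[, 2])
    weights <- S[keep]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = unname(ids))
  g <- igraph::set_vertex_attr(g, "source", value =
                                 vapply(bgcs, `[[`, "", "source"))
  g <- igraph::set_vertex_attr(g, "class", value =
                                 vapply(bgcs, `[[`, "", "bgc_class"))
  g <- igraph::set_vertex_attr(g, "genome", value =
                                 vapply(bgcs, `[[`, "", "genome_id"))
  if (length(weights)) {
    g <- igraph::add_edges(g, as.vector(edges))
    g <- igraph::set_edge_attr(g, "weight", value = weights)
  }
  g <- igraph::set_graph_attr(g, "threshold", params$threshold)
  as_similarity_network(g)
}

# Full pairwise combined-similarity matrix, computed by linear algebra on
# the BGC x domain count matrix; agrees entry-wise with
# combined_similarity() (the scalar definitions are the reference and are
# oracle-tested against it).
pairwise_domain_similarity <- function(bgcs, params = similarity_params()) {
  doms <- lapply(bgcs, `[[`, "domains")
  acc <- sort(unique(unlist(lapply(doms, names))))
  n <- length(bgcs)
  if (!length(acc)) return(matrix(0, n, n))
  C <- matrix(0, n, length(acc), dimnames = list(NULL, acc))
  for (i in seq_len(n)) if (length(doms[[i]])) C[i, names(doms[[i]])] <-
      doms[[i]]
  B <- C > 0
  inter <- tcrossprod(B * 1)
  sizes <- rowSums(B)
  uni <- outer(sizes, sizes, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  l1 <- as.matrix(stats::dist(C, method = "manhattan"))
  copies <- rowSums(C)
  summax <- (outer(copies, copies, "+") + l1) / 2
  ddi <- ifelse(summax > 0, 1 - l1 / summax, 0)
  S <- params$w_jaccard * J + params$w_ddi * ddi
  diag(S) <- 1
  S[sizes == 0, ] <- 0
  S[, sizes == 0] <- 0
  S
}

as_similarity_network <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  structure(list(graph = g,
                 components = setNames(comp$membership,
                                       igraph::V(g)$name),
                 n_components = comp$no,
                 n_singletons = sum(sizes == 1L)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d BGCs, %d edges, %d components (%d singletons)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_components, x$n_singletons))
  invisible(x)
}

#' Classify network components by their source composition
#'
#' For a network built over own-study plus reference (e.g. MIBiG-derived)
#' clusters, counts the components containing only own clusters, only
#' reference clusters, or both, and the own-only singletons — the accounting
#' used to gauge how much of a genus' biosynthetic repertoire is unknown.
#'
#' @param network A `similarity_network` whose nodes all carry a `source`
#'   attribute (`"own"` or `"reference"`).
#' @return List with `own_only`, `reference_only`, `mixed`,
#'   `own_only_singletons`, and `n_components` (their total).
#' @export
partition_vs_reference <- function(network) {
  src <- igraph::V(network$graph)$source
  if (is.null(src) || anyNA(src) || any(!nzchar(src)))
    stop("every node must carry a source label")
  memb <- network$components
  comp_src <- split(src, memb)
  kinds <- vapply(comp_src, function(s) {
    has_own <- any(s == "own"); has_ref <- any(s == "reference")
    if (has_own && has_ref) "mixed" else if (has_own) "own" else "reference"
  }, "")
  sizes <- lengths(comp_src)
  list(own_only = sum(kinds == "own"),
       reference_only = sum(kinds == "reference"),
       mixed = sum(kinds == "mixed"),
       own_only_singletons = sum(kinds == "own" & sizes == 1L),
       n_components = length(kinds))
}
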