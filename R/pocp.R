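# Percentage of conserved proteins (POCP) between genome pairs and the
# genus-boundary rule (two strains of one genus share >= 50% of proteins).

#' Parameters for POCP computation
#'
#' A protein counts as conserved when it has at least one hit in the other
#' proteome with e-value at most `evalue_max`, identity at least
#' `identity_min`, and aligned fraction of the query at least
#' `aligned_fraction_min`. The cutoffs follow the originally proposed POCP
#' procedure (1e-5 / 40% / 50%); the genus boundary is a POCP of at least
#' `genus_threshold` percent.
#'
#' @param evalue_max,identity_min,aligned_fraction_min Hit cutoffs.
#' @param genus_threshold Same-genus POCP threshold in percent.
#' @return A `pocp_params` list.
#' @export
pocp_params <- function(evalue_max = 1e-5, identity_min = 0.40,
                        aligned_fraction_min = 0.50, genus_threshold = 50.0) {
  if (identity_min < 0 || identity_min > 1 ||
      aligned_fraction_min < 0 || aligned_fraction_min > 1)
    stop("identity_min and aligned_fraction_min must lie in [0,1]")
  if (genus_threshold < 0 || genus_threshold > 100)
    stop("genus_threshold must lie in [0,100]")
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 aligned_fraction_min = aligned_fraction_min,
                 genus_threshold = genus_threshold), class = "pocp_params")
}

conserved_count <- function(hits, params) {
  if (is.null(hits) || nrow(hits) == 0L) return(0L)
  pass <- hits$identity >= params$identity_min &
    hits$query_coverage >= params$aligned_fraction_min
  if ("evalue" %in% names(hits)) {
    ev <- hits$evalue
    pass <- pass & (is.na(ev) | ev <= params$evalue_max)
  }
  length(unique(hits$query_id[pass]))
}

#' Percentage of conserved proteins between two genomes
#'
#' `POCP = (C_a + C_b) / (T_a + T_b) * 100`, with `C_a` the number of
#' distinct proteins of genome A having at least one qualifying hit in B
#' (and `C_b` symmetric), and `T_a`, `T_b` the proteome sizes. The measure
#' is symmetric under swapping the genomes.
#'
#' @param hits_ab Hit table of A-vs-B searches (columns `query_id`,
#'   `subject_id`, `identity`, `query_coverage`, optional `evalue`).
#' @param hits_ba Hit table of B-vs-A searches.
#' @param t_a,t_b Proteome sizes (number of proteins), both >= 1.
#' @param params A [pocp_params()] list.
#' @return List with `pocp` (percentage in \[0, 100\]), `conserved_a`,
#'   `conserved_b`, and `same_genus`.
#' @export
pocp <- function(hits_ab, hits_ba, t_a, t_b, params = pocp_params()) {
  if (t_a < 1L || t_b < 1L) stop("proteome sizes must be >= 1")
  c_a <- conserved_count(hits_ab, params)
  c_b <- conserved_count(hits_ba, params)
  val <- (c_a + c_b) / (t_a + t_b) * 100
  list(pocp = val, conserved_a = c_a, conserved_b = c_b,
       same_genus = val >= params$genus_threshold)
}

#' POCP directly from protein sequences
#'
#' Desk-scale alternative to an external search tool: all-vs-all local
#' alignments ([align_identity()]) generate the two hit tables, which are
#' then scored by [pocp()]. No e-value is produced in this mode, so only
#' the identity and aligned-fraction cutoffs apply.
#'
#' @param proteome_a,proteome_b Named character vectors of amino-acid
#'   sequences.
#' @param params A [pocp_params()] list.
#' @param max_proteins Refuse larger inputs (supply precomputed hit tables
#'   instead); default 500.
#' @return As [pocp()].
#' @export
pocp_from_sequences <- function(proteome_a, proteome_b,
                                params = pocp_params(), max_proteins = 500L) {
  if (length(proteome_a) > max_proteins || length(proteome_b) > max_proteins)
    stop("proteome exceeds ", max_proteins,
         " proteins; supply precomputed hit tables to pocp() instead")
  if (!length(proteome_a) || !length(proteome_b))
    stop("proteome sizes must be >= 1")
  if (is.null(names(proteome_a))) names(proteome_a) <-
      paste0("a", seq_along(proteome_a))
  if (is.null(names(proteome_b))) names(proteome_b) <-
      paste0("b", seq_along(proteome_b))
  hits_dir <- function(qs, ss) {
    rows <- list()
    for (si in seq_along(ss)) {
      # all queries against one subject in a single vectorized alignment
      # call; coverage here is the aligned fraction of the query
      r <- align_many(unname(qs), ss[[si]])
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(qs), subject_id = names(ss)[si],
        identity = r$identity, query_coverage = r$coverage,
        evalue = NA_real_, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  pocp(hits_dir(proteome_a, proteome_b), hits_dir(proteome_b, proteome_a),
       length(proteome_a), length(proteome_b), params)
}

#' POCP matrix over a set of proteomes
#'
#' @param proteomes Named list of named character vectors.
#' @param params A [pocp_params()] list.
#' @return Symmetric matrix of POCP percentages (diagonal 100).
#' @export
pocp_matrix <- function(proteomes, params = pocp_params()) {
  n <- length(proteomes)
  m <- matrix(100, n, n, dimnames = list(names(proteomes), names(proteomes)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <-
      pocp_from_sequences(proteomes[[i]], proteomes[[j]], params)$pocp
  }
  m
}
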