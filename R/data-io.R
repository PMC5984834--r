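# Readers and writers for the tabular exchange formats of the pipeline.
# Conventions: all coordinates 0-based, half-open, forward-strand frame.

BGC_TABLE_COLUMNS <- c("genome_id", "bgc_id", "bgc_class", "bgc_start",
                       "bgc_end", "gene_id", "gene_start", "gene_end",
                       "strand", "role", "domains", "module_domains",
                       "protein_id")

#' Read a per-gene BGC annotation table
#'
#' One row per gene. Rows sharing (`genome_id`, `bgc_id`) are aggregated into
#' a single [bgc_record]; the cluster's Pfam-domain multiset is the sum of
#' copy numbers over its gene rows. The `domains` column holds
#' semicolon-separated `"PFxxxxx:copies"` tokens, `module_domains` holds
#' `"KS:1"` / `"C:2"` tokens (kind:module-index).
#'
#' @param path TSV file with header columns
#'   `genome_id, bgc_id, bgc_class, bgc_start, bgc_end, gene_id, gene_start,
#'   gene_end, strand, role, domains, module_domains, protein_id`.
#' @param source_label `"own"` or `"reference"`.
#' @param proteins Optional named character vector (or `AAStringSet`) mapping
#'   `protein_id` to amino-acid sequence.
#' @return Named list of [bgc_record].
#' @export
read_bgc_table <- function(path, source_label = "own", proteins = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character")
  missing <- setdiff(BGC_TABLE_COLUMNS, names(tab))
  if (length(missing))
    stop("BGC table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(proteins))
    proteins <- setNames(as.character(proteins), names(proteins))
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric value in column '", col, "'")
    v
  }
  tab$bgc_start <- num(tab$bgc_start, "bgc_start")
  tab$bgc_end <- num(tab$bgc_end, "bgc_end")
  tab$gene_start <- num(tab$gene_start, "gene_start")
  tab$gene_end <- num(tab$gene_end, "gene_end")
  bad <- which(tab$gene_end <= tab$gene_start)
  if (length(bad))
    stop("gene end <= start at row ", bad[1], " of '", path, "'")
  bad <- which(tab$bgc_end <= tab$bgc_start)
  if (length(bad))
    stop("BGC end <= start at row ", bad[1], " of '", path, "'")

  key <- paste(tab$genome_id, tab$bgc_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
                function(rows) {
    sub <- tab[rows, , drop = FALSE]
    dom <- parse_domain_tokens(unlist(lapply(sub$domains, split_tokens)))
    genes <- data.frame(
      gene_id = sub$gene_id, start = sub$gene_start, end = sub$gene_end,
      strand = sub$strand, role = sub$role,
      protein = if (is.null(proteins)) NA_character_
                else unname(proteins[sub$protein_id]),
      stringsAsFactors = FALSE)
    genes$modules <- I(lapply(sub$module_domains, parse_module_tokens))
    genes$domains <- I(lapply(sub$domains, function(x) {
      d <- parse_domain_tokens(split_tokens(x))
      if (length(d)) d else NULL
    }))
    bgc_record(bgc_id = sub$bgc_id[1], genome_id = sub$genome_id[1],
               bgc_class = sub$bgc_class[1],
               start = sub$bgc_start[1], end = sub$bgc_end[1],
               genes = genes, domains = dom, source = source_label)
  })
  names(out) <- vapply(out, `[[`, "", "bgc_id")
  out
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

parse_domain_tokens <- function(tokens) {
  if (!length(tokens)) return(setNames(integer(), character()))
  parts <- strsplit(tokens, ":", fixed = TRUE)
  acc <- vapply(parts, `[`, "", 1L)
  cp <- vapply(parts, function(p) {
    if (length(p) < 2L) 1L else as.integer(p[2L])
  }, 1L)
  agg <- tapply(cp, acc, sum)
  setNames(as.integer(agg), names(agg))
}

parse_module_tokens <- function(x) {
  tokens <- split_tokens(x)
  if (!length(tokens)) return(NULL)
  parts <- strsplit(tokens, ":", fixed = TRUE)
  data.frame(kind = vapply(parts, `[`, "", 1L),
             index = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read a genome metadata table
#'
#' @param path TSV with columns `genome_id, length, topology, dnaA_start,
#'   dnaA_strand` and optionally `clade`.
#' @return List of [genome_record] (BGC lists empty; see [attach_bgcs()]).
#' @export
read_genome_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  needed <- c("genome_id", "length", "topology", "dnaA_start", "dnaA_strand")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("genome table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  has_clade <- "clade" %in% names(tab)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    genome_record(genome_id = as.character(tab$genome_id[i]),
                  length = tab$length[i], topology = tab$topology[i],
                  dnaA_start = tab$dnaA_start[i],
                  dnaA_strand = tab$dnaA_strand[i],
                  clade = if (has_clade) as.character(tab$clade[i]) else NA)
  })
  names(out) <- vapply(out, `[[`, "", "genome_id")
  out
}

#' Read conserved-region intervals from a BED file
#'
#' @param path BED file (>= 3 columns, 0-based half-open). Intervals are
#'   sorted and overlapping ones merged.
#' @param seqname Optional: keep only lines whose first (sequence-name)
#'   column equals this value, e.g. one genome of a multi-genome BED.
#' @return 2-column matrix (`start`, `end`) of disjoint intervals.
#' @export
read_regions_bed <- function(path, seqname = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!is.null(seqname) && length(lines))
    lines <- lines[vapply(strsplit(lines, "\t", fixed = TRUE),
                          `[`, "", 1L) == seqname]
  if (!length(lines))
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("BED line with fewer than 3 columns in '", path, "'")
  s <- vapply(fields, `[`, "", 2L)
  e <- vapply(fields, `[`, "", 3L)
  if (any(!grepl("^-?[0-9]+$", c(s, e))))
    stop("non-integer coordinates in BED file '", path, "'")
  s <- as.numeric(s); e <- as.numeric(e)
  if (any(s < 0)) stop("negative coordinate in BED file '", path, "'")
  if (any(s >= e)) stop("BED interval with start >= end in '", path, "'")
  merge_intervals(cbind(s, e))
}

#' Write a similarity network as GraphML and edge-list TSV
#'
#' @param network A [build_network()] result.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  g <- network$graph
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("bgc_a", "bgc_b")
    write.table(el, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Read a network back from GraphML
#'
#' @param path GraphML file written by [write_network()].
#' @return A `similarity_network` object (threshold recovered from the graph
#'   attribute stored at write time).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  as_similarity_network(g)
}

#' Write/read a binary presence/absence matrix as TSV
#'
#' Rows are strains, columns are GCFs; row names in the first column.
#' @param mat Binary matrix.
#' @param path Output/input TSV.
#' @return `write_matrix_tsv`: invisible path; `read_matrix_tsv`: the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(strain = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a rooted tree to Newick
#'
#' @param tree `phylo` object.
#' @param path Output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector keyed by the first word of each header.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read a precomputed protein hit table
#'
#' @param path TSV with columns `query_id, subject_id, identity,
#'   query_coverage` and optionally `evalue` (identity and coverage as
#'   fractions in \[0, 1\]).
#' @return Validated `data.frame` of hits.
#' @export
read_hit_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
  needed <- c("query_id", "subject_id", "identity", "query_coverage")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("hit table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"evalue" %in% names(tab)) tab$evalue <- NA_real_
  with(tab, {
    if (any(identity < 0 | identity > 1, na.rm = TRUE))
      stop("identity outside [0,1] in '", path, "'")
    if (any(query_coverage < 0 | query_coverage > 1, na.rm = TRUE))
      stop("query_coverage outside [0,1] in '", path, "'")
  })
  tab
}
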