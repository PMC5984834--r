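#' Construct a biosynthetic gene cluster record
#'
#' A `bgc_record` bundles everything downstream stages need about one BGC:
#' its genomic interval, its genes (with functional roles, protein sequences
#' and KS/C module positions), and its aggregated Pfam-domain content.
#'
#' All coordinates are 0-based, half-open, in the forward-strand frame of the
#' deposited sequence. On circular replicons a cluster spanning the origin is
#' represented with `end > genome length`; positions are interpreted modulo
#' the genome length.
#'
#' @param bgc_id Unique cluster identifier.
#' @param genome_id Identifier of the genome carrying the cluster.
#' @param bgc_class Product class, one of `"PKS"`, `"NRPS"`,
#'   `"PKS/NRPS-hybrid"`, `"RiPP"`, `"Terpene"`, `"Other"`.
#' @param start,end Cluster interval (0-based, half-open); `start < end`.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `role` (free-text functional role), `protein`
#'   (amino-acid sequence or `NA`), and a list-column `modules` whose entries
#'   are data frames with columns `kind` (`"KS"`/`"C"`) and `index`
#'   (1-based module position, strictly increasing within a gene).
#' @param domains Named integer vector of Pfam accession -> copy number. If
#'   `NULL`, aggregated from per-gene annotation is expected upstream.
#' @param source `"own"` for study genomes, `"reference"` for external
#'   (MIBiG-like) clusters used only for network comparison.
#' @return An object of class `bgc_record`.
#' @export
bgc_record <- function(bgc_id, genome_id, bgc_class, start, end,
                       genes = empty_gene_table(), domains = integer(),
                       source = "own") {
  stopifnot(is.character(bgc_id), nchar(bgc_id) > 0L,
            is.character(genome_id))
  if (!bgc_class %in% BGC_CLASSES)
    stop("unknown bgc_class '", bgc_class, "'; expected one of: ",
         paste(BGC_CLASSES, collapse = ", "))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("BGC '", bgc_id, "': start must be < end")
  if (start < 0) stop("BGC '", bgc_id, "': negative start coordinate")
  domains <- validate_domains(domains, bgc_id)
  genes <- validate_genes(genes, bgc_id, start, end)
  # when both cluster-level and per-gene domain annotation are present they
  # must agree (cluster multiset = sum over genes)
  gene_dom <- aggregate_gene_domains(genes)
  if (length(gene_dom) && length(domains)) {
    if (!identical(gene_dom[order(names(gene_dom))],
                   domains[order(names(domains))]))
      stop("BGC '", bgc_id,
           "': cluster domains inconsistent with per-gene annotation")
  } else if (length(gene_dom) && !length(domains)) {
    domains <- gene_dom
  }
  if (!source %in% c("own", "reference"))
    stop("source must be 'own' or 'reference'")
  structure(list(bgc_id = bgc_id, genome_id = genome_id,
                 bgc_class = bgc_class, start = start, end = end,
                 genes = genes, domains = domains, source = source),
            class = "bgc_record")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), start = numeric(), end = numeric(),
             strand = character(), role = character(), protein = character(),
             modules = I(list()), stringsAsFactors = FALSE)
}

validate_domains <- function(domains, bgc_id) {
  if (is.null(domains)) return(integer())
  if (length(domains) == 0L) return(setNames(integer(), character()))
  domains <- setNames(as.integer(domains), names(domains))
  if (is.null(names(domains)) || any(!nzchar(names(domains))))
    stop("BGC '", bgc_id, "': domain accessions must be non-empty names")
  if (any(domains < 1L))
    stop("BGC '", bgc_id, "': domain copy numbers must be >= 1")
  if (anyDuplicated(names(domains)))
    stop("BGC '", bgc_id, "': duplicated domain accession")
  domains
}

validate_genes <- function(genes, bgc_id, bgc_start, bgc_end) {
  needed <- c("gene_id", "start", "end", "strand", "role", "protein")
  missing <- setdiff(needed, names(genes))
  if (length(missing))
    stop("gene table for '", bgc_id, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!"modules" %in% names(genes))
    genes$modules <- I(replicate(nrow(genes), NULL, simplify = FALSE))
  if (!"domains" %in% names(genes))
    genes$domains <- I(replicate(nrow(genes), NULL, simplify = FALSE))
  if (nrow(genes)) {
    if (any(genes$start >= genes$end))
      stop("BGC '", bgc_id, "': gene with start >= end")
    if (any(genes$start < bgc_start) || any(genes$end > bgc_end))
      stop("BGC '", bgc_id, "': gene outside the cluster interval")
    for (m in genes$modules) {
      if (is.null(m) || nrow(m) == 0L) next
      for (kind in unique(m$kind)) {
        idx <- m$index[m$kind == kind]
        if (any(diff(idx) <= 0))
          stop("BGC '", bgc_id,
               "': module indices must be strictly increasing within a gene")
      }
    }
  }
  genes
}

aggregate_gene_domains <- function(genes) {
  doms <- genes$domains
  if (is.null(doms)) return(integer())
  doms <- doms[!vapply(doms, is.null, TRUE)]
  if (!length(doms)) return(integer())
  all_acc <- unlist(lapply(doms, names))
  all_cp <- unlist(doms, use.names = FALSE)
  agg <- tapply(as.integer(all_cp), all_acc, sum)
  setNames(as.integer(agg), names(agg))
}

#' @export
print.bgc_record <- function(x, ...) {
  cat(sprintf("<bgc_record> %s [%s] %s:%s-%s  %d genes, %d domain types (%s)\n",
              x$bgc_id, x$bgc_class, x$genome_id,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              nrow(x$genes), length(x$domains), x$source))
  invisible(x)
}

#' Construct a genome record
#'
#' One replicon per genome: a single circular (or linear) chromosome with its
#' dnaA anchor, optional clade label, attached BGCs and optional conserved
#' (core-alignment) intervals whose complement is the hypervariable fraction
#' of the chromosome.
#'
#' @param genome_id Genome/strain identifier.
#' @param length Replicon length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @param dnaA_start 0-based coordinate of the dnaA gene start;
#'   `0 <= dnaA_start < length`.
#' @param dnaA_strand `"+"` or `"-"`.
#' @param clade Optional phylogenetic group label (e.g. `"A"` .. `"D"`,
#'   `"singleton"`); `NA` when unknown.
#' @param bgcs List of [bgc_record] objects on this replicon.
#' @param conserved_intervals Optional 2-column matrix (`start`, `end`;
#'   0-based half-open) of conserved regions; overlapping intervals are
#'   merged on construction.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, length, topology = "circular",
                          dnaA_start = 0, dnaA_strand = "+", clade = NA,
                          bgcs = list(), conserved_intervals = NULL) {
  stopifnot(is.character(genome_id), length > 0)
  if (!topology %in% c("circular", "linear"))
    stop("topology must be 'circular' or 'linear'")
  dnaA_start <- as.numeric(dnaA_start)
  if (!is.na(dnaA_start) && (dnaA_start < 0 || dnaA_start >= length))
    stop("genome '", genome_id, "': dnaA_start must lie in [0, length)")
  if (!dnaA_strand %in% c("+", "-")) stop("dnaA_strand must be '+' or '-'")
  if (!is.null(conserved_intervals)) {
    ci <- as.matrix(conserved_intervals)
    if (ncol(ci) != 2L) stop("conserved_intervals needs 2 columns")
    if (nrow(ci) && (any(ci[, 1] < 0) || any(ci[, 2] > length)))
      stop("genome '", genome_id, "': conserved interval outside [0, length)")
    conserved_intervals <- merge_intervals(ci)
  }
  structure(list(genome_id = genome_id, length = as.numeric(length),
                 topology = topology, dnaA_start = dnaA_start,
                 dnaA_strand = dnaA_strand, clade = clade, bgcs = bgcs,
                 conserved_intervals = conserved_intervals),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  %s bp (%s), dnaA %s%s, clade %s, %d BGCs\n",
              x$genome_id, format(x$length, big.mark = ",",
                                  scientific = FALSE),
              x$topology, format(x$dnaA_start, scientific = FALSE),
              x$dnaA_strand, ifelse(is.na(x$clade), "?", x$clade),
              length(x$bgcs)))
  invisible(x)
}

#' Merge overlapping or bookended intervals
#'
#' @param intervals 2-column numeric matrix of 0-based half-open intervals.
#' @return Sorted matrix of disjoint intervals covering the same positions.
#' @export
merge_intervals <- function(intervals) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) == 0L)
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  if (any(intervals[, 1] >= intervals[, 2]))
    stop("interval with start >= end")
  r <- IRanges::reduce(IRanges::IRanges(start = intervals[, 1] + 1,
                                        end = intervals[, 2]))
  cbind(start = IRanges::start(r) - 1, end = IRanges::end(r))
}

#' Attach BGC records to genome records by genome id
#'
#' @param genomes List of [genome_record].
#' @param bgcs List of [bgc_record].
#' @param strict Error when a BGC references an unknown genome (default TRUE).
#' @return The genome list with `bgcs` fields populated.
#' @export
attach_bgcs <- function(genomes, bgcs, strict = TRUE) {
  gid <- vapply(genomes, `[[`, "", "genome_id")
  names(genomes) <- gid
  for (b in bgcs) {
    if (!b$genome_id %in% gid) {
      if (strict) stop("BGC '", b$bgc_id, "' references unknown genome '",
                       b$genome_id, "'")
      next
    }
    genomes[[b$genome_id]]$bgcs <- c(genomes[[b$genome_id]]$bgcs, list(b))
  }
  genomes
}

#' Collect all BGCs from a list of genomes
#'
#' @param genomes List of [genome_record].
#' @return Flat list of [bgc_record], named by `bgc_id`.
#' @export
all_bgcs <- function(genomes) {
  out <- unlist(lapply(genomes, `[[`, "bgcs"), recursive = FALSE)
  if (is.null(out)) out <- list()
  names(out) <- vapply(out, `[[`, "", "bgc_id")
  out
}
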