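# BGC positions relative to the replication origin (oriC, anchored at the
# dnaA gene) on circular genomes, regional densities, positional
# conservation within clades, and overlap with hypervariable regions.

#' Relative position of a BGC downstream of oriC
#'
#' The circular chromosome is linearized with the dnaA gene as the start.
#' The BGC is represented by its interval midpoint (circular midpoint when
#' the cluster wraps the origin). For a dnaA gene on the plus strand the
#' position is `p = ((m - dnaA_start) mod L) / L`; when dnaA lies on the
#' minus strand the reverse-complement frame is used, i.e. coordinates are
#' mirrored: `p = ((dnaA_start - m) mod L) / L`.
#'
#' @param bgc A [bgc_record] (its `end` may exceed the genome length to
#'   denote a cluster wrapping the origin).
#' @param genome The [genome_record] carrying it. Linear genomes are
#'   accepted only with `dnaA_start` explicitly set (used as the origin).
#' @return Relative position `p` in \[0, 1).
#' @export
relative_position <- function(bgc, genome) {
  L <- genome$length
  if (is.na(genome$dnaA_start))
    stop("genome '", genome$genome_id, "' has no stated origin: set ",
         "dnaA_start explicitly to linearize",
         if (genome$topology == "linear") " (linear replicon)" else "")
  m <- circular_midpoint(bgc$start, bgc$end, L)
  p <- if (genome$dnaA_strand == "+") ((m - genome$dnaA_start) %% L) / L
       else ((genome$dnaA_start - m) %% L) / L
  # guard against p == 1 from floating-point roundoff
  if (p >= 1) p <- 0
  p
}

circular_midpoint <- function(start, end, L) {
  if (end <= start) stop("interval with end <= start")
  if (end - start > L) stop("interval longer than the genome")
  (start + (end - start) / 2) %% L
}

#' Relative positions for every BGC of a genome set
#'
#' @param genomes List of [genome_record].
#' @param partition Optional `gcf_partition` used to annotate family ids.
#' @return `data.frame` with `bgc_id`, `genome_id`, `bgc_class`, `clade`,
#'   `family_id` (NA without a partition), `p`.
#' @export
relative_positions <- function(genomes, partition = NULL) {
  rows <- list()
  for (g in genomes) for (b in g$bgcs) {
    rows[[length(rows) + 1L]] <- data.frame(
      bgc_id = b$bgc_id, genome_id = g$genome_id, bgc_class = b$bgc_class,
      clade = if (is.na(g$clade)) NA_character_ else g$clade,
      p = relative_position(b, g), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bgc_id = character(), genome_id = character(),
                      bgc_class = character(), clade = character(),
                      p = numeric())
  out$family_id <- if (!is.null(partition))
    partition$assignments$family_id[match(out$bgc_id,
                                          partition$assignments$bgc_id)]
  else NA_character_
  out
}

#' Regional BGC densities along the linearized genome
#'
#' Divides the \[0, 1) relative-coordinate axis into `n_bins` contiguous
#' equal regions and counts BGCs per region, in total and per product
#' class. A BGC at position p falls in region `floor(p * n_bins)`.
#'
#' @param positions `data.frame` from [relative_positions()] (or any frame
#'   with columns `p` and `bgc_class`).
#' @param n_bins Number of regions (default 8).
#' @return `data.frame` with `bin` (0-based), `bin_start`, `bin_end`,
#'   `total`, and one count column per class present.
#' @export
bin_densities <- function(positions, n_bins = 8L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  bin <- pmin(floor(positions$p * n_bins), n_bins - 1L)
  out <- data.frame(bin = 0:(n_bins - 1L))
  out$bin_start <- out$bin / n_bins
  out$bin_end <- (out$bin + 1) / n_bins
  out$total <- vapply(out$bin, function(b) sum(bin == b), 1L)
  for (cls in BGC_CLASSES) {
    sel <- positions$bgc_class == cls
    if (any(sel))
      out[[cls]] <- vapply(out$bin, function(b) sum(bin[sel] == b), 1L)
  }
  out
}

#' Circular distance between relative positions
#'
#' @param p1,p2 Positions in \[0, 1).
#' @return `min(|p1 - p2|, 1 - |p1 - p2|)`.
#' @export
circular_distance <- function(p1, p2) {
  d <- abs(p1 - p2)
  pmin(d, 1 - d)
}

#' Positional conservation of a family within a strain group
#'
#' A family is positionally conserved when the maximum pairwise circular
#' distance between its members' relative positions stays within
#' `tolerance` (a fraction of genome length).
#'
#' @param p Numeric vector of member relative positions (one strain group).
#' @param tolerance Maximum allowed spread (default 0.05).
#' @return `"conserved"`, `"variable"`, or `"not-applicable"` for fewer
#'   than two members.
#' @export
positional_conservation <- function(p, tolerance = 0.05) {
  if (length(p) < 2L) return("not-applicable")
  mx <- 0
  for (i in seq_len(length(p) - 1L))
    mx <- max(mx, circular_distance(p[i], p[(i + 1L):length(p)]))
  if (mx <= tolerance) "conserved" else "variable"
}

#' Positional conservation report per family and clade
#'
#' @param positions `data.frame` from [relative_positions()] with
#'   `family_id` and `clade` filled in.
#' @param tolerance Passed to [positional_conservation()].
#' @return `data.frame` with `family_id`, `clade`, `n_members`, `status`.
#' @export
conservation_report <- function(positions, tolerance = 0.05) {
  pos <- positions[!is.na(positions$family_id) & !is.na(positions$clade), ,
                   drop = FALSE]
  key <- interaction(pos$family_id, pos$clade, drop = TRUE)
  sp <- split(pos, key)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    family_id = d$family_id[1], clade = d$clade[1], n_members = nrow(d),
    status = positional_conservation(d$p, tolerance),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$family_id, out$clade), , drop = FALSE]
}

#' Fraction of a genome's BGCs lying in hypervariable regions
#'
#' A BGC is counted as hypervariable when more than half of its span lies
#' outside the genome's conserved (core-alignment) intervals. Clusters
#' wrapping the origin are split at the origin before the overlap
#' computation.
#'
#' @param genome A [genome_record] with `conserved_intervals` set.
#' @param min_outside_fraction Span fraction outside conserved intervals
#'   needed to call a BGC hypervariable (default 0.5, exclusive).
#' @return List with `n_bgcs`, `n_hypervariable`, `fraction`, and the
#'   per-BGC logical vector `hypervariable` (named by bgc id).
#' @export
hypervariable_fraction <- function(genome, min_outside_fraction = 0.5) {
  ci <- genome$conserved_intervals
  if (is.null(ci))
    stop("genome '", genome$genome_id, "' has no conserved intervals")
  L <- genome$length
  flags <- vapply(genome$bgcs, function(b) {
    pieces <- if (b$end <= L) cbind(b$start, b$end)
              else rbind(cbind(b$start, L), cbind(0, b$end - L))
    span <- sum(pieces[, 2] - pieces[, 1])
    inside <- 0
    for (r in seq_len(nrow(pieces))) for (k in seq_len(nrow(ci)))
      inside <- inside + max(0, min(pieces[r, 2], ci[k, 2]) -
                                  max(pieces[r, 1], ci[k, 1]))
    (span - inside) / span > min_outside_fraction
  }, TRUE)
  names(flags) <- vapply(genome$bgcs, `[[`, "", "bgc_id")
  list(n_bgcs = length(flags), n_hypervariable = sum(flags),
       fraction = if (length(flags)) mean(flags) else 0,
       hypervariable = flags)
}
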