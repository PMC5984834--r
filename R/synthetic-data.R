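# Synthetic genomes with planted gene-cluster-family structure.
#
# The generator emulates a genus-scale comparative dataset: a fixed number
# of phylogenetic clades plus outlier strains; family tiers (core families
# in every strain, clade families vertical within one clade, rare families
# in 2-3 strains, unique families in a single strain); within-family
# sequence divergence that keeps true pairs above the 50%/80% criteria
# thresholds while unrelated clusters stay far below them; and an
# HGT-acquired fraction concentrated in a variable region of the chromosome
# opposite the dnaA-anchored replication origin. Ground-truth labels for
# every planted feature are emitted alongside the genomes.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","V","Y")

ROLE_VOCAB <- sprintf("enzyme-%03d", 1:150)

#' Simulation parameters for the synthetic dataset
#'
#' Defaults describe the study conditions the generator emulates: 4 clades
#' of 5 strains plus 2 outliers; 5 core families, 8 clade families per
#' clade, 10 rare families and on average 6 unique families per strain
#' (about two thirds of all families end up unique — the hallmark of
#' strain-specific diversification); a 300-type Pfam alphabet with 5%
#' domain gain/loss and 10% copy jitter per instantiation; 0.15
#' substitutions/site within-family protein divergence; and a variable
#' (non-core) region spanning relative positions 0.3-0.7, opposite oriC,
#' where HGT-derived (rare/unique) clusters land.
#'
#' @param n_clades Number of phylogenetic clades.
#' @param strains_per_clade Strains per clade.
#' @param n_outlier_strains Strains outside any clade (label `"singleton"`).
#' @param genome_length Chromosome length in bp.
#' @param n_core_gcfs Families planted in every strain.
#' @param n_clade_gcfs_per_clade Families vertical within each clade.
#' @param n_rare_gcfs Families planted in 2-3 random strains.
#' @param mean_unique_per_strain Poisson mean of unique families per strain.
#' @param domain_alphabet_size Number of distinct Pfam-like accessions.
#' @param domain_gain_loss_prob Per domain type per instantiation.
#' @param copy_jitter_prob Probability a retained domain's copy number
#'   moves by one.
#' @param within_gcf_protein_divergence Substitutions/site applied to each
#'   instance relative to the family's seed proteins.
#' @param module_gene_conservation Divergence multiplier for genes carrying
#'   KS/C module domains (assembly-line domains are strongly conserved, and
#'   module-position identity is itself a family criterion).
#' @param between_gcf_identity_ceiling Documented ceiling on cross-family
#'   identity; independent random seed proteins stay below it.
#' @param variable_region Relative-position interval (fractions of genome
#'   length downstream of oriC) receiving HGT-derived clusters.
#' @param core_region_positions Optional fixed relative positions for the
#'   core families; default: evenly spaced outside the variable region.
#' @param position_noise Positional noise (fraction of genome length) on
#'   conserved-position families.
#' @param genes_per_cluster_range,protein_length_range Cluster gene counts
#'   and protein lengths (aa) drawn uniformly from these ranges.
#' @param gene_shuffle_prob Probability that an instance swaps one adjacent
#'   non-module gene pair (family criteria are order-insensitive).
#' @param seed Integer RNG seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_clades = 4L, strains_per_clade = 5L,
                              n_outlier_strains = 2L,
                              genome_length = 1e6,
                              n_core_gcfs = 5L,
                              n_clade_gcfs_per_clade = 8L,
                              n_rare_gcfs = 10L,
                              mean_unique_per_strain = 6,
                              domain_alphabet_size = 300L,
                              domain_gain_loss_prob = 0.05,
                              copy_jitter_prob = 0.1,
                              within_gcf_protein_divergence = 0.15,
                              module_gene_conservation = 0.25,
                              between_gcf_identity_ceiling = 0.3,
                              variable_region = c(0.3, 0.7),
                              core_region_positions = NULL,
                              position_noise = 0.02,
                              genes_per_cluster_range = c(4L, 7L),
                              protein_length_range = c(120L, 200L),
                              gene_shuffle_prob = 0.3,
                              seed = 42L) {
  p <- as.list(environment())
  probs <- c(p$domain_gain_loss_prob, p$copy_jitter_prob,
             p$gene_shuffle_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (p$variable_region[1] < 0 || p$variable_region[2] > 1 ||
      p$variable_region[1] >= p$variable_region[2])
    stop("variable_region must be an increasing interval within [0,1)")
  structure(p, class = "simulation_params")
}

# Domain alphabet, excluding the accessions reserved for KS/C domains.
domain_alphabet <- function(params) {
  acc <- sprintf("PF%05d", seq_len(params$domain_alphabet_size))
  setdiff(acc, c("PF00109", "PF00668"))
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

#' Mutate a protein under a uniform substitution model
#'
#' Each site substitutes independently with probability `1 - exp(-d)` (d in
#' substitutions/site) to one of the 19 other residues, so the expected
#' per-site identity to the input is `exp(-d)`; no indels.
#'
#' @param protein Amino-acid sequence.
#' @param divergence Substitutions per site.
#' @return Mutated sequence.
#' @export
mutate_protein <- function(protein, divergence) {
  if (divergence <= 0) return(protein)
  chars <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(chars)) < (1 - exp(-divergence)))
  if (length(hit)) {
    # uniform over the 19 residues other than the current one
    shift <- sample.int(19L, length(hit), replace = TRUE)
    chars[hit] <- AA20[(match(chars[hit], AA20) + shift - 1L) %% 20L + 1L]
  }
  paste(chars, collapse = "")
}

# An archetype is the family's ancestral cluster: per-gene roles, domain
# multisets, module annotations, and seed proteins.
make_archetype <- function(gcf_id, bgc_class, params) {
  n_genes <- sample(seq(params$genes_per_cluster_range[1],
                        params$genes_per_cluster_range[2]), 1L)
  modular <- bgc_class %in% MODULAR_CLASSES
  n_mod <- if (modular) min(sample(2:3, 1L), n_genes - 1L) else 0L
  kinds <- if (!modular) character() else switch(
    bgc_class,
    "PKS" = rep("KS", n_mod),
    "NRPS" = rep("C", n_mod),
    "PKS/NRPS-hybrid" = rep(c("KS", "C"), length.out = n_mod))
  alphabet <- domain_alphabet(params)
  genes <- vector("list", n_genes)
  kind_counter <- c(KS = 0L, C = 0L)
  for (i in seq_len(n_genes)) {
    len <- sample(seq(params$protein_length_range[1],
                      params$protein_length_range[2]), 1L)
    if (i <= n_mod) {
      kind <- kinds[i]
      kind_counter[kind] <- kind_counter[kind] + 1L
      anchor <- if (kind == "KS") "PF00109" else "PF00668"
      dom <- setNames(c(1L, sample(1:2, 1L)),
                      c(anchor, sample(alphabet, 1L)))
      genes[[i]] <- list(role = paste0(kind, "-module"),
                         domains = dom,
                         modules = data.frame(kind = kind,
                                              index = kind_counter[[kind]]),
                         protein = random_protein(len),
                         conservation = params$module_gene_conservation)
    } else {
      dom_acc <- sample(alphabet, sample(1:2, 1L))
      genes[[i]] <- list(role = sample(ROLE_VOCAB, 1L),
                         domains = setNames(sample(1:3, length(dom_acc),
                                                   TRUE), dom_acc),
                         modules = NULL,
                         protein = random_protein(len),
                         conservation = 1)
    }
  }
  # avoid duplicated non-module roles within one archetype
  roles <- vapply(genes, `[[`, "", "role")
  for (i in which(duplicated(roles) & !grepl("-module$", roles))) {
    genes[[i]]$role <- sample(setdiff(ROLE_VOCAB, roles), 1L)
    roles[i] <- genes[[i]]$role
  }
  list(gcf_id = gcf_id, bgc_class = bgc_class, genes = genes)
}

#' Instantiate one BGC from a family archetype
#'
#' Models within-family variation: each gene's domain types are lost (or a
#' new type gained) with `domain_gain_loss_prob`, retained copy numbers
#' jitter by one with `copy_jitter_prob`, proteins are mutated at
#' `within_gcf_protein_divergence` substitutions/site (scaled down by the
#' gene's conservation factor for KS/C module genes), and with
#' `gene_shuffle_prob` one adjacent non-module gene pair is swapped —
#' family membership criteria are insensitive to gene order.
#'
#' @param archetype Internal archetype object (>= 3 genes with roles,
#'   domains and seed proteins).
#' @param params A [simulation_params()] list.
#' @param bgc_id,genome_id Identifiers for the new record.
#' @param start,end Cluster interval on the genome (`end` may exceed the
#'   genome length when the cluster wraps the origin).
#' @param divergence Override for the protein divergence (defaults to
#'   `params$within_gcf_protein_divergence`).
#' @return A [bgc_record].
#' @export
instantiate_cluster <- function(archetype, params, bgc_id, genome_id,
                                start = 0, end = NULL,
                                divergence = params$within_gcf_protein_divergence) {
  if (length(archetype$genes) < 3L)
    stop("archetype needs at least 3 genes")
  alphabet <- domain_alphabet(params)
  genes <- archetype$genes
  # local shuffle: swap one adjacent non-module pair
  n <- length(genes)
  non_mod <- which(vapply(genes, function(g) is.null(g$modules), TRUE))
  if (length(non_mod) >= 2L && runif(1) < params$gene_shuffle_prob) {
    adj <- non_mod[which(diff(non_mod) == 1L)]
    if (length(adj)) {
      i <- sample(adj, 1L)
      genes[c(i, i + 1L)] <- genes[c(i + 1L, i)]
    }
  }
  inst <- lapply(genes, function(g) {
    dom <- g$domains
    keep <- runif(length(dom)) >= params$domain_gain_loss_prob
    dom <- dom[keep]
    n_gain <- rbinom(1L, length(g$domains), params$domain_gain_loss_prob)
    if (n_gain > 0L) {
      new_acc <- sample(setdiff(alphabet, names(dom)), n_gain)
      dom <- c(dom, setNames(sample(1:2, n_gain, TRUE), new_acc))
    }
    if (length(dom)) {
      jit <- runif(length(dom)) < params$copy_jitter_prob
      dom[jit] <- pmax(1L, dom[jit] + sample(c(-1L, 1L), sum(jit), TRUE))
    }
    g$domains <- dom
    g$protein <- mutate_protein(g$protein, divergence * g$conservation)
    g
  })
  gene_bp <- vapply(inst, function(g) nchar(g$protein) * 3 + 3, 0)
  gap <- 50
  offsets <- cumsum(c(100, head(gene_bp + gap, -1)))
  span <- offsets[length(offsets)] + gene_bp[length(gene_bp)] + 100
  if (is.null(end)) end <- start + span
  scale <- (end - start) / span
  gt <- data.frame(
    gene_id = sprintf("%s_g%02d", bgc_id, seq_along(inst)),
    start = floor(start + offsets * scale),
    end = floor(start + (offsets + gene_bp) * scale),
    strand = "+",
    role = vapply(inst, `[[`, "", "role"),
    protein = vapply(inst, `[[`, "", "protein"),
    stringsAsFactors = FALSE)
  gt$modules <- I(lapply(inst, `[[`, "modules"))
  gt$domains <- I(lapply(inst, function(g)
    if (length(g$domains)) g$domains else NULL))
  bgc_record(bgc_id = bgc_id, genome_id = genome_id,
             bgc_class = archetype$bgc_class, start = start, end = end,
             genes = gt, source = "own")
}

# bp span an instance of this archetype will occupy
archetype_span <- function(archetype) {
  gene_bp <- vapply(archetype$genes, function(g) nchar(g$protein) * 3 + 3, 0)
  sum(gene_bp) + 50 * (length(gene_bp) - 1) + 200
}

# map a relative (oriC-downstream) position to the absolute midpoint
absolute_midpoint <- function(p, dnaA_start, dnaA_strand, L) {
  if (dnaA_strand == "+") (dnaA_start + p * L) %% L
  else (dnaA_start - p * L) %% L
}

# map a relative interval [a, b) to absolute intervals (possibly split at
# the origin), honoring the dnaA strand mirroring
relative_interval_to_absolute <- function(a, b, dnaA_start, dnaA_strand, L) {
  if (dnaA_strand == "+") {
    s <- (dnaA_start + a * L) %% L; e <- (dnaA_start + b * L) %% L
  } else {
    s <- (dnaA_start - b * L) %% L; e <- (dnaA_start - a * L) %% L
  }
  if (abs(e - s) < 1e-9 && b - a >= 1 - 1e-9) return(cbind(0, L))
  if (s < e) cbind(s, e) else rbind(cbind(s, L), cbind(0, e))
}

#' Generate a synthetic genome set with planted family structure
#'
#' @param params A [simulation_params()] list.
#' @return List with `genomes` (list of [genome_record]) and `truth`
#'   (class `synthetic_truth`): `bgc_truth` (data.frame `bgc_id`,
#'   `genome_id`, `gcf`, `tier`, `positional_class`, `p_planted`),
#'   `gcf_tiers` (`gcf`, `tier`), `clades` (`genome_id`, `clade`), and
#'   `clade_tree` (Newick string; clades as polytomous cherries).
#' @export
generate_dataset <- function(params = simulation_params()) {
  with_rng_seed(params$seed, generate_dataset_impl(params))
}

generate_dataset_impl <- function(params) {
  L <- params$genome_length
  vr <- params$variable_region
  n_strains <- params$n_clades * params$strains_per_clade +
    params$n_outlier_strains
  genome_ids <- sprintf("G%02d", seq_len(n_strains))
  clades <- c(rep(LETTERS[seq_len(params$n_clades)],
                  each = params$strains_per_clade),
              rep("singleton", params$n_outlier_strains))

  # conserved-position slots: evenly spaced in the complement of the
  # variable region, with margin so positional noise cannot leak in
  margin <- 2 * params$position_noise
  n_vertical <- params$n_core_gcfs +
    params$n_clades * params$n_clade_gcfs_per_clade
  slots <- conserved_slots(n_vertical, vr, margin)
  core_pos <- if (!is.null(params$core_region_positions))
    params$core_region_positions else slots[seq_len(params$n_core_gcfs)]
  if (length(core_pos) != params$n_core_gcfs)
    stop("core_region_positions must have length n_core_gcfs")
  clade_pos <- slots[params$n_core_gcfs + seq_len(n_vertical - params$n_core_gcfs)]

  classes <- BGC_CLASSES
  new_arch <- function(id) {
    make_archetype(id, sample(classes, 1L), params)
  }
  core_arch <- lapply(seq_len(params$n_core_gcfs),
                      function(i) new_arch(sprintf("core%02d", i)))
  clade_arch <- list(); clade_arch_clade <- character()
  k <- 0L
  for (cl in LETTERS[seq_len(params$n_clades)])
    for (i in seq_len(params$n_clade_gcfs_per_clade)) {
      k <- k + 1L
      clade_arch[[k]] <- new_arch(sprintf("clade%s%02d", cl, i))
      clade_arch_clade[k] <- cl
    }
  rare_arch <- lapply(seq_len(params$n_rare_gcfs),
                      function(i) new_arch(sprintf("rare%02d", i)))
  rare_members <- lapply(rare_arch, function(a)
    sample(genome_ids, sample(2:3, 1L)))

  truth_rows <- list()
  genomes <- vector("list", n_strains)

  for (gi in seq_len(n_strains)) {
    gid <- genome_ids[gi]
    clade <- clades[gi]
    dnaA_start <- floor(runif(1) * L)
    dnaA_strand <- sample(c("+", "-"), 1L)

    plan <- list()  # (archetype, gcf, tier, p, positional_class)
    for (i in seq_along(core_arch))
      plan[[length(plan) + 1L]] <- list(arch = core_arch[[i]],
        tier = "core", p = core_pos[i] + runif(1, -1, 1) * params$position_noise,
        pclass = "conserved-position")
    if (clade != "singleton") {
      for (i in which(clade_arch_clade == clade))
        plan[[length(plan) + 1L]] <- list(arch = clade_arch[[i]],
          tier = "clade",
          p = clade_pos[i] + runif(1, -1, 1) * params$position_noise,
          pclass = "conserved-position")
    }
    for (i in seq_along(rare_arch))
      if (gid %in% rare_members[[i]])
        plan[[length(plan) + 1L]] <- list(arch = rare_arch[[i]],
          tier = "rare", p = runif(1, vr[1], vr[2]),
          pclass = "variable-region")
    n_unique <- rpois(1L, params$mean_unique_per_strain)
    for (i in seq_len(n_unique))
      plan[[length(plan) + 1L]] <- list(
        arch = new_arch(sprintf("uniq.%s.%02d", gid, i)),
        tier = "unique", p = runif(1, vr[1], vr[2]),
        pclass = "variable-region")

    total_bp <- sum(vapply(plan, function(x) archetype_span(x$arch), 0))
    if (total_bp > 0.9 * L)
      stop("infeasible layout: planted clusters need ", total_bp,
           " bp on a ", L, " bp genome")

    bgcs <- vector("list", length(plan))
    for (bi in seq_along(plan)) {
      x <- plan[[bi]]
      p <- x$p %% 1
      span <- archetype_span(x$arch)
      m <- absolute_midpoint(p, dnaA_start, dnaA_strand, L)
      start <- (m - span / 2) %% L
      bgc_id <- sprintf("%s.%s", gid, x$arch$gcf_id)
      bgcs[[bi]] <- instantiate_cluster(x$arch, params, bgc_id, gid,
                                        start = start, end = start + span)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        bgc_id = bgc_id, genome_id = gid, gcf = x$arch$gcf_id,
        tier = x$tier, positional_class = x$pclass, p_planted = p,
        stringsAsFactors = FALSE)
    }
    conserved <- rbind(
      relative_interval_to_absolute(0, vr[1], dnaA_start, dnaA_strand, L),
      relative_interval_to_absolute(vr[2], 1, dnaA_start, dnaA_strand, L))
    genomes[[gi]] <- genome_record(
      genome_id = gid, length = L, topology = "circular",
      dnaA_start = dnaA_start, dnaA_strand = dnaA_strand, clade = clade,
      bgcs = bgcs, conserved_intervals = conserved)
  }
  names(genomes) <- genome_ids

  bgc_truth <- do.call(rbind, truth_rows)
  gcf_tiers <- unique(bgc_truth[, c("gcf", "tier")])
  rownames(gcf_tiers) <- NULL
  cherries <- vapply(LETTERS[seq_len(params$n_clades)], function(cl)
    paste0("(", paste(genome_ids[clades == cl], collapse = ","), ")", cl),
    "")
  tips <- c(cherries, genome_ids[clades == "singleton"])
  truth <- structure(list(
    bgc_truth = bgc_truth, gcf_tiers = gcf_tiers,
    clades = data.frame(genome_id = genome_ids, clade = clades,
                        stringsAsFactors = FALSE),
    clade_tree = paste0("(", paste(tips, collapse = ","), ");")),
    class = "synthetic_truth")
  list(genomes = genomes, truth = truth)
}

# evenly spaced positions in [0, vr1) U [vr2, 1), margin away from the
# variable region boundaries
conserved_slots <- function(n, vr, margin) {
  left <- c(0, max(vr[1] - margin, 0))
  right <- c(min(vr[2] + margin, 1), 1)
  wl <- left[2] - left[1]; wr <- right[2] - right[1]
  if (wl + wr <= 0) stop("variable region leaves no conserved positions")
  nl <- round(n * wl / (wl + wr)); nr <- n - nl
  pos <- c(if (nl > 0) left[1] + (seq_len(nl) - 0.5) / nl * wl,
           if (nr > 0) right[1] + (seq_len(nr) - 0.5) / nr * wr)
  pos[seq_len(n)]
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d BGCs, %d families (%s), %d strains\n",
              nrow(x$bgc_truth), nrow(x$gcf_tiers),
              paste(sprintf("%s: %d", names(table(x$gcf_tiers$tier)),
                            table(x$gcf_tiers$tier)), collapse = ", "),
              nrow(x$clades)))
  invisible(x)
}

# evaluate `expr` under a reproducible RNG state, restoring the caller's
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a synthetic dataset to the pipeline's exchange formats
#'
#' Emits the BGC table (TSV, one row per gene), the protein FASTA, the
#' genome metadata table, conserved regions as BED (first column genome
#' id), the ground-truth tables, and the parameters as YAML.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param params The [simulation_params()] used (echoed to `params.yaml`).
#' @return Invisibly, the named vector of files written.
#' @export
write_dataset <- function(dataset, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bgc_table = file.path(dir, "bgcs.tsv"),
             proteins = file.path(dir, "proteins.faa"),
             genome_table = file.path(dir, "genomes.tsv"),
             regions = file.path(dir, "conserved_regions.bed"),
             truth = file.path(dir, "truth_bgcs.tsv"),
             clade_tree = file.path(dir, "clade_tree.nwk"),
             params = file.path(dir, "params.yaml"))
  rows <- list(); prots <- character()
  for (g in dataset$genomes) for (b in g$bgcs) {
    gt <- b$genes
    pid <- paste(b$bgc_id, gt$gene_id, sep = "|")
    prots[pid] <- gt$protein
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = b$genome_id, bgc_id = b$bgc_id, bgc_class = b$bgc_class,
      bgc_start = b$start, bgc_end = b$end,
      gene_id = gt$gene_id, gene_start = gt$start, gene_end = gt$end,
      strand = gt$strand, role = gt$role,
      domains = vapply(gt$domains, format_domain_tokens, ""),
      module_domains = vapply(gt$modules, format_module_tokens, ""),
      protein_id = pid, stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, rows), paths["bgc_table"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_protein_fasta(prots, paths["proteins"])
  gt <- do.call(rbind, lapply(dataset$genomes, function(g) data.frame(
    genome_id = g$genome_id, length = g$length, topology = g$topology,
    dnaA_start = g$dnaA_start, dnaA_strand = g$dnaA_strand,
    clade = g$clade, stringsAsFactors = FALSE)))
  write.table(gt, paths["genome_table"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- do.call(rbind, lapply(dataset$genomes, function(g) {
    ci <- g$conserved_intervals
    if (is.null(ci) || nrow(ci) == 0L) return(NULL)
    data.frame(chrom = g$genome_id, start = round(ci[, 1]),
               end = round(ci[, 2]))
  }))
  writeLines(if (is.null(bed)) character()
             else sprintf("%s\t%d\t%d", bed$chrom, as.integer(bed$start),
                          as.integer(bed$end)), paths["regions"])
  write.table(dataset$truth$bgc_truth, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$truth$clade_tree, paths["clade_tree"])
  if (!is.null(params))
    yaml::write_yaml(unclass(params), paths["params"])
  invisible(paths)
}

format_domain_tokens <- function(d) {
  if (is.null(d) || !length(d)) return("")
  paste(sprintf("%s:%d", names(d), as.integer(d)), collapse = ";")
}

format_module_tokens <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(sprintf("%s:%d", m$kind, m$index), collapse = ";")
}
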