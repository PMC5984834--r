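# End-to-end orchestration: load (or simulate) -> similarity network ->
# family assignment -> frequency categories -> presence/absence profiling
# (Dice/UPGMA) -> rarefaction -> oriC-relative locations and densities ->
# optional POCP. Every stage writes its documented exchange format; a JSON
# manifest records checksums so reruns are verifiable byte-for-byte.

#' Assemble a pipeline configuration
#'
#' Either point `bgc_table`/`genome_table`/`proteins` at existing inputs, or
#' leave them `NULL` and set `simulate = TRUE` to run on a generated
#' dataset.
#'
#' @param output_dir Directory receiving all stage outputs.
#' @param bgc_table,genome_table,proteins,regions,reference_bgc_table Input
#'   paths (TSV / TSV / FASTA / BED / TSV); any may be `NULL`.
#' @param hit_tables Optional named list of POCP hit-table paths
#'   (`a_vs_b`, `b_vs_a`) plus proteome sizes (`t_a`, `t_b`).
#' @param simulate Generate the inputs with [generate_dataset()].
#' @param sim_params [simulation_params()] for simulation mode.
#' @param similarity [similarity_params()].
#' @param gcf [gcf_params()].
#' @param pocp [pocp_params()].
#' @param n_bins Number of genome regions for density profiles.
#' @param conservation_tolerance Positional-conservation tolerance.
#' @param rarefaction_method `"exact"` or `"montecarlo"`.
#' @param exclude_bgcs BGC ids dropped before any analysis (e.g. clusters
#'   reclassified as primary metabolism such as the ubiquitous ectoine
#'   cluster).
#' @param run_pocp Compute the POCP matrix from per-genome BGC proteins
#'   (desk-scale only) or supplied hit tables.
#' @param seed Integer seed recorded in the outputs and used for every
#'   stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            bgc_table = NULL, genome_table = NULL,
                            proteins = NULL, regions = NULL,
                            reference_bgc_table = NULL, hit_tables = NULL,
                            simulate = is.null(bgc_table),
                            sim_params = simulation_params(seed = seed),
                            similarity = similarity_params(),
                            gcf = gcf_params(),
                            pocp = pocp_params(),
                            n_bins = 8L, conservation_tolerance = 0.05,
                            rarefaction_method = "exact",
                            exclude_bgcs = character(),
                            run_pocp = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!simulate) {
    for (field in c("bgc_table", "genome_table")) {
      if (is.null(cfg[[field]]))
        stop("config field '", field, "' is required when simulate = FALSE")
      if (!file.exists(cfg[[field]]))
        stop("config field '", field, "': file not found: ", cfg[[field]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; nested parameter
#' blocks (`similarity`, `gcf`, `pocp`, `sim_params`) override individual
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("similarity", "gcf", "pocp", "sim_params"))]
  if (!is.null(y$similarity))
    args$similarity <- do.call(similarity_params, y$similarity)
  if (!is.null(y$gcf)) args$gcf <- do.call(gcf_params, y$gcf)
  if (!is.null(y$pocp)) args$pocp <- do.call(pocp_params, y$pocp)
  if (!is.null(y$sim_params))
    args$sim_params <- do.call(simulation_params, y$sim_params)
  do.call(pipeline_config, args)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full comparative pipeline
#'
#' Executes every stage on the configured inputs and writes: the similarity
#' network (GraphML + edge list + component table), the family table with
#' frequency categories, the presence/absence matrix, the Dice/UPGMA strain
#' dendrogram (Newick), rarefaction tables per clade, oriC-relative
#' positions, regional densities, per-family positional-conservation calls,
#' hypervariable-overlap fractions, optionally a POCP matrix, a summary TSV
#' and a JSON manifest with MD5 checksums of every output. Identical
#' config + seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, a list with the main in-memory results (`genomes`,
#'   `network`, `partition`, `matrix`, `tree`, `rarefaction`, `positions`,
#'   `densities`, `summary`, `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  files <- character()

  # --- load or simulate -----------------------------------------------
  truth <- NULL
  if (config$simulate) {
    pipeline_log("simulate", "generating synthetic dataset (seed %d)",
                 config$sim_params$seed)
    ds <- generate_dataset(config$sim_params)
    genomes <- ds$genomes
    truth <- ds$truth
    write_dataset(ds, file.path(config$output_dir, "simulated"),
                  params = config$sim_params)
  } else {
    pipeline_log("load", "reading %s", config$bgc_table)
    prot <- if (!is.null(config$proteins))
      read_protein_fasta(config$proteins) else NULL
    bgcs <- read_bgc_table(config$bgc_table, "own", proteins = prot)
    genomes <- read_genome_table(config$genome_table)
    genomes <- attach_bgcs(genomes, bgcs)
    if (!is.null(config$regions)) {
      for (gid in names(genomes)) {
        ci <- read_regions_bed(config$regions, seqname = gid)
        if (nrow(ci)) genomes[[gid]]$conserved_intervals <- ci
      }
    }
  }
  if (length(config$exclude_bgcs)) {
    for (gid in names(genomes)) {
      keep <- !vapply(genomes[[gid]]$bgcs, `[[`, "", "bgc_id") %in%
        config$exclude_bgcs
      genomes[[gid]]$bgcs <- genomes[[gid]]$bgcs[keep]
    }
  }
  own <- all_bgcs(genomes)
  pipeline_log("load", "%d genomes, %d BGCs", length(genomes), length(own))
  if (!length(own)) stop("stage 'load': no BGCs to analyse")

  # --- similarity network ---------------------------------------------
  nodes <- own
  if (!is.null(config$reference_bgc_table)) {
    ref <- read_bgc_table(config$reference_bgc_table, "reference")
    nodes <- c(own, ref)
  }
  network <- build_network(nodes, config$similarity)
  pipeline_log("network", "%d components, %d singletons",
               network$n_components, network$n_singletons)
  write_network(network, out("network.graphml"), out("network_edges.tsv"))
  comp_tab <- data.frame(bgc_id = names(network$components),
                         component = as.integer(network$components))
  write.table(comp_tab, out("network_components.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, "network.graphml", "network_edges.tsv",
             "network_components.tsv")
  ref_counts <- if (!is.null(config$reference_bgc_table))
    partition_vs_reference(network) else NULL

  # --- family assignment and categories -------------------------------
  partition <- assign_gcfs(own, config$gcf, sim_params = config$similarity)
  partition <- categorize_gcfs(partition)
  pipeline_log("gcf", "%d families (%s)", nrow(partition$families),
               paste(sprintf("%s %d", partition$frequency$category,
                             partition$frequency$n_families),
                     collapse = ", "))
  fam_tab <- merge(partition$assignments,
                   partition$families[, c("family_id", "category",
                                          "n_strains")],
                   by = "family_id", sort = TRUE)
  fam_tab <- fam_tab[order(fam_tab$bgc_id),
                     c("bgc_id", "family_id", "category", "n_strains")]
  write.table(fam_tab, out("gcf_families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, "gcf_families.tsv")

  # --- presence/absence, UPGMA, rarefaction ---------------------------
  mat <- presence_absence(partition)
  write_matrix_tsv(mat, out("presence_absence.tsv"))
  dmat <- dice_distance_matrix(mat)
  tree <- upgma_tree(dmat)
  write_tree_newick(tree, out("strain_dendrogram.nwk"))
  clades <- setNames(vapply(genomes, function(g)
    ifelse(is.na(g$clade), "unassigned", g$clade), ""), names(genomes))
  rar <- rarefaction_by_group(mat, clades,
                              method = config$rarefaction_method)
  write.table(rar, out("rarefaction.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, "presence_absence.tsv", "strain_dendrogram.nwk",
             "rarefaction.tsv")

  # --- locations, densities, conservation, hypervariable overlap ------
  pos <- relative_positions(genomes, partition)
  pos$bin <- pmin(floor(pos$p * config$n_bins), config$n_bins - 1L)
  pos$hypervariable <- NA
  dens <- bin_densities(pos, config$n_bins)
  cons <- conservation_report(pos, config$conservation_tolerance)
  hv <- lapply(genomes, function(g) {
    if (is.null(g$conserved_intervals)) return(NULL)
    r <- hypervariable_fraction(g)
    pos$hypervariable[match(names(r$hypervariable), pos$bgc_id)] <<-
      r$hypervariable
    data.frame(genome_id = g$genome_id, n_bgcs = r$n_bgcs,
               n_hypervariable = r$n_hypervariable, fraction = r$fraction)
  })
  hv <- do.call(rbind, hv)
  write.table(pos, out("bgc_positions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dens, out("bgc_densities.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cons, out("positional_conservation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, "bgc_positions.tsv", "bgc_densities.tsv",
             "positional_conservation.tsv")
  if (!is.null(hv)) {
    write.table(hv, out("hypervariable_overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, "hypervariable_overlap.tsv")
  }

  # --- optional POCP ---------------------------------------------------
  pocp_mat <- NULL
  if (isTRUE(config$run_pocp)) {
    if (!is.null(config$hit_tables)) {
      ht <- config$hit_tables
      res <- pocp(read_hit_table(ht$a_vs_b), read_hit_table(ht$b_vs_a),
                  ht$t_a, ht$t_b, config$pocp)
      pocp_mat <- matrix(c(100, res$pocp, res$pocp, 100), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B")))
    } else {
      proteomes <- lapply(genomes, function(g) {
        p <- unlist(lapply(g$bgcs, function(b)
          setNames(b$genes$protein, paste(b$bgc_id, b$genes$gene_id,
                                          sep = "|"))))
        p[!is.na(p)]
      })
      pocp_mat <- pocp_matrix(proteomes, config$pocp)
    }
    write_matrix_tsv(pocp_mat, out("pocp_matrix.tsv"))
    files <- c(files, "pocp_matrix.tsv")
  }

  # --- summary + manifest ---------------------------------------------
  freq <- partition$frequency
  summary <- data.frame(
    key = c("seed", "n_genomes", "n_bgcs", "n_families",
            "common_families", "rare_families", "unique_families",
            "unique_fraction", "network_components", "network_singletons",
            if (!is.null(ref_counts)) c("components_own_only",
                                        "components_reference_only",
                                        "components_mixed",
                                        "own_only_singletons")),
    value = c(config$seed, length(genomes), length(own),
              nrow(partition$families),
              freq$n_families[freq$category == "common"],
              freq$n_families[freq$category == "rare"],
              freq$n_families[freq$category == "unique"],
              round(freq$fraction[freq$category == "unique"], 6),
              network$n_components, network$n_singletons,
              if (!is.null(ref_counts)) c(ref_counts$own_only,
                                          ref_counts$reference_only,
                                          ref_counts$mixed,
                                          ref_counts$own_only_singletons)))
  write.table(summary, out("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, "summary.tsv")

  manifest <- list(
    seed = config$seed,
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(genomes = genomes, truth = truth, network = network,
                 partition = partition, matrix = mat, tree = tree,
                 rarefaction = rar, positions = pos, densities = dens,
                 conservation = cons, hypervariable = hv,
                 pocp_matrix = pocp_mat, reference_counts = ref_counts,
                 summary = summary,
                 files = vapply(files, out, "")))
}
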