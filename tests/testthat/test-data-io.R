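# Data model invariants and the tabular exchange formats.

make_bgc_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste(c("genome_id", "bgc_id", "bgc_class", "bgc_start",
                    "bgc_end", "gene_id", "gene_start", "gene_end",
                    "strand", "role", "domains", "module_domains",
                    "protein_id"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("record constructors enforce their invariants", {
  expect_error(bgc_record("b1", "g1", "PKS", 100, 100), "start must be <")
  expect_error(bgc_record("b1", "g1", "polyketide", 0, 10), "unknown bgc_class")
  expect_error(bgc_record("b1", "g1", "PKS", 0, 10,
                          domains = c(PF00001 = 0L)), "copy numbers")
  genes <- data.frame(gene_id = "g", start = 5, end = 20, strand = "+",
                      role = "r", protein = NA, stringsAsFactors = FALSE)
  genes$modules <- I(list(data.frame(kind = "KS", index = c(2L, 1L))))
  expect_error(bgc_record("b1", "g1", "PKS", 0, 30, genes = genes),
               "strictly increasing")
  expect_error(genome_record("g", 1000, dnaA_start = 1000),
               "dnaA_start")
  expect_error(genome_record("g", 1000, dnaA_start = -1), "dnaA_start")
  g <- genome_record("g", 1000, dnaA_start = 0)
  expect_identical(g$clade, NA)
})

test_that("cluster-level and per-gene domain annotation must agree", {
  genes <- data.frame(gene_id = c("a", "b"), start = c(0, 50),
                      end = c(40, 90), strand = "+", role = c("r1", "r2"),
                      protein = NA, stringsAsFactors = FALSE)
  genes$domains <- I(list(c(PF00109 = 2L), c(PF00109 = 1L)))
  b <- bgc_record("b1", "g1", "PKS", 0, 100, genes = genes)
  expect_identical(b$domains, c(PF00109 = 3L))
  expect_error(bgc_record("b1", "g1", "PKS", 0, 100, genes = genes,
                          domains = c(PF00109 = 2L)), "inconsistent")
})

test_that("BGC table reader aggregates gene rows into one record", {
  path <- make_bgc_tsv(c(
    "g1\tb1\tPKS\t0\t5000\tga\t100\t1000\t+\tKS-module\tPF00109:2\tKS:1\tp1",
    "g1\tb1\tPKS\t0\t5000\tgb\t1200\t2000\t-\ttailoring\tPF00109:1;PF00550:1\t\tp2"))
  bgcs <- read_bgc_table(path, "own",
                         proteins = c(p1 = "MKLV", p2 = "MKIV"))
  expect_length(bgcs, 1L)
  b <- bgcs[["b1"]]
  expect_equal(nrow(b$genes), 2L)
  # copies summed across the two gene rows
  expect_equal(b$domains[["PF00109"]], 3L)
  expect_equal(b$domains[["PF00550"]], 1L)
  expect_equal(b$genes$protein, c("MKLV", "MKIV"))
  expect_equal(b$genes$modules[[1]],
               data.frame(kind = "KS", index = 1L))
})

test_that("BGC table reader rejects malformed rows and missing columns", {
  path <- make_bgc_tsv(
    "g1\tb1\tPKS\t0\t5000\tga\t1000\t100\t+\tKS-module\tPF00109:2\t\tp1")
  expect_error(read_bgc_table(path), "end <= start.*row 1")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tbgc_id", path2)
  expect_error(read_bgc_table(path2), "missing required column.*bgc_class")
})

test_that("genome table reader echoes fields and enforces bounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tlength\ttopology\tdnaA_start\tdnaA_strand\tclade",
               "g1\t1000\tcircular\t0\t+\tA"), path)
  g <- read_genome_table(path)[["g1"]]
  expect_equal(g$length, 1000)
  expect_equal(g$dnaA_start, 0)
  expect_equal(g$clade, "A")
  # dnaA_start == length violates the half-open convention
  writeLines(c("genome_id\tlength\ttopology\tdnaA_start\tdnaA_strand",
               "g1\t1000\tcircular\t1000\t+"), path)
  expect_error(read_genome_table(path), "dnaA_start")
  # clade column optional
  writeLines(c("genome_id\tlength\ttopology\tdnaA_start\tdnaA_strand",
               "g1\t1000\tcircular\t10\t+"), path)
  expect_true(is.na(read_genome_table(path)[["g1"]]$clade))
})

test_that("BED reader sorts, merges, and validates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t50\t200", "chr\t0\t100"), path)
  expect_equal(unname(read_regions_bed(path)), cbind(0, 200),
               ignore_attr = TRUE)
  writeLines(character(), path)
  expect_equal(nrow(read_regions_bed(path)), 0L)
  writeLines("chr\t200\t100", path)
  expect_error(read_regions_bed(path), "start >= end")
  writeLines("chr\t1.5\t100", path)
  expect_error(read_regions_bed(path), "non-integer")
})

test_that("network, tree and matrix writers round-trip", {
  bgcs <- list(domain_bgc("A", c(PF00001 = 1L, PF00002 = 1L)),
               domain_bgc("B", c(PF00001 = 1L, PF00002 = 1L)),
               domain_bgc("C", c(PF00099 = 2L)))
  net <- build_network(bgcs)
  gml <- withr::local_tempfile(fileext = ".graphml")
  edg <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, edg)
  back <- read_network(gml)
  expect_setequal(igraph::V(back$graph)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))
  expect_equal(back$n_components, net$n_components)
  el <- read.table(edg, header = TRUE, sep = "\t")
  expect_equal(nrow(el), igraph::ecount(net$graph))

  nwk <- withr::local_tempfile(fileext = ".nwk")
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,C:0.3);")
  write_tree_newick(tree, nwk)
  expect_equal(ape::write.tree(ape::read.tree(nwk)),
               "((A:0.1,B:0.1):0.2,C:0.3);")

  m <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L), 3, 4,
              dimnames = list(c("s1", "s2", "s3"), paste0("f", 1:4)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tsv)
  expect_identical(read_matrix_tsv(tsv), m)
  expect_equal(length(readLines(tsv)), 4L)  # header + 3 data rows
})

test_that("a generated dataset survives a full write/read round-trip", {
  params <- simulation_params(n_clades = 2, strains_per_clade = 2,
                              n_outlier_strains = 0, n_core_gcfs = 2,
                              n_clade_gcfs_per_clade = 2, n_rare_gcfs = 1,
                              mean_unique_per_strain = 1, seed = 11)
  ds <- generate_dataset(params)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, params)
  prot <- read_protein_fasta(paths[["proteins"]])
  bgcs <- read_bgc_table(paths[["bgc_table"]], "own", proteins = prot)
  genomes <- read_genome_table(paths[["genome_table"]])
  genomes <- attach_bgcs(genomes, bgcs)
  for (gid in names(genomes))
    genomes[[gid]]$conserved_intervals <-
      read_regions_bed(paths[["regions"]], seqname = gid)
  orig <- all_bgcs(ds$genomes)
  back <- all_bgcs(genomes)
  expect_setequal(names(back), names(orig))
  for (id in names(orig)) {
    expect_equal(back[[id]]$domains[sort(names(back[[id]]$domains))],
                 orig[[id]]$domains[sort(names(orig[[id]]$domains))])
    expect_equal(back[[id]]$genes$protein, orig[[id]]$genes$protein)
    expect_equal(back[[id]]$genes$role, orig[[id]]$genes$role)
    expect_equal(back[[id]]$start, orig[[id]]$start, tolerance = 1e-9)
  }
  for (gid in names(ds$genomes))
    expect_equal(unname(genomes[[gid]]$conserved_intervals),
                 unname(round(ds$genomes[[gid]]$conserved_intervals)))
})
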