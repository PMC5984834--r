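# The four family criteria, pairwise alignment, family grouping and
# frequency categories.

test_that("alignment identity and coverage behave on anchor cases", {
  s <- random_protein_seq(80)
  expect_equal(align_identity(s, s), c(identity = 1, coverage = 1))
  # one mismatch in four aligned columns, full span of the 4-mer
  r <- align_identity("MKLV", "MKIV")
  expect_equal(unname(r["identity"]), 0.75)
  expect_equal(unname(r["coverage"]), 1)
  expect_error(align_identity("", "MKIV"), "empty")
  # symmetric by construction
  a <- random_protein_seq(60); b <- random_protein_seq(90)
  expect_equal(align_identity(a, b), align_identity(b, a))
})

test_that("sequences with no positive-scoring alignment fail criterion III", {
  # poly-A vs poly-W: every substitution score negative, no local alignment
  a <- strrep("A", 50); w <- strrep("W", 50)
  r <- align_identity(a, w)
  expect_equal(unname(r["coverage"]), 0)
  expect_equal(unname(r["identity"]), 0)
  x <- gene_bgc("x", c("r1", "r2", "r3"), c(a, a, a))
  y <- gene_bgc("y", c("r1", "r2", "r3"), c(w, w, w))
  rep <- criteria_report(x, y)
  expect_true(rep$criterion_i)   # same class, same roles
  expect_true(rep$criterion_ii)
  expect_false(rep$criterion_iii)
  expect_false(rep$same_gcf)
})

test_that("criteria evaluate the documented truth table", {
  withr::local_seed(42)
  p <- replicate(3, random_protein_seq(120))
  ident <- gene_bgc("a", c("r1", "r2", "r3"), p)
  ident2 <- gene_bgc("b", c("r1", "r2", "r3"), p)
  rep <- criteria_report(ident, ident2)
  expect_true(rep$criterion_i && rep$criterion_ii && rep$criterion_iii)
  expect_true(rep$same_gcf)
  expect_true(is.na(rep$criterion_iv))  # non-modular class

  # two of three genes with qualifying hits -> criterion III majority holds
  q <- c(p[1], p[2], random_protein_seq(120))
  twothirds <- gene_bgc("c", c("r1", "r2", "r3"), q)
  rep2 <- criteria_report(ident, twothirds)
  expect_true(rep2$criterion_iii)

  # same domains but disjoint roles and a different class: I and II fail
  other <- gene_bgc("d", c("x1", "x2", "x3"), p, class = "RiPP")
  rep3 <- criteria_report(ident, other)
  expect_false(rep3$criterion_i)
  expect_false(rep3$criterion_ii)
  expect_false(rep3$same_gcf)
})

test_that("criterion IV compares module domains by position", {
  withr::local_seed(43)
  ks1 <- random_protein_seq(150); ks2 <- random_protein_seq(150)
  other <- replicate(2, random_protein_seq(100))
  mods <- function(idx) data.frame(kind = "KS", index = idx)
  mk <- function(id, ks_a, ks_b) {
    gene_bgc(id, c("KS-module", "KS-module", "r1", "r2"),
             c(ks_a, ks_b, other[1], other[2]), class = "PKS",
             modules = list(mods(1L), mods(2L), NULL, NULL))
  }
  a <- mk("a", ks1, ks2)
  b <- mk("b", ks1, ks2)
  expect_true(criteria_report(a, b)$criterion_iv)
  expect_true(criteria_report(a, b)$same_gcf)
  # position-matched domains unrelated -> IV fails even though roles align
  c_ <- mk("c", random_protein_seq(150), random_protein_seq(150))
  repc <- criteria_report(a, c_)
  expect_false(repc$criterion_iv)
  # modular class without module annotation: IV not applicable, warned
  d <- gene_bgc("d", c("r1", "r2", "r3"),
                replicate(3, random_protein_seq(100)), class = "PKS")
  expect_warning(repd <- criteria_report(d, d), "not applicable")
  expect_true(is.na(repd$criterion_iv))
  expect_true(repd$same_gcf)  # IV waived when not applicable
})

test_that("criteria are symmetric in their arguments", {
  withr::local_seed(44)
  ds <- generate_dataset(simulation_params(
    n_clades = 2, strains_per_clade = 2, n_outlier_strains = 0,
    n_core_gcfs = 2, n_clade_gcfs_per_clade = 1, n_rare_gcfs = 1,
    mean_unique_per_strain = 1, seed = 5))
  bgcs <- all_bgcs(ds$genomes)
  for (i in 1:15) {
    pair <- sample(bgcs, 2)
    r1 <- suppressWarnings(criteria_report(pair[[1]], pair[[2]]))
    r2 <- suppressWarnings(criteria_report(pair[[2]], pair[[1]]))
    expect_identical(r1, r2)
  }
})

test_that("families are the transitive closure of pairwise membership", {
  withr::local_seed(45)
  P <- random_protein_seq(150); Q <- random_protein_seq(150)
  R <- random_protein_seq(150); S <- random_protein_seq(150)
  TT <- random_protein_seq(150)
  roles <- c("r1", "r2", "r3")
  A <- gene_bgc("A", roles, c(P, Q, R), genome = "g1")
  B <- gene_bgc("B", roles, c(P, Q, S), genome = "g2")
  C <- gene_bgc("C", roles, c(TT, Q, S), genome = "g3")
  # A~B share 2/3, B~C share 2/3, A~C share only 1/3
  expect_true(criteria_report(A, B)$same_gcf)
  expect_true(criteria_report(B, C)$same_gcf)
  expect_false(criteria_report(A, C)$same_gcf)
  part <- assign_gcfs(list(A, B, C))
  expect_equal(nrow(part$families), 1L)
  expect_equal(unique(part$assignments$family_id), "GCF:A")

  # unrelated clusters each form their own family
  lone <- lapply(1:4, function(i)
    gene_bgc(paste0("L", i), paste0("q", i, 1:3),
             replicate(3, random_protein_seq(100)), genome = paste0("g", i)))
  part2 <- assign_gcfs(lone)
  expect_equal(nrow(part2$families), 4L)
})

test_that("assignment is invariant to BGC input order", {
  ds <- generate_dataset(simulation_params(
    n_clades = 2, strains_per_clade = 2, n_outlier_strains = 1,
    n_core_gcfs = 2, n_clade_gcfs_per_clade = 2, n_rare_gcfs = 2,
    mean_unique_per_strain = 1, seed = 9))
  bgcs <- all_bgcs(ds$genomes)
  p1 <- assign_gcfs(bgcs)
  withr::local_seed(46)
  p2 <- assign_gcfs(sample(bgcs))
  a1 <- p1$assignments[order(p1$assignments$bgc_id), ]
  a2 <- p2$assignments[order(p2$assignments$bgc_id), ]
  expect_equal(a1$family_id, a2$family_id)
})

test_that("a precomputed hit table can stand in for alignment", {
  roles <- c("r1", "r2", "r3")
  protless <- function(id, genome) {
    g <- gene_bgc(id, roles, c("M", "M", "M"), genome = genome)
    g$genes$protein <- NA_character_
    g
  }
  A <- protless("A", "g1"); B <- protless("B", "g2")
  hits <- data.frame(
    query_id = c("A_g1", "A_g2"), subject_id = c("B_g1", "B_g2"),
    identity = c(0.9, 0.9), query_coverage = c(1, 1))
  rep <- criteria_report(A, B, hits = hits)
  expect_true(rep$criterion_iii)  # 2/3 qualifying > 0.5
  expect_true(rep$same_gcf)
  # without hits and without proteins the criterion cannot be evaluated
  expect_error(criteria_report(A, B), "protein sequences or a hit table")
})

test_that("family frequency categories follow strain counts", {
  lab <- gcf_partition_from_labels(
    bgc_id = c("b1", "b2", "b3", "b4", "b5", "b6", "b7", "b8", "b9"),
    genome_id = c("s1", "s2", "s3", "s4", "s5", "s1", "s2", "s1", "s1"),
    bgc_class = "Other",
    family_id = c("F1", "F1", "F1", "F1", "F1", "F2", "F2", "F3", "F3"))
  cat_ <- categorize_gcfs(lab)
  fam <- cat_$families
  expect_equal(fam$category[fam$family_id == "F1"], "common")  # 5 strains
  expect_equal(fam$category[fam$family_id == "F2"], "rare")    # 2 strains
  # F3 has two BGC copies but in a single strain: unique by strain count
  expect_equal(fam$category[fam$family_id == "F3"], "unique")
  expect_equal(cat_$frequency$n_families,
               c(1L, 1L, 1L))
})
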