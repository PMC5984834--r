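# Domain-content similarity metrics and the thresholded network.

test_that("Jaccard index matches hand-computed values", {
  expect_equal(domain_jaccard(c(PF00109 = 1L, PF02801 = 2L),
                              c(PF00109 = 3L, PF02801 = 1L)), 1)
  expect_equal(domain_jaccard(c(PF00109 = 1L), c(PF00668 = 1L)), 0)
  # |{PF02801, PF00550}| / |{PF00109, PF02801, PF00550, PF00668}|
  expect_equal(domain_jaccard(c(PF00109 = 1L, PF02801 = 1L, PF00550 = 1L),
                              c(PF02801 = 1L, PF00550 = 1L, PF00668 = 1L)),
               0.5)
  expect_equal(domain_jaccard(integer(), integer()), 0)
})

test_that("domain duplication index matches hand-computed values", {
  a <- c(PF00109 = 2L, PF02801 = 1L)
  expect_equal(domain_duplication_similarity(a, a), 1)
  expect_equal(domain_duplication_similarity(c(PF00109 = 1L),
                                             c(PF00668 = 1L)), 0)
  # |2-1| / (2 + 1) -> 1 - 1/3
  expect_equal(domain_duplication_similarity(a, c(PF00109 = 1L,
                                                  PF02801 = 1L)), 2 / 3)
  expect_warning(v <- domain_duplication_similarity(integer(), integer()),
                 "empty domain annotation")
  expect_equal(v, 0)
})

test_that("combined similarity is the weighted sum of its components", {
  a <- c(PF00109 = 2L, PF02801 = 1L)
  b <- c(PF00109 = 1L, PF02801 = 1L)
  # J = 1, DDI = 2/3 under default weights 0.36/0.64
  expect_equal(combined_similarity(a, b), 0.36 + 0.64 * 2 / 3)
  expect_equal(combined_similarity(a, a), 1)
  expect_equal(combined_similarity(c(PF00109 = 1L), c(PF00668 = 2L)), 0)
  expect_equal(combined_similarity(integer(), integer()), 0)
  expect_error(similarity_params(w_jaccard = 0.5, w_ddi = 0.6),
               "sum to 1")
})

test_that("similarity metrics are symmetric, bounded, and agree with the
           enumeration oracle on random pairs", {
  withr::local_seed(101)
  for (i in 1:300) {
    a <- random_domains(); b <- random_domains()
    j <- domain_jaccard(a, b)
    expect_identical(j, domain_jaccard(b, a))
    expect_true(j >= 0 && j <= 1)
    expect_equal(j, oracle_jaccard(a, b), tolerance = 1e-12)
    if (length(a) || length(b)) {
      dd <- domain_duplication_similarity(a, b)
      expect_identical(dd, domain_duplication_similarity(b, a))
      expect_true(dd >= 0 && dd <= 1)
      expect_equal(dd, oracle_ddi(a, b), tolerance = 1e-12)
    }
  }
})

test_that("adding a domain shared by both clusters never decreases Jaccard", {
  withr::local_seed(102)
  for (i in 1:100) {
    a <- random_domains(alphabet = 20); b <- random_domains(alphabet = 20)
    new <- setdiff(sprintf("PF%05d", 21:40),
                   c(names(a), names(b)))[1]
    j0 <- domain_jaccard(a, b)
    j1 <- domain_jaccard(c(a, setNames(1L, new)), c(b, setNames(1L, new)))
    expect_gte(j1, j0)
  }
})

test_that("network edges follow thresholding and components the closure", {
  # single BGC: 1 node, no edges, 1 singleton component
  net1 <- build_network(list(domain_bgc("A", c(PF00001 = 1L))))
  expect_equal(igraph::vcount(net1$graph), 1L)
  expect_equal(igraph::ecount(net1$graph), 0L)
  expect_equal(net1$n_components, 1L)
  expect_equal(net1$n_singletons, 1L)

  # pair with S = 0.36 + 0.64 * 2/3 ~ 0.787 >= 0.65: one edge, one component
  a <- domain_bgc("A", c(PF00109 = 2L, PF02801 = 1L))
  b <- domain_bgc("B", c(PF00109 = 1L, PF02801 = 1L))
  net2 <- build_network(list(a, b))
  expect_equal(igraph::ecount(net2$graph), 1L)
  expect_equal(net2$n_components, 1L)

  # A-B similar, B-C similar, A-C dissimilar: one component, two edges
  A <- domain_bgc("A", setNames(rep(1L, 4), sprintf("PF%05d", 1:4)))
  B <- domain_bgc("B", setNames(rep(1L, 5), sprintf("PF%05d", 1:5)))
  C <- domain_bgc("C", setNames(rep(1L, 5), sprintf("PF%05d", 2:6)))
  sAB <- combined_similarity(A, B); sBC <- combined_similarity(B, C)
  sAC <- combined_similarity(A, C)
  expect_true(sAB >= 0.65 && sBC >= 0.65 && sAC < 0.65)
  net3 <- build_network(list(A, B, C))
  expect_equal(igraph::ecount(net3$graph), 2L)
  expect_equal(net3$n_components, 1L)
  expect_equal(unname(net3$components["A"]), unname(net3$components["C"]))
})

test_that("component partition is invariant to node input order", {
  withr::local_seed(103)
  bgcs <- lapply(1:25, function(i)
    domain_bgc(sprintf("B%02d", i), random_domains(alphabet = 12)))
  ref <- build_network(bgcs)$components
  for (rep in 1:5) {
    perm <- sample(bgcs)
    got <- build_network(perm)$components
    # same partition as sets of node names
    ref_sets <- sort(unname(vapply(split(names(ref), ref),
                            function(s) paste(sort(s), collapse = ","), "")))
    got_sets <- sort(unname(vapply(split(names(got), got),
                            function(s) paste(sort(s), collapse = ","), "")))
    expect_identical(got_sets, ref_sets)
  }
})

test_that("reference partition accounting classifies components by source", {
  mk <- function(id, dom, src) domain_bgc(id, dom, source = src)
  d1 <- c(PF00001 = 1L, PF00002 = 1L)
  d2 <- c(PF00010 = 1L)
  d3 <- c(PF00020 = 2L, PF00021 = 1L)
  net <- build_network(list(mk("o1", d1, "own"), mk("o2", d1, "own"),
                            mk("r1", d2, "reference"),
                            mk("o3", d3, "own"), mk("r2", d3, "reference")))
  counts <- partition_vs_reference(net)
  expect_equal(counts$own_only, 1L)
  expect_equal(counts$reference_only, 1L)
  expect_equal(counts$mixed, 1L)
  expect_equal(counts$own_only_singletons, 0L)
  expect_equal(counts$n_components, 3L)

  # all own, no edges
  solo <- lapply(1:5, function(i)
    domain_bgc(paste0("s", i), setNames(1L, sprintf("PF%05d", i * 10))))
  counts2 <- partition_vs_reference(build_network(solo))
  expect_equal(counts2$own_only, 5L)
  expect_equal(counts2$own_only_singletons, 5L)
  expect_equal(counts2$reference_only, 0L)
  expect_equal(counts2$mixed, 0L)
})
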