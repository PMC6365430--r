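test_that("local alignment scores match contract cases", {
  s <- "MKWVHEAGAW"
  expect_equal(sw_score(s, s),
               sum(diag(blosum62)[strsplit(s, "")[[1]]]))
  expect_equal(sw_score("", s), 0L)
  expect_equal(sw_score(s, ""), 0L)
  # frozen from the independent DP oracle
  expect_equal(sw_score("HEAGAWGHEE", "PAWHEAE"), 17L)
  expect_equal(oracle_sw("HEAGAWGHEE", "PAWHEAE", blosum62), 17)
})

test_that("local alignment equals the independent DP oracle and is symmetric", {
  set.seed(421)
  for (k in 1:60) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    s <- sw_score(a, b)
    expect_equal(s, as.integer(oracle_sw(a, b, blosum62)))
    expect_equal(s, sw_score(b, a))
  }
})

test_that("similarity graph edges follow the normalization and coverage rules", {
  set.seed(7)
  p <- random_protein(80)
  genes <- make_genes(c("sA_g1", "sB_g1"), c("sA", "sB"), c(p, p))
  g <- build_similarity_graph(genes)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1.0)

  unrelated <- make_genes(c("sA_g1", "sB_g1"), c("sA", "sB"),
                          c(random_protein(80), random_protein(80)))
  g2 <- build_similarity_graph(unrelated, min_norm_score = 0.5,
                               min_shared_kmers = 0L)
  expect_equal(nrow(g2$edges), 0L)

  single <- make_genes("sA_g1", "sA", random_protein(40))
  g3 <- build_similarity_graph(single)
  expect_equal(length(g3$nodes), 1L)
  expect_equal(nrow(g3$edges), 0L)

  ## a half-length fragment of p: weight 1 against p, coverage of the
  ## shorter sequence is complete, so the edge is kept
  frag <- substr(p, 1, 40)
  gf <- build_similarity_graph(
    make_genes(c("sA_g1", "sB_g1"), c("sA", "sB"), c(p, frag)))
  expect_equal(nrow(gf$edges), 1L)
  expect_equal(gf$edges$weight, 1.0)
})

test_that("MCL resolves the canonical fixtures", {
  tri <- function(nodes, w = 1) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = w)
  }
  ## two disjoint triangles -> the two components, any inflation
  g <- make_graph(c(letters[1:6]),
                  rbind(tri(letters[1:3]), tri(letters[4:6])))
  cl <- mcl_cluster(g, inflation = 1.5)
  expect_equal(cl, list(c("a", "b", "c"), c("d", "e", "f")),
               ignore_attr = TRUE)
  ## complete graph K4 -> one cluster
  g4 <- make_graph(letters[1:4], tri(letters[1:4]))
  expect_equal(length(mcl_cluster(g4, inflation = 1.5)), 1L)
  ## two triangles joined by a weak bridge -> 2 clusters at inflation 2
  gb <- make_graph(letters[1:6],
                   rbind(tri(letters[1:3]), tri(letters[4:6]),
                         data.frame(from = "c", to = "d", weight = 0.1)))
  clb <- mcl_cluster(gb, inflation = 2.0)
  expect_equal(clb, list(c("a", "b", "c"), c("d", "e", "f")),
               ignore_attr = TRUE)
})

test_that("MCL output is a partition and respects components", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 14
    nodes <- sprintf("n%02d", 1:n)
    ## random graph in two halves with no cross edges
    mk <- function(idx) {
      p <- t(combn(idx, 2))
      keep <- runif(nrow(p)) < 0.5
      data.frame(from = nodes[p[keep, 1]], to = nodes[p[keep, 2]],
                 weight = runif(sum(keep), 0.3, 1))
    }
    edges <- rbind(mk(1:7), mk(8:14))
    g <- make_graph(nodes, edges)
    cl <- mcl_cluster(g, inflation = 1.5 + rep / 4)
    expect_setequal(unlist(cl), nodes)
    expect_equal(anyDuplicated(unlist(cl)), 0L)
    for (memb in cl) {
      half <- unique(as.integer(substring(memb, 2)) <= 7)
      expect_length(half, 1L)   # never spans the two components
    }
  }
})

test_that("clusters become OGs with states, copy flags and stable ids", {
  genes <- make_genes(
    c("sA_g1", "sB_g1", "sC_g1", "sB_g2", "sC_g2", "sC_g3"),
    c("sA", "sB", "sC", "sB", "sC", "sC"),
    rep("MKTEST", 6),
    intact = c("intact", "intact", "intact", "pseudo", "intact", "intact"))
  part <- list(c("sA_g1", "sB_g1", "sC_g1"),    # single-copy core
               c("sB_g2"),                      # pseudo-only in sB
               c("sC_g2", "sC_g3"))             # paralogs in sC
  ogs <- clusters_to_ogs(part, genes)
  expect_true(ogs$ogs[[1]]$single_copy)
  expect_equal(unname(ogs$ogs[[1]]$state), rep("present", 3))
  og2 <- ogs$ogs[[2]]
  expect_equal(unname(og2$state[c("sA", "sB", "sC")]),
               c("absent", "pseudo", "absent"))
  expect_false(og2$single_copy)
  expect_false(ogs$ogs[[3]]$single_copy)
  expect_equal(vapply(ogs$ogs, `[[`, character(1), "og_id"),
               c("OG0001", "OG0002", "OG0003"))
  expect_error(clusters_to_ogs(part[-1], genes), "cover")
})

test_that("OG tables round-trip including pseudogene marks", {
  genes <- make_genes(c("sA_g1", "sB_g1", "sB_g2"),
                      c("sA", "sB", "sB"), rep("MKT", 3),
                      intact = c("intact", "pseudo", "intact"))
  ogs <- clusters_to_ogs(list(c("sA_g1", "sB_g1"), "sB_g2"), genes)
  tmp <- tempfile(fileext = ".tsv")
  write_og_table(ogs, genes, tmp)
  back <- read_og_table(tmp)
  expect_equal(back$strains, ogs$strains)
  expect_equal(back$ogs, ogs$ogs)
  expect_equal(og_gene_intact(back)[["sB_g1"]], "pseudo")
  expect_equal(og_gene_intact(back)[["sA_g1"]], "intact")
})
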