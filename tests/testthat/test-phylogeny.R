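test_that("single-copy core selection follows copy counts", {
  genes <- make_genes(
    c("sA_g1", "sB_g1", "sA_g2", "sB_g2", "sB_g3", "sA_g4"),
    c("sA", "sB", "sA", "sB", "sB", "sA"), rep("MKT", 6))
  part <- list(c("sA_g1", "sB_g1"),            # 1 copy everywhere
               c("sA_g2", "sB_g2", "sB_g3"),   # 2 copies in sB
               c("sA_g4"))                     # missing in sB
  ogs <- clusters_to_ogs(part, genes)
  expect_equal(select_single_copy_core(ogs), "OG0001")
  ogs2 <- clusters_to_ogs(list(c("sA_g1"), c("sB_g1"), c("sA_g2"),
                               c("sB_g2"), c("sB_g3"), c("sA_g4")), genes)
  expect_error(select_single_copy_core(ogs2), "single-copy")
})

test_that("supermatrix isolates variable columns with provenance", {
  ## identical blocks -> empty supermatrix
  blk0 <- list(og1 = c(sA = "ACGT", sB = "ACGT"))
  expect_equal(build_supermatrix(blk0)$total_columns, 0L)
  ## single difference
  blk1 <- list(og1 = c(sA = "ACGT", sB = "ACGA"))
  sm <- build_supermatrix(blk1)
  expect_equal(sm$total_columns, 1L)
  expect_equal(unname(sm$seqs), c("T", "A"))
  expect_equal(sm$provenance$column, 4L)
  ## gap and ambiguity columns are skipped
  blk2 <- list(og1 = c(sA = "A-GTN", sB = "ACGAN"))
  sm2 <- build_supermatrix(blk2)
  expect_equal(sm2$total_columns, 1L)
  expect_equal(sm2$provenance$column, 4L)
  expect_error(build_supermatrix(list(og1 = c(sA = "AC", sB = "ACG"))),
               "lengths")
  expect_error(build_supermatrix(list(og1 = c(sA = "AC", sB = "AC"),
                                      og2 = c(sA = "AC", sC = "AC"))),
               "strain sets")
})

test_that("multi-block supermatrix equals an independent per-block scan", {
  set.seed(5)
  strains <- c("sA", "sB", "sC")
  blocks <- lapply(setNames(1:3, c("ogA", "ogB", "ogC")), function(i) {
    L <- 30
    base <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    vary <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(L, 5)
      ch[idx] <- sample(c("A", "C", "G", "T"), 5, TRUE)
      paste(ch, collapse = "")
    }
    setNames(c(base, vary(base), vary(base)), strains)
  })
  sm <- build_supermatrix(blocks)
  ## oracle: scan each block independently, concatenate in sorted order
  exp_cols <- list()
  for (og in sort(names(blocks))) {
    ch <- do.call(rbind, strsplit(blocks[[og]][strains], ""))
    for (j in seq_len(ncol(ch)))
      if (length(unique(ch[, j])) >= 2)
        exp_cols[[length(exp_cols) + 1L]] <- list(og = og, col = j,
                                                  chars = ch[, j])
  }
  expect_equal(sm$total_columns, length(exp_cols))
  expect_equal(sm$provenance$og_id,
               vapply(exp_cols, `[[`, character(1), "og"))
  expect_equal(sm$provenance$column,
               vapply(exp_cols, function(x) x$col, numeric(1)))
  want <- apply(do.call(cbind, lapply(exp_cols, `[[`, "chars")), 1, paste,
                collapse = "")
  expect_equal(unname(sm$seqs), unname(want))
  ## row-order invariance of the input
  sm2 <- build_supermatrix(lapply(blocks, function(b) b[rev(strains)]))
  expect_equal(sm2$seqs, sm$seqs)
})

test_that("p-distances count mismatching columns", {
  sm <- build_supermatrix(list(og = c(sA = "AAAA", sB = "AAAT",
                                      sC = "TTTT")))
  d <- p_distance_matrix(sm)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["sA", "sC"], 1)
  expect_equal(d["sA", "sB"], 0.25)
  expect_equal(d, t(d))
  empty <- build_supermatrix(list(og = c(sA = "AA", sB = "AA")))
  expect_error(p_distance_matrix(empty), "no columns")
})

test_that("neighbor joining solves the small closed-form cases", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(t2$edge.length, c(0.2, 0.2))
  ## three taxa: exact three-point formulas
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 0.3
  d3["a", "c"] <- d3["c", "a"] <- 0.5
  d3["b", "c"] <- d3["c", "b"] <- 0.6
  t3 <- nj_tree(d3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(len[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(len[["c"]], (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("neighbor joining is exact on additive matrices", {
  ## hand-built 4-taxon additive tree: ((a:0.1,b:0.2):0.05,(c:0.3,d:0.4));
  tru <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.4):0.0);")
  d <- ape::cophenetic.phylo(tru)
  fit <- nj_tree(d)
  expect_equal(rf_distance(fit, tru), 0L)
  expect_equal(ape::cophenetic.phylo(fit)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  ## random simulated trees, noiseless patristic distances
  for (seed in 1:6) {
    tr <- simulate_tree(8, seed = seed)
    pd <- ape::cophenetic.phylo(tr)
    fit <- nj_tree(pd)
    expect_equal(rf_distance(fit, tr), 0L)
    expect_lt(max(abs(ape::cophenetic.phylo(fit)[rownames(pd),
                                                 colnames(pd)] - pd)),
              1e-9)
    ## dual route: ape's own NJ agrees on the topology
    expect_equal(rf_distance(fit, ape::nj(pd)), 0L)
  }
})

test_that("rerooting splits the outgroup edge and preserves topology", {
  tr <- simulate_tree(6, seed = 3)
  un <- ape::unroot(tr)
  out <- .tips_under_test(un)
  rt <- reroot_tree(un, out)
  expect_true(ape::is.rooted(rt))
  expect_equal(rf_distance(rt, un), 0L)
  root <- rt$edge[1, 1]
  re <- which(rt$edge[, 1] == root)
  expect_equal(rt$edge.length[re][1], rt$edge.length[re][2])
  ## single-tip outgroup
  rt1 <- reroot_tree(un, un$tip.label[1])
  expect_true(ape::is.rooted(rt1))
  expect_equal(rf_distance(rt1, un), 0L)
  expect_error(reroot_tree(un, un$tip.label), "proper")
  ## a non-split tip set must be refused
  bad <- .non_split_pair(un)
  if (!is.null(bad)) expect_error(reroot_tree(un, bad), "monophyletic")
})

test_that("RF distance equals the exhaustive bipartition oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  for (seed in 1:6) {
    x <- ape::unroot(simulate_tree(8, seed = seed))
    y <- ape::unroot(simulate_tree(8, seed = seed + 100))
    expect_equal(rf_distance(x, y), oracle_rf(x, y))
  }
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_distance(t1, t3), "leaf")
})

test_that("supermatrix files are written as PHYLIP plus provenance", {
  sm <- build_supermatrix(list(og = c(sA = "ACGT", sB = "ACGA")))
  phy <- tempfile(fileext = ".phy"); prov <- tempfile(fileext = ".tsv")
  write_supermatrix(sm, phy, prov)
  lines <- readLines(phy)
  expect_equal(lines[1], "2 1")
  expect_equal(lines[2], "sA T")
  expect_equal(nrow(read.delim(prov)), 1L)
})
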