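test_that("trait score handles perfect, constant and pseudo-neutral cases", {
  lab <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "B", s5 = "B", s6 = "B")
  perfect <- c(s1 = 2L, s2 = 2L, s3 = 2L, s4 = 0L, s5 = 0L, s6 = 0L)
  r <- og_trait_score(perfect, lab)
  expect_equal(r$score, 1)
  expect_equal(r$orientation, "present->A")
  constant <- setNames(rep(2L, 6), names(lab))
  rc <- og_trait_score(constant, lab)
  expect_equal(rc$score, 0.5)          # 1 - min(3,3)/6 for balanced classes
  pseudo <- perfect
  pseudo["s4"] <- 1L                   # would-be error cell is neutral
  rp <- og_trait_score(pseudo, lab)
  expect_equal(rp$score, 1)
  expect_equal(rp$n_pseudo_neutral, 1L)
  expect_error(og_trait_score(perfect, c(s1 = "A", s2 = "B", s3 = "B")),
               "at least 2")
})

test_that("trait score is invariant to swapping the class labels", {
  set.seed(41)
  for (k in 1:20) {
    n <- 8
    states <- setNames(sample(0:2, n, TRUE), sprintf("s%d", 1:n))
    lab <- setNames(c("A", "A", "B", "B", sample(c("A", "B"), n - 4, TRUE)),
                    names(states))
    swapped <- setNames(ifelse(lab == "A", "B", "A"), names(lab))
    r1 <- og_trait_score(states, lab)
    r2 <- og_trait_score(states, swapped)
    expect_equal(r1$score, r2$score)
    ## unless the orientations tie (when the deterministic tie-break wins),
    ## the predicted-class name flips with the labels
    errA <- sum(states == 2L & lab == "B") + sum(states == 0L & lab == "A")
    errB <- sum(states == 2L & lab == "A") + sum(states == 0L & lab == "B")
    if (errA != errB)
      expect_equal(sub("present->", "", r1$orientation) == "A",
                   sub("present->", "", r2$orientation) == "B")
  }
})

test_that("converting an error cell to pseudo never decreases the score", {
  set.seed(43)
  for (k in 1:30) {
    n <- 10
    states <- setNames(sample(c(0L, 2L), n, TRUE), sprintf("s%d", 1:n))
    lab <- setNames(rep(c("A", "B"), each = n / 2), names(states))
    r <- og_trait_score(states, lab)
    ## find an error cell under the fitted orientation
    presA <- sub("present->", "", r$orientation) == "A"
    err <- names(states)[(states == 2L & (lab == "B") == presA) |
                         (states == 0L & (lab == "A") == presA)]
    if (!length(err)) next
    states2 <- states
    states2[err[1]] <- 1L
    expect_gte(og_trait_score(states2, lab)$score, r$score)
  }
})

test_that("permutation p-values are exact for planted markers", {
  ## 24 strains: the permutation space (C(24,12) ~ 2.7e6) dwarfs n_perm,
  ## so no permuted labeling reproduces a perfect split and the planted
  ## marker attains the minimum attainable p.
  set.seed(47)
  n <- 24
  strains <- sprintf("s%02d", 1:n)
  lab <- setNames(rep(c("A", "B"), each = n / 2), strains)
  m <- matrix(sample(0:2, n * 50, TRUE), n,
              dimnames = list(strains, sprintf("bg%02d", 1:50)))
  m <- cbind(m, marker = c(rep(2L, n / 2), rep(0L, n / 2)))
  m[1, colSums(m) == 0] <- 2L
  pm <- as_pm(m)
  res <- rank_discriminating_ogs(pm, lab, n_perm = 199, seed = 7)
  expect_equal(res$og_id[1], "marker")
  expect_equal(res$score[1], 1)
  expect_equal(res$p_perm[1], 1 / 200)
  ## a constant OG can never beat its own permuted scores
  pmc <- as_pm(cbind(m, const = rep(2L, n)))
  resc <- rank_discriminating_ogs(pmc, lab, n_perm = 199, seed = 7)
  expect_equal(resc$p_perm[resc$og_id == "const"], 1)
  expect_equal(resc$score[resc$og_id == "const"], 0.5)
  ## BH q-values are monotone in p-value rank
  o <- order(res$p_perm)
  expect_true(all(diff(res$q_bh[o]) >= -1e-12))
})

test_that("leave-one-out prediction is perfect on planted markers", {
  sim <- cached_sim(303, n_strains = 16L)
  pm <- sim_presence_matrix(sim)
  res <- rank_discriminating_ogs(pm, sim$traits$clade, n_perm = 99,
                                 seed = 3)
  sel <- top_discriminating_ogs(res)
  expect_true(all(sim$truth$marker_ogs$clade %in% sel))
  loo <- loo_predict(pm, sim$traits$clade, sel)
  expect_equal(loo$error_rate, 0)
  expect_equal(unname(loo$predicted[names(sim$traits$clade)]),
               unname(sim$traits$clade))
  expect_error(loo_predict(pm, sim$traits$clade, "nope"), "unknown OG")
})

test_that("length-based pseudogene calls respect the median rule", {
  aa <- c(strrep("M", 100), strrep("M", 100), strrep("M", 100),
          strrep("M", 50), strrep("M", 100))
  genes <- make_genes(sprintf("s%d_g", 1:5), sprintf("s%d", 1:5), aa)
  part <- list(genes$gene_id[1:4], genes$gene_id[5])
  out <- call_pseudogenes(genes, part, length_fraction = 0.8)
  expect_equal(out$intact, c("intact", "intact", "intact", "pseudo",
                             "intact"))
  ## full-length member stays intact
  out2 <- call_pseudogenes(genes, list(genes$gene_id[1:3]), 0.8)
  expect_true(all(out2$intact == "intact"))
  ## pairs are too small for a median rule
  small <- make_genes(c("a_g", "b_g"), c("a", "b"),
                      c(strrep("M", 100), strrep("M", 10)))
  expect_true(all(call_pseudogenes(small, list(small$gene_id))$intact ==
                    "intact"))
})

test_that("heatmap ordering matches complete-linkage and keeps twins together", {
  ## tie-free 4-point fixture checked against the brute-force linkage oracle
  m <- as_pm(rbind(r1 = c(2L, 2L, 0L, 0L), r2 = c(2L, 2L, 0L, 2L),
                   r3 = c(0L, 0L, 2L, 2L), r4 = c(0L, 1L, 2L, 2L)))
  colnames(m) <- sprintf("og%d", 1:4)
  got <- heatmap_order(m, metric = "manhattan")
  oracle <- oracle_complete_linkage(unclass(m) / 2, "manhattan")
  heights <- vapply(oracle, `[[`, numeric(1), "height")
  expect_equal(sort(got$hclust$height), sort(heights))
  first <- rownames(m)[oracle[[1]]$members]
  pos <- match(first, got$order)
  expect_equal(abs(diff(pos)), 1L)   # first merge pair ends up adjacent
  ## identical rows are adjacent leaves
  m2 <- as_pm(rbind(a = c(2L, 0L, 2L), b = c(0L, 2L, 0L),
                    c = c(2L, 0L, 2L), d = c(2L, 2L, 2L)))
  ho <- heatmap_order(m2, metric = "euclidean")
  expect_equal(abs(diff(match(c("a", "c"), ho$order))), 1L)
  expect_error(heatmap_order(m2, metric = "cosine"), "arg")
})
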