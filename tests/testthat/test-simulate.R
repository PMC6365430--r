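test_that("simulated trees have the promised shape and determinism", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(t2$tip.label), c("s01", "s02"))
  expect_equal(nrow(t2$edge), 2L)
  for (n in c(5, 9, 12)) {
    tr <- simulate_tree(n, seed = n)
    expect_equal(length(tr$tip.label), n)
    cl <- attr(tr, "clades")
    expect_true(all(table(cl) >= 2L))
    ## unit root-to-tip depth
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_equal(max(depths), 1)
  }
  expect_equal(ape::write.tree(simulate_tree(10, seed = 5)),
               ape::write.tree(simulate_tree(10, seed = 5)))
  expect_error(simulate_tree(1, seed = 1), "at least 2")
})

test_that("sequence evolution is seeded, rate-0 exact, and stop-free", {
  tr <- simulate_tree(4, seed = 2)
  g0 <- evolve_sequences(tr, 3, 90, rate = 0, seed = 9)
  for (g in g0) expect_equal(length(unique(g)), 1L)
  g1 <- evolve_sequences(tr, 3, 90, rate = 0.1, seed = 9)
  g2 <- evolve_sequences(tr, 3, 90, rate = 0.1, seed = 9)
  expect_identical(g1, g2)
  stops <- c("TAA", "TAG", "TGA")
  for (g in g1) for (s in g) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% stops))
  }
})

test_that("observed p-distance matches the Jukes-Cantor expectation", {
  tr <- simulate_tree(2, seed = 6)
  rate <- 0.05
  L <- 30000L
  sep <- ape::cophenetic.phylo(tr)[1, 2]
  g <- evolve_sequences(tr, 1, L, rate = rate, seed = 8)[[1]]
  a <- strsplit(g[[1]], "")[[1]]
  b <- strsplit(g[[2]], "")[[1]]
  p_obs <- mean(a != b)
  p_exp <- 0.75 * (1 - exp(-4 * sep * rate / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("planted structure matches its indicators and knobs", {
  cfg <- sim_config(seed = 21, n_strains = 10L)
  sim <- simulate_dataset(cfg)
  pm <- sim_presence_matrix(sim)
  cl <- sim$traits$clade
  for (f in sim$truth$marker_ogs$clade)
    expect_equal(unname(pm[names(cl), f] == 2L), unname(cl == "A"))
  ni <- sim$traits$niche
  for (f in sim$truth$marker_ogs$niche)
    expect_equal(unname(pm[names(ni), f] == 2L), unname(ni == "dairy"))
  for (f in sim$truth$plasmid_ogs)
    expect_setequal(rownames(pm)[pm[, f] != 0L], sim$truth$plasmid_strains)
  ## pseudogenized pairs sit inside the nominated subclade, truncated 30-70%
  pp <- sim$truth$pseudo_pairs
  expect_true(all(pp$strain %in% sim$truth$pseudo_clade))
  full_aa <- nchar(sim$genes$aa_seq[sim$genes$intact == "intact"][1])
  pseudo_len <- nchar(sim$genes$aa_seq[sim$genes$intact == "pseudo"])
  expect_true(all(pseudo_len >= floor(0.3 * full_aa) - 1 &
                    pseudo_len <= ceiling(0.7 * full_aa) + 1))
  ## plasmid contigs sit at the configured coverage multiple
  covA <- sim$coverage
  for (s in unique(covA$strain[covA$contig == "p1"])) {
    r <- covA$mean_depth[covA$strain == s & covA$contig == "p1"] /
      covA$mean_depth[covA$strain == s & covA$contig == "c1"]
    expect_equal(r, cfg$coverage_multiplier)
  }
  ## no pseudogenes at all when the fraction is zero
  sim0 <- simulate_dataset(sim_config(seed = 22, n_strains = 8L,
                                      pseudo_fraction = 0))
  expect_equal(nrow(sim0$truth$pseudo_pairs), 0L)
  expect_true(all(sim0$genes$intact == "intact"))
})

test_that("emitted datasets are complete and byte-identical under a seed", {
  cfg <- sim_config(seed = 23, n_strains = 6L, n_core_ogs = 8L)
  d1 <- file.path(tempdir(), "emit1"); d2 <- file.path(tempdir(), "emit2")
  p1 <- emit_dataset(simulate_dataset(cfg), d1)
  p2 <- emit_dataset(simulate_dataset(cfg), d2)
  expect_true(all(file.exists(p1)))
  st <- read_strain_table(file.path(d1, "strains.tsv"))
  expect_equal(nrow(st), 6L)
  expect_equal(length(read_trait_table(file.path(d1, "trait_clade.tsv"))),
               6L)
  expect_equal(length(list.files(file.path(d1, "genes"),
                                 pattern = "\\.fna$")), 6L)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_equal(h1, h2)
  ## re-reading the emitted genes reproduces the in-memory gene table
  g <- read_gene_fasta(file.path(d1, "genes", "s01.fna"),
                       file.path(d1, "genes", "s01.faa"), "s01")
  sim <- simulate_dataset(cfg)
  mem <- sim$genes[sim$genes$strain == "s01", ]
  mem <- mem[order(mem$gene_id), ]
  rownames(mem) <- NULL
  expect_equal(g[c("gene_id", "nt_seq", "aa_seq")],
               mem[c("gene_id", "nt_seq", "aa_seq")])
})
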