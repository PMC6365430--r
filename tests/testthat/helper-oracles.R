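## Independent oracles used across the suite. Each is a deliberately naive
## reimplementation, kept separate from the code paths it checks.

## Quadratic Gotoh local-alignment DP. A gap of length L costs
## open + L * extend, matching the package contract.
oracle_sw <- function(a, b, submat, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)    # best score ending at (i,j)
  E <- matrix(-Inf, n + 1, m + 1) # gap in A (consuming B)
  F <- matrix(-Inf, n + 1, m + 1) # gap in B (consuming A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_protein <- function(len) {
  paste(sample(rownames(blosum62)[1:20], len, replace = TRUE),
        collapse = "")
}

## Exhaustive pan/core curves: enumerate all strain orderings.
oracle_pan_core <- function(pm) {
  nonabs <- unclass(pm) != 0L
  n <- nrow(nonabs)
  perms <- combinat_perms(n)
  pan <- core <- matrix(0L, length(perms), n)
  for (r in seq_along(perms)) {
    o <- perms[[r]]
    for (k in seq_len(n)) {
      sub <- nonabs[o[seq_len(k)], , drop = FALSE]
      pan[r, k] <- sum(colSums(sub) >= 1L)
      core[r, k] <- sum(colSums(sub) == k)
    }
  }
  data.frame(k = seq_len(n),
             pan_mean = colMeans(pan), pan_sd = apply(pan, 2, sd),
             core_mean = colMeans(core), core_sd = apply(core, 2, sd))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, pos - 1L)
  }
  out
}

## Non-trivial bipartitions of an unrooted tree as canonical strings.
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  internal_children <- tree$edge[tree$edge[, 2] > length(tree$tip.label), 2]
  parts <- lapply(internal_children, below)
  canon <- vapply(parts, function(s) {
    s <- sort(s)
    comp <- sort(setdiff(tips, s))
    if (length(s) < 2L || length(comp) < 2L) return(NA_character_)
    paste(if (s[1] < comp[1]) s else comp, collapse = ",")
  }, character(1))
  unique(canon[!is.na(canon)])
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

## Brute-force complete-linkage agglomeration; returns merge heights and the
## member sets at each merge, for tie-free fixtures.
oracle_complete_linkage <- function(m, metric) {
  d <- as.matrix(dist(m, method = metric))
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best_h)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

## A tip set forming one side of a genuine split (usable outgroup).
.tips_under_test <- function(tree) {
  strsplit(oracle_bipartitions(tree)[1], ",", fixed = TRUE)[[1]]
}

## A pair of tips that is NOT one side of any split (non-monophyletic
## outgroup candidate); NULL if every pair forms a cherry.
.non_split_pair <- function(tree) {
  bips <- oracle_bipartitions(tree)
  tips <- sort(tree$tip.label)
  for (p in utils::combn(tips, 2, simplify = FALSE)) {
    side <- paste(sort(p), collapse = ",")
    comp <- paste(sort(setdiff(tips, p)), collapse = ",")
    if (!(side %in% bips) && !(comp %in% bips)) return(p)
  }
  NULL
}

## Hand-built similarity graph for MCL fixtures.
make_graph <- function(nodes, edges, strain = NULL) {
  if (is.null(strain)) strain <- setNames(rep("sX", length(nodes)), nodes)
  structure(list(nodes = sort(nodes), strain = strain,
                 edges = data.frame(from = pmin(edges$from, edges$to),
                                    to = pmax(edges$from, edges$to),
                                    weight = edges$weight,
                                    stringsAsFactors = FALSE)),
            class = "sim_graph")
}

## Small in-memory gene table.
make_genes <- function(ids, strains, aa, nt = NULL, intact = NULL) {
  n <- length(ids)
  data.frame(gene_id = ids, strain = strains, contig = "c1",
             start = 0L, end = nchar(aa) * 3L, strand = "+",
             nt_seq = if (is.null(nt)) strrep("ACG", nchar(aa)) else nt,
             aa_seq = aa,
             intact = if (is.null(intact)) "intact" else intact,
             stringsAsFactors = FALSE)
}

## Presence matrix from a plain integer matrix.
as_pm <- function(m) {
  storage.mode(m) <- "integer"
  class(m) <- c("presence_matrix", class(m))
  m
}

## Shared simulated datasets, cached per (seed, args) within the session so
## acceptance blocks do not re-cluster the same data.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(sim_config(seed = seed, ...))
  .sim_cache[[key]]
}

## Full orthology pass: graph -> MCL -> og_set.
cluster_sim <- function(sim) {
  g <- build_similarity_graph(sim$genes)
  part <- mcl_cluster(g)
  clusters_to_ogs(part, sim$genes)
}
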