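## Core-gene supermatrix and distance-based phylogeny. Variable alignment
## columns of single-copy core OGs are concatenated into one sequence per
## strain; pairwise p-distances over that supermatrix feed neighbor joining.
## Neighbor joining is implemented here (rather than delegated) so that tie
## breaking and the treatment of negative branch lengths are fully
## specified: ties on the Q criterion go to the lexicographically smallest
## taxon pair, and a negative branch length is clamped to zero with the
## deficit moved to its sister branch so the joined path length is kept.

#' Select single-copy core OGs
#'
#' OGs with exactly one member (intact or pseudogene) in every strain.
#'
#' @param ogs `og_set`.
#' @return character vector of OG ids.
#' @export
select_single_copy_core <- function(ogs) {
  stopifnot(inherits(ogs, "og_set"))
  ids <- vapply(ogs$ogs, `[[`, character(1), "og_id")
  sel <- ids[vapply(ogs$ogs, `[[`, logical(1), "single_copy")]
  if (length(sel) == 0L)
    stop("no single-copy core OGs; consider laxer similarity thresholds")
  sort(sel)
}

#' Build the variable-site supermatrix ("artificial sequence")
#'
#' From per-OG aligned nucleotide blocks, columns with at least two distinct
#' residues among the strains are isolated and concatenated in (sorted OG
#' id, column index) order. Columns containing a gap or any character
#' outside A/C/G/T are skipped, so behavior on real (gapped) alignments is
#' deterministic; simulated alignments are ungapped.
#'
#' @param alignments named list: OG id -> named character vector
#'   (strain -> aligned sequence, all the same length within a block).
#' @return object of class `supermatrix`: list with `strains` (sorted),
#'   `seqs` (named concatenated variable-column strings), `provenance`
#'   (data.frame `og_id`, `column` giving each kept column's origin),
#'   `total_columns`.
#' @export
build_supermatrix <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  strains <- sort(names(alignments[[1L]]))
  for (og in names(alignments)) {
    blk <- alignments[[og]]
    if (!setequal(names(blk), strains))
      stop("strain sets differ across alignment blocks (block ", og, ")")
    if (length(unique(nchar(blk))) != 1L)
      stop("unequal row lengths in alignment block ", og)
  }
  kept <- character(length(strains))
  names(kept) <- strains
  prov_og <- character(0); prov_col <- integer(0)
  for (og in sort(names(alignments))) {
    blk <- toupper(alignments[[og]][strains])
    chars <- do.call(rbind, strsplit(blk, ""))
    ok <- apply(chars, 2L, function(col)
      all(col %in% c("A", "C", "G", "T")) && length(unique(col)) >= 2L)
    if (any(ok)) {
      idx <- which(ok)
      kept <- paste0(kept, apply(chars[, idx, drop = FALSE], 1L, paste,
                                 collapse = ""))
      prov_og <- c(prov_og, rep(og, length(idx)))
      prov_col <- c(prov_col, idx)
    }
  }
  structure(list(strains = strains, seqs = setNames(kept, strains),
                 provenance = data.frame(og_id = prov_og, column = prov_col,
                                         stringsAsFactors = FALSE),
                 total_columns = length(prov_og)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$strains), "strains x", x$total_columns,
      "variable columns from", length(unique(x$provenance$og_id)), "OGs\n")
  invisible(x)
}

#' Pairwise distance matrix over a supermatrix
#'
#' The p-distance d(i,j) is the fraction of supermatrix columns at which
#' strains i and j differ ("single nucleotide differences"); the
#' Jukes-Cantor correction -3/4 log(1 - 4p/3) is available as a model
#' switch. p-distances need not satisfy the triangle inequality; that is
#' expected and permitted.
#'
#' @param sm `supermatrix` with at least one column.
#' @param model `"p"` (default) or `"jc"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = strains.
#' @export
p_distance_matrix <- function(sm, model = c("p", "jc")) {
  model <- match.arg(model)
  if (sm$total_columns == 0L)
    stop("supermatrix has no columns; distances are undefined")
  chars <- do.call(rbind, strsplit(sm$seqs, ""))
  n <- length(sm$strains)
  d <- matrix(0, n, n, dimnames = list(sm$strains, sm$strains))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(chars[i, ] != chars[j, ])
    if (model == "jc") {
      if (p >= 0.75) stop("p-distance >= 0.75; JC correction undefined")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. At each step
#' the pair minimizing Q(i,j) = (m-2) d(i,j) - r_i - r_j is joined; ties are
#' broken toward the lexicographically smallest pair of cluster
#' representatives (each cluster is represented by its smallest leaf
#' label). Negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch. Exact on additive distances.
#'
#' @param d symmetric numeric matrix, zero diagonal, >= 2 taxa, with
#'   dimnames.
#' @return unrooted `phylo` tree (class from package ape).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d)))
    stop("d must be a matrix with taxon dimnames")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, byrow = TRUE),
               edge.length = rep(d[1L, 2L] / 2, 2L),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ## active clusters: node id (tips 1..n, internals n+1...), representative
  act_id <- seq_len(n)
  rep_lab <- labels
  D <- unname(d)
  edges <- matrix(integer(0), ncol = 2L)
  elen <- numeric(0)
  next_node <- n + 1L
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    elen <<- c(elen, len)
  }
  m <- n
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]]),
                 pmax(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]]), sep = "\r")
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, act_id[i], li)
    add_edge(u, act_id[j], lj)
    Dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], Dnew[keep]),
               c(Dnew[keep], 0))
    act_id <- c(act_id[keep], u)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    m <- m - 1L
  }
  ## final three-point join
  u <- next_node
  l1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  l2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  l3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  for (k in 1:3) add_edge(u, act_id[k], max(0, c(l1, l2, l3)[k]))
  ## renumber internal nodes to ape convention (root = n+1)
  internal <- unique(edges[, 1L])
  node_map <- integer(max(internal))
  node_map[u] <- n + 1L
  others <- setdiff(internal, u)
  node_map[others] <- n + 1L + seq_along(others)
  remap <- function(v) ifelse(v > n, node_map[v], v)
  tr <- list(edge = cbind(remap(edges[, 1L]), remap(edges[, 2L])),
             edge.length = elen, tip.label = labels,
             Nnode = length(internal))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Re-root a tree on the edge separating an outgroup
#'
#' The outgroup must form one side of a split of the unrooted tree
#' (monophyletic); the root is placed on that edge, splitting its length
#' equally. Unrooting the result reproduces the input topology.
#'
#' @param tree unrooted `phylo`.
#' @param outgroup character vector of tip labels (a proper non-empty
#'   subset of the leaves).
#' @return rooted `phylo`.
#' @export
reroot_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(outgroup %in% tips))
    stop("outgroup contains unknown tips: ",
         paste(setdiff(outgroup, tips), collapse = ", "))
  if (length(outgroup) == 0L || setequal(outgroup, tips))
    stop("outgroup must be a proper non-empty subset of the leaves")
  ## an outgroup is usable iff {outgroup | rest} is a split of the tree
  splits <- ape::prop.part(tree)
  sets <- lapply(splits, function(s) tips[s])
  og_set <- sort(outgroup)
  rest <- sort(setdiff(tips, outgroup))
  is_split <- length(outgroup) == 1L ||
    any(vapply(sets, function(s)
      setequal(s, og_set) || setequal(s, rest), logical(1)))
  if (!is_split)
    stop("outgroup {", paste(og_set, collapse = ","),
         "} is not monophyletic in the unrooted tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rooted <- ape::reorder.phylo(rooted, "cladewise")
  root_node <- rooted$edge[1L, 1L]
  re <- which(rooted$edge[, 1L] == root_node)
  if (length(re) == 2L) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions between two trees
#' on the same leaf set; 0 means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees with identical tip label sets.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Write a tree as Newick
#' @param tree `phylo`.
#' @param path output path.
#' @param digits branch length precision (default 9 decimals).
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path, digits = 9L) {
  write_atomic(path, function(tmp)
    ape::write.tree(tree, file = tmp, digits = digits))
}

#' Write a supermatrix as relaxed PHYLIP plus column provenance
#'
#' @param sm `supermatrix`.
#' @param phylip_path output path for the relaxed PHYLIP file.
#' @param provenance_path output path for the per-column provenance TSV
#'   (`og_id`, `column`); omit to skip.
#' @return invisibly, the PHYLIP path.
#' @export
write_supermatrix <- function(sm, phylip_path, provenance_path = NULL) {
  write_atomic(phylip_path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste(length(sm$strains), sm$total_columns), con)
    writeLines(paste(sm$strains, sm$seqs[sm$strains]), con)
  })
  if (!is.null(provenance_path)) write_tsv(sm$provenance, provenance_path)
  invisible(phylip_path)
}
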