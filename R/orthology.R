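## All-vs-all protein similarity graph and Markov clustering into
## orthologous groups. Local alignment is exact Smith-Waterman with affine
## gaps (BLOSUM62, open 11 / extend 1 by default): at the scale of a strain
## collection on one machine exact dynamic programming is affordable and,
## unlike a heuristic search, fully deterministic. A gap of length L costs
## gap_open + L * gap_extend.

.blosum_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_cache$BLOSUM62))
    utils::data("BLOSUM62", package = "Biostrings", envir = .blosum_cache)
  .blosum_cache$BLOSUM62
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score with affine gap penalties; symmetric in its
#' two arguments. Empty sequences score 0 by contract.
#'
#' @param a,b protein sequences (single strings over the 20-letter alphabet
#'   plus `X`, `B`, `Z` and `*`).
#' @param gap_open,gap_extend positive gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param submat substitution matrix (default BLOSUM62).
#' @return integer score (>= 0).
#' @export
sw_score <- function(a, b, gap_open = 11, gap_extend = 1, submat = NULL) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  if (is.null(submat)) submat <- .blosum62()
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "local", scoreOnly = TRUE))
}

## Self-alignment score: with an all-positive diagonal this is the sum of
## diagonal substitution scores, computed without running the DP.
.self_scores <- function(seqs, submat) {
  diag_sc <- diag(submat)
  vapply(strsplit(seqs, ""), function(ch) sum(diag_sc[ch]), numeric(1))
}

## Candidate gene pairs sharing at least `min_shared` k-mers. A seeding
## prescreen only: every surviving pair is still scored exactly, so the
## screen affects speed, not which edges pass the thresholds, for any pair
## of sequences sharing k-mers (homologs at the divergences handled here
## always do).
.kmer_candidate_pairs <- function(seqs, k = 4L, min_shared = 1L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  idx <- split(rep(seq_len(n), lengths(kmers)), unlist(kmers))
  pair_keys <- unlist(lapply(idx, function(g) {
    if (length(g) < 2L) return(integer(0))
    p <- combn(sort(g), 2L)
    (p[1L, ] - 1L) * n + p[2L, ]
  }), use.names = FALSE)
  if (!length(pair_keys)) return(matrix(integer(0), ncol = 2L))
  tab <- tabulate(pair_keys)
  keys <- which(tab >= min_shared)
  cbind(((keys - 1L) %/% n) + 1L, ((keys - 1L) %% n) + 1L)
}

#' Build an all-vs-all protein similarity graph
#'
#' Every pair of genes is scored by exact local alignment; the edge weight
#' is the score normalized by the smaller of the two self-alignment scores,
#' so weights lie in (0, 1] and identical proteins get weight 1. An edge is
#' kept when the weight reaches `min_norm_score` and the alignment covers at
#' least `min_coverage` of the shorter sequence. A k-mer seeding prescreen
#' (shared k-mer count) skips pairs that cannot reach the thresholds.
#'
#' @param genes gene data.frame as from [read_gene_fasta()] (columns
#'   `gene_id`, `strain`, `aa_seq` are used).
#' @param min_norm_score minimum normalized score for an edge, in (0, 1].
#' @param min_coverage minimum aligned fraction of the shorter sequence.
#' @param gap_open,gap_extend affine gap costs, see [sw_score()].
#' @param kmer_k,min_shared_kmers prescreen parameters; set
#'   `min_shared_kmers = 0` to disable the prescreen and score all pairs.
#' @return object of class `sim_graph`: list with `nodes` (gene ids, sorted),
#'   `strain` (named vector node -> strain), `edges` (data.frame `from`,
#'   `to`, `weight`).
#' @export
build_similarity_graph <- function(genes, min_norm_score = 0.4,
                                   min_coverage = 0.5,
                                   gap_open = 11, gap_extend = 1,
                                   kmer_k = 4L, min_shared_kmers = 1L) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  o <- order(genes$gene_id)
  ids <- genes$gene_id[o]
  seqs <- toupper(genes$aa_seq[o])
  strain <- setNames(genes$strain[o], ids)
  n <- length(ids)
  submat <- .blosum62()
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  if (n >= 2L) {
    if (min_shared_kmers > 0L) {
      cand <- .kmer_candidate_pairs(seqs, k = kmer_k,
                                    min_shared = min_shared_kmers)
    } else {
      cand <- t(combn(n, 2L))
    }
    if (nrow(cand)) {
      self <- .self_scores(seqs, submat)
      len <- nchar(seqs)
      keep_from <- character(0); keep_to <- character(0); keep_w <- numeric(0)
      aa <- Biostrings::AAStringSet(seqs)
      for (i in sort(unique(cand[, 1L]))) {
        js <- cand[cand[, 1L] == i, 2L]
        aln <- Biostrings::pairwiseAlignment(
          aa[js], aa[[i]], substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_extend, type = "local")
        sc <- Biostrings::score(aln)
        w <- pmin(sc / pmin(self[i], self[js]), 1)
        ## aligned span on the shorter of the two sequences
        span_j <- Biostrings::width(Biostrings::pattern(aln)) -
          Biostrings::nindel(aln)@insertion[, "WidthSum"]
        span_i <- Biostrings::width(Biostrings::subject(aln)) -
          Biostrings::nindel(aln)@deletion[, "WidthSum"]
        span_short <- ifelse(len[js] <= len[i], span_j, span_i)
        cov <- span_short / pmin(len[i], len[js])
        ok <- w >= min_norm_score & cov >= min_coverage & sc > 0
        if (any(ok)) {
          keep_from <- c(keep_from, rep(ids[i], sum(ok)))
          keep_to <- c(keep_to, ids[js[ok]])
          keep_w <- c(keep_w, w[ok])
        }
      }
      edges <- data.frame(from = pmin(keep_from, keep_to),
                          to = pmax(keep_from, keep_to),
                          weight = keep_w, stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = ids, strain = strain, edges = edges),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat("similarity graph:", length(x$nodes), "genes,",
      nrow(x$edges), "edges,",
      length(unique(x$strain)), "strains\n")
  invisible(x)
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Classical MCL on the column-stochastic transition matrix of the weighted
#' graph: alternate expansion (matrix squaring) and inflation (element-wise
#' power `inflation` followed by column renormalization), pruning entries
#' below `prune_threshold`, until the matrix changes by less than `tol` or
#' `max_iter` is reached. Self-loops with the maximum incident edge weight
#' (at least 1e-6) are added before normalization. Clusters are the weakly
#' connected components of the non-zero structure of the limit matrix, so
#' the result is always a partition of the nodes and never merges
#' disconnected components of the input graph.
#'
#' @param graph `sim_graph` from [build_similarity_graph()].
#' @param inflation inflation exponent, > 1; larger values give finer
#'   clusters.
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iter iteration cap; on hitting it the current partition is
#'   returned with a warning.
#' @param tol convergence tolerance on the maximum absolute entry change.
#' @return list of character vectors (the clusters), each sorted, ordered by
#'   their smallest member; attribute `iterations` records the number of
#'   iterations run.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune_threshold = 1e-5,
                        max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(graph, "sim_graph"), inflation > 1)
  ids <- graph$nodes
  n <- length(ids)
  if (n == 0L) stop("empty graph")
  e <- graph$edges
  i <- c(match(e$from, ids), match(e$to, ids))
  j <- c(match(e$to, ids), match(e$from, ids))
  w <- c(e$weight, e$weight)
  ## self-loops: max incident weight, floor 1e-6
  loop <- rep(1e-6, n)
  if (length(w)) {
    mx <- tapply(w, i, max)
    loop[as.integer(names(mx))] <- pmax(loop[as.integer(names(mx))], mx)
  }
  A <- Matrix::sparseMatrix(i = c(i, seq_len(n)), j = c(j, seq_len(n)),
                            x = c(w, loop), dims = c(n, n))
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    zero <- cs == 0
    if (any(zero)) {            # resurrect emptied columns as identity
      M <- M + Matrix::sparseMatrix(i = which(zero), j = which(zero),
                                    x = 1, dims = dim(M))
      cs <- Matrix::colSums(M)
    }
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(A)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- M %*% M
    E <- as(E, "CsparseMatrix")
    E@x <- E@x^inflation
    E@x[E@x < prune_threshold] <- 0
    E <- Matrix::drop0(E)
    E <- normalize(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current partition")
  S <- (M != 0) | Matrix::t(M != 0)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  cl <- split(ids, comp)
  cl <- lapply(cl, sort)
  cl <- unname(cl[order(vapply(cl, `[`, character(1), 1L))])
  attr(cl, "iterations") <- it
  cl
}

#' Turn a gene partition into orthologous groups
#'
#' One OG per cluster. The per-strain state is `present` when the strain has
#' at least one intact member, `pseudo` when it has members but all are
#' pseudogenes, and `absent` otherwise. `single_copy` is true when every
#' strain of the collection has exactly one member. OG ids are assigned in
#' the order of each cluster's smallest gene id, so they are deterministic.
#'
#' @param partition list of character vectors of gene ids (a partition of
#'   `genes$gene_id`, e.g. from [mcl_cluster()]).
#' @param genes gene data.frame (columns `gene_id`, `strain`, `intact`).
#' @param strains character vector of all strain ids in the collection;
#'   defaults to the strains present in `genes`.
#' @return object of class `og_set`: list with `strains` and `ogs`, the
#'   latter a list of OGs, each a list with `og_id`, `members` (named list
#'   strain -> gene ids), `state` (named vector over all strains),
#'   `single_copy`.
#' @export
clusters_to_ogs <- function(partition, genes,
                            strains = sort(unique(genes$strain))) {
  all_genes <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_genes) || !setequal(all_genes, genes$gene_id))
    stop("partition must cover every gene exactly once")
  g_strain <- setNames(genes$strain, genes$gene_id)
  g_intact <- setNames(genes$intact, genes$gene_id)
  if (!all(g_strain %in% strains))
    stop("genes reference strains not in the strain list")
  partition <- partition[order(vapply(partition, min, character(1)))]
  ndig <- max(4L, nchar(length(partition)))
  ogs <- lapply(seq_along(partition), function(k) {
    mem_ids <- sort(partition[[k]])
    members <- split(mem_ids, g_strain[mem_ids])
    state <- setNames(rep("absent", length(strains)), strains)
    for (s in names(members)) {
      state[s] <- if (any(g_intact[members[[s]]] == "intact"))
        "present" else "pseudo"
    }
    list(og_id = sprintf("OG%0*d", ndig, k),
         members = members,
         state = state,
         single_copy = length(members) == length(strains) &&
           all(lengths(members) == 1L))
  })
  structure(list(strains = strains, ogs = ogs), class = "og_set")
}

#' @export
print.og_set <- function(x, ...) {
  sc <- sum(vapply(x$ogs, `[[`, logical(1), "single_copy"))
  cat("og_set:", length(x$ogs), "orthologous groups over",
      length(x$strains), "strains (", sc, "single-copy core )\n")
  invisible(x)
}

#' Write an orthologous-group table
#'
#' TSV with one row per OG: `og_id`, then one column per strain holding a
#' comma-separated gene list, with pseudogene members prefixed `pseudo:`,
#' or `-` for absence.
#'
#' @param ogs `og_set` from [clusters_to_ogs()].
#' @param genes gene data.frame (for the intact flag of each member).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_og_table <- function(ogs, genes, path) {
  g_intact <- setNames(genes$intact, genes$gene_id)
  rows <- lapply(ogs$ogs, function(og) {
    cells <- vapply(ogs$strains, function(s) {
      m <- og$members[[s]]
      if (is.null(m)) return("-")
      paste(ifelse(g_intact[m] == "pseudo", paste0("pseudo:", m), m),
            collapse = ",")
    }, character(1))
    c(og$og_id, cells)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("og_id", ogs$strains)
  write_tsv(df, path)
}

#' Read an orthologous-group table written by [write_og_table()]
#'
#' @param path path to the OG table TSV.
#' @return `og_set`, with states and single-copy flags reconstructed from
#'   the table cells.
#' @export
read_og_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  strains <- setdiff(names(x), "og_id")
  intact_flags <- character(0)
  ogs <- lapply(seq_len(nrow(x)), function(k) {
    members <- list(); state <- setNames(rep("absent", length(strains)),
                                         strains)
    for (s in strains) {
      cell <- x[[s]][k]
      if (cell == "-") next
      toks <- strsplit(cell, ",", fixed = TRUE)[[1L]]
      pseudo <- startsWith(toks, "pseudo:")
      ids <- sub("^pseudo:", "", toks)
      members[[s]] <- ids
      intact_flags[ids] <<- ifelse(pseudo, "pseudo", "intact")
      state[s] <- if (all(pseudo)) "pseudo" else "present"
    }
    list(og_id = x$og_id[k], members = members, state = state,
         single_copy = length(members) == length(strains) &&
           all(lengths(members) == 1L))
  })
  structure(list(strains = strains, ogs = ogs), class = "og_set",
            gene_intact = intact_flags)
}

#' Per-gene intactness flags recorded in an OG table
#'
#' @param ogs `og_set` read back from disk by [read_og_table()].
#' @return named character vector gene_id -> "intact"/"pseudo".
#' @export
og_gene_intact <- function(ogs) {
  attr(ogs, "gene_intact")
}
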