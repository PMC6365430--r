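## Pseudogene-aware gene-trait matching. A pseudogene is an intermediate
## state between presence and absence: for scoring it is neutral (it is
## compatible with either class and contributes no error), while distance
## computations for heatmap ordering encode it numerically as 0.5.

## Validate a label vector against a presence matrix / state vector and
## return list(classes, labels-without-missing).
.check_labels <- function(labels, strains) {
  labels <- labels[strains]
  names(labels) <- strains
  obs <- labels[!is.na(labels)]
  classes <- sort(unique(obs))
  if (length(classes) != 2L)
    stop("need exactly two label classes, got: ",
         paste(classes, collapse = ", "))
  n_per <- table(obs)
  if (any(n_per < 2L))
    stop("each class needs at least 2 strains (",
         paste(names(n_per), n_per, sep = "=", collapse = ", "), ")")
  list(classes = classes, labels = labels)
}

#' Discrimination score of one OG for a binary trait
#'
#' For the orientation "presence predicts class A", the errors are the
#' strains of class B with the OG present plus the strains of class A with
#' it absent; the other orientation swaps the classes. Pseudogene cells are
#' neutral: they are compatible with either state and contribute no error,
#' and they are excluded from the denominator. The score is
#' `1 - min(errors)/n_scored`; orientation ties go to "present->A" (A being
#' the alphabetically first class).
#'
#' @param states per-strain states: named vector, either codes 0/1/2 or
#'   "absent"/"pseudo"/"present".
#' @param labels named vector of class labels (NA = missing).
#' @return list with `score` in `[0, 1]`, `orientation` ("present->A" form,
#'   naming the class that presence predicts), `n_pseudo_neutral`,
#'   `n_scored`.
#' @export
og_trait_score <- function(states, labels) {
  if (is.character(states))
    states <- c(absent = 0L, pseudo = 1L, present = 2L)[states]
  chk <- .check_labels(labels, names(states))
  lab <- chk$labels; cls <- chk$classes
  use <- !is.na(lab)
  s <- states[use]; l <- lab[use]
  pseudo <- s == STATE_PSEUDO
  n_pseudo <- sum(pseudo)
  s <- s[!pseudo]; l <- l[!pseudo]
  n_scored <- length(s)
  errA <- sum(s == STATE_PRESENT & l == cls[2L]) +
    sum(s == STATE_ABSENT & l == cls[1L])
  errB <- sum(s == STATE_PRESENT & l == cls[1L]) +
    sum(s == STATE_ABSENT & l == cls[2L])
  score <- if (n_scored == 0L) 1 else 1 - min(errA, errB) / n_scored
  list(score = score,
       orientation = paste0("present->", if (errA <= errB) cls[1L] else
         cls[2L]),
       n_pseudo_neutral = n_pseudo,
       n_scored = n_scored)
}

## Vectorized scores for all OGs of a presence matrix under one label
## vector. Returns matrix with rows score/errA/errB, plus counts.
.score_all_ogs <- function(pm, lab, cls) {
  use <- !is.na(lab)
  m <- unclass(pm)[use, , drop = FALSE]
  l <- lab[use]
  isP <- m == STATE_PRESENT
  isA <- m == STATE_ABSENT
  inA <- l == cls[1L]
  errA <- colSums(isP & !inA) + colSums(isA & inA)
  errB <- colSums(isP & inA) + colSums(isA & !inA)
  n_scored <- colSums(m != STATE_PSEUDO)
  score <- ifelse(n_scored == 0L, 1, 1 - pmin(errA, errB) / n_scored)
  list(score = score, errA = errA, errB = errB,
       n_pseudo = colSums(m == STATE_PSEUDO), n_scored = n_scored)
}

#' Rank OGs by trait discrimination with a permutation null
#'
#' Scores every OG against the labels, then estimates per-OG permutation
#' p-values by rescoring under `n_perm` random label permutations (the same
#' permuted vector is applied to all OGs in a replicate, preserving the
#' between-OG correlation structure):
#' `p = (1 + #{permutations with score >= observed}) / (n_perm + 1)`.
#' Benjamini-Hochberg q-values are computed over all tested OGs.
#'
#' @param pm `presence_matrix`.
#' @param labels named vector of class labels (NA = missing).
#' @param n_perm number of label permutations (>= 99).
#' @param seed RNG seed.
#' @return data.frame sorted by (score desc, p_perm asc, og_id) with columns
#'   `og_id`, `score`, `orientation`, `p_perm`, `q_bh`, `n_pseudo_neutral`.
#' @export
rank_discriminating_ogs <- function(pm, labels, n_perm = 999L, seed = NULL) {
  stopifnot(n_perm >= 99L)
  chk <- .check_labels(labels, rownames(pm))
  lab <- chk$labels; cls <- chk$classes
  obs <- .score_all_ogs(pm, lab, cls)
  exceed <- integer(ncol(pm))
  with_seed(seed, {
    idx <- which(!is.na(lab))
    for (b in seq_len(n_perm)) {
      perm <- lab
      perm[idx] <- lab[sample(idx)]
      ps <- .score_all_ogs(pm, perm, cls)$score
      exceed <- exceed + (ps >= obs$score - 1e-12)
    }
  })
  p_perm <- (1 + exceed) / (n_perm + 1)
  orientation <- paste0("present->",
                        ifelse(obs$errA <= obs$errB, cls[1L], cls[2L]))
  res <- data.frame(og_id = colnames(pm), score = obs$score,
                    orientation = orientation, p_perm = p_perm,
                    q_bh = p.adjust(p_perm, method = "BH"),
                    n_pseudo_neutral = obs$n_pseudo,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$p_perm, res$og_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Leave-one-out trait prediction from selected OGs
#'
#' Each held-out strain is classified by majority vote of the selected OGs:
#' each OG's orientation is re-fit on the training strains, presence votes
#' for the class its orientation predicts, absence for the other, and a
#' pseudogene abstains. Vote ties, and strains for which every OG abstains
#' (logged as a warning), go to the alphabetically first class.
#'
#' @param pm `presence_matrix`.
#' @param labels named vector of class labels (NA = missing strains are
#'   skipped).
#' @param selected_ogs character vector of OG ids to vote (>= 1).
#' @return list with `predicted` (named vector over labeled strains) and
#'   `error_rate`.
#' @export
loo_predict <- function(pm, labels, selected_ogs) {
  if (length(selected_ogs) == 0L) stop("need at least one selected OG")
  missing_ogs <- setdiff(selected_ogs, colnames(pm))
  if (length(missing_ogs))
    stop("unknown OG id(s): ", paste(missing_ogs, collapse = ", "))
  chk <- .check_labels(labels, rownames(pm))
  lab <- chk$labels; cls <- chk$classes
  strains <- names(lab)[!is.na(lab)]
  sub <- unclass(pm)[, selected_ogs, drop = FALSE]
  predicted <- setNames(character(length(strains)), strains)
  for (s in strains) {
    train <- setdiff(strains, s)
    l <- lab[train]
    m <- sub[train, , drop = FALSE]
    inA <- l == cls[1L]
    errA <- colSums(m == STATE_PRESENT & !inA) +
      colSums(m == STATE_ABSENT & inA)
    errB <- colSums(m == STATE_PRESENT & inA) +
      colSums(m == STATE_ABSENT & !inA)
    pres_class <- ifelse(errA <= errB, cls[1L], cls[2L])
    abs_class <- ifelse(errA <= errB, cls[2L], cls[1L])
    st <- sub[s, ]
    vote <- ifelse(st == STATE_PRESENT, pres_class,
                   ifelse(st == STATE_ABSENT, abs_class, NA))
    vote <- vote[!is.na(vote)]
    if (length(vote) == 0L) {
      warning("all OGs abstain for strain ", s, "; defaulting to ",
              cls[1L])
      predicted[s] <- cls[1L]
    } else {
      nA <- sum(vote == cls[1L]); nB <- length(vote) - nA
      predicted[s] <- if (nA >= nB) cls[1L] else cls[2L]
    }
  }
  list(predicted = predicted,
       error_rate = mean(predicted != lab[strains]))
}

#' Length-based pseudogene calls within OGs
#'
#' Within each OG of at least 3 members, a member is (re)called a pseudogene
#' when its protein is shorter than `length_fraction` times the median
#' intact-member protein length, or when it already carries an internal
#' stop. Smaller OGs keep their stop-codon-based flags untouched, as a
#' median over fewer than 3 members is not meaningful.
#'
#' @param genes gene data.frame (columns `gene_id`, `aa_seq`, `intact`).
#' @param partition list of gene-id clusters (an OG partition).
#' @param length_fraction truncation threshold as a fraction of the median
#'   intact protein length.
#' @return the gene data.frame with the `intact` column updated.
#' @export
call_pseudogenes <- function(genes, partition, length_fraction = 0.8) {
  intact <- setNames(genes$intact, genes$gene_id)
  len <- setNames(nchar(sub("\\*$", "", genes$aa_seq)), genes$gene_id)
  for (cl in partition) {
    if (length(cl) < 3L) next
    ref <- cl[intact[cl] == "intact"]
    if (length(ref) == 0L) next
    med <- median(len[ref])
    short <- cl[len[cl] < length_fraction * med]
    intact[short] <- "pseudo"
  }
  genes$intact <- unname(intact[genes$gene_id])
  genes
}

#' Order heatmap rows by hierarchical clustering
#'
#' Complete-linkage agglomerative clustering of the rows of a tri-state
#' matrix under the Manhattan or Euclidean metric, with cells encoded
#' absent = 0, pseudogene = 0.5, present = 1. To order columns, pass the
#' transposed matrix.
#'
#' @param pm `presence_matrix` (or any 0/1/2 integer matrix).
#' @param metric `"manhattan"` or `"euclidean"`.
#' @return list with `order` (row labels in dendrogram order) and `hclust`
#'   (the stats::hclust object).
#' @export
heatmap_order <- function(pm, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  m <- unclass(pm) / 2
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  hc <- hclust(dist(m, method = metric), method = "complete")
  list(order = rownames(m)[hc$order], hclust = hc)
}

#' The "most discriminating" OG set for heatmap display
#'
#' All OGs with a perfect score when any exist, otherwise the top `k` by
#' rank.
#'
#' @param results data.frame from [rank_discriminating_ogs()].
#' @param k fallback size when no OG scores 1.
#' @return character vector of OG ids.
#' @export
top_discriminating_ogs <- function(results, k = 50L) {
  perfect <- results$og_id[results$score >= 1 - 1e-12]
  if (length(perfect)) perfect else
    utils::head(results$og_id, k)
}
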