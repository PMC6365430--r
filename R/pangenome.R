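## Tri-state presence matrix and pan/core rarefaction. Cells are coded
## 0 = absent, 1 = pseudogene, 2 = present; pseudogenes count as non-absent
## for pan/core membership (OG counting precedes intactness filtering), with
## an intact-only switch where it matters.

#' Build the strains x OGs presence matrix
#'
#' @param ogs `og_set` from [clusters_to_ogs()].
#' @return integer matrix (class `presence_matrix`), rows = strains, columns
#'   = OGs (both sorted), cells 0 (absent), 1 (pseudogene), 2 (present).
#' @export
build_presence_matrix <- function(ogs) {
  stopifnot(inherits(ogs, "og_set"))
  strains <- sort(ogs$strains)
  og_ids <- vapply(ogs$ogs, `[[`, character(1), "og_id")
  o <- order(og_ids)
  m <- matrix(STATE_ABSENT, nrow = length(strains), ncol = length(og_ids),
              dimnames = list(strains, og_ids[o]))
  code <- c(absent = STATE_ABSENT, pseudo = STATE_PSEUDO,
            present = STATE_PRESENT)
  for (og in ogs$ogs[o]) {
    m[names(og$state), og$og_id] <- code[og$state]
  }
  if (any(colSums(m != STATE_ABSENT) == 0L))
    stop("every OG must be non-absent in at least one strain")
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Pan- and core-genome rarefaction curves
#'
#' For each random ordering of the strains, pan(k) counts OGs non-absent in
#' at least one of the first k strains and core(k) counts OGs non-absent in
#' all of them; means and standard deviations are taken over orderings.
#' With `exhaustive = TRUE` all N! orderings are enumerated instead of
#' sampled (N <= 8).
#'
#' @param pm `presence_matrix`.
#' @param n_permutations number of sampled strain orderings (>= 1).
#' @param seed RNG seed (required for sampled orderings; reproducible).
#' @param exhaustive enumerate all orderings instead of sampling.
#' @return data.frame with columns `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`; attributes `n_permutations` and `seed`. The attribute
#'   `plateau_k` reports the first k at which the mean pan increment drops
#'   below 0.5% of the total OG count (NA if never), a descriptive analogue
#'   of the curve "leveling off".
#' @export
pan_core_curves <- function(pm, n_permutations = 500L, seed = NULL,
                            exhaustive = FALSE) {
  nonabs <- unclass(pm) != STATE_ABSENT
  n <- nrow(nonabs)
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration is limited to 8 strains")
    orders <- all_permutations(n)
  } else {
    stopifnot(n_permutations >= 1L)
    if (is.null(seed)) stop("seed is required for sampled orderings")
    orders <- with_seed(seed, replicate(n_permutations, sample.int(n),
                                        simplify = FALSE))
  }
  pan <- matrix(0L, nrow = length(orders), ncol = n)
  core <- matrix(0L, nrow = length(orders), ncol = n)
  for (r in seq_along(orders)) {
    o <- orders[[r]]
    any_acc <- rep(FALSE, ncol(nonabs))
    all_acc <- rep(TRUE, ncol(nonabs))
    for (k in seq_len(n)) {
      row <- nonabs[o[k], ]
      any_acc <- any_acc | row
      all_acc <- all_acc & row
      pan[r, k] <- sum(any_acc)
      core[r, k] <- sum(all_acc)
    }
  }
  res <- data.frame(
    k = seq_len(n),
    pan_mean = colMeans(pan),
    pan_sd = apply(pan, 2L, sd),
    core_mean = colMeans(core),
    core_sd = apply(core, 2L, sd)
  )
  inc <- diff(res$pan_mean)
  plateau <- which(inc < 0.005 * ncol(nonabs))
  attr(res, "n_permutations") <- length(orders)
  attr(res, "seed") <- seed
  attr(res, "plateau_k") <- if (length(plateau)) plateau[1L] + 1L else
    NA_integer_
  res
}

#' Core, group-unique and group-pangenome OG sets
#'
#' @param pm `presence_matrix`.
#' @param group character vector of strain ids (non-empty subset of rows).
#' @param require_intact when TRUE, core membership requires the `present`
#'   state in every group member (a pseudogene breaks coreness); otherwise
#'   any non-absent state counts.
#' @return list with `core` (OG ids non-absent, or intact, in every group
#'   member), `unique_to_group` (OG ids non-absent in the group and absent
#'   in every non-member), `group_pan_size` (OG count non-absent in >= 1
#'   group member).
#' @export
core_and_group_ogs <- function(pm, group, require_intact = FALSE) {
  if (length(group) == 0L) stop("group must be non-empty")
  unknown <- setdiff(group, rownames(pm))
  if (length(unknown))
    stop("unknown strain(s) in group: ", paste(unknown, collapse = ", "))
  m <- unclass(pm)
  gm <- m[group, , drop = FALSE]
  others <- m[setdiff(rownames(m), group), , drop = FALSE]
  core_state <- if (require_intact) STATE_PRESENT else STATE_PSEUDO
  core <- colnames(m)[colSums(gm >= core_state) == length(group)]
  in_group <- colSums(gm != STATE_ABSENT) >= 1L
  out_group <- colSums(others != STATE_ABSENT) >= 1L
  list(core = core,
       unique_to_group = colnames(m)[in_group & !out_group],
       group_pan_size = sum(in_group))
}

#' Write a presence matrix as TSV
#'
#' Cells are written `0` (absent), `P` (pseudogene), `1` (present); rows are
#' strains.
#'
#' @param pm `presence_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  chr <- matrix(c("0", "P", "1")[unclass(pm) + 1L], nrow = nrow(pm),
                dimnames = dimnames(pm))
  df <- data.frame(strain = rownames(chr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a presence matrix written by [write_presence_matrix()]
#' @param path path to the TSV.
#' @return `presence_matrix`.
#' @export
read_presence_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  strains <- x$strain
  x$strain <- NULL
  m <- matrix(match(as.matrix(x), c("0", "P", "1")) - 1L,
              nrow = length(strains),
              dimnames = list(strains, names(x)))
  if (anyNA(m)) stop("presence matrix cells must be 0, P or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Write rarefaction curves as TSV
#' @param curves data.frame from [pan_core_curves()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_curves <- function(curves, path) {
  write_tsv(curves, path)
}
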