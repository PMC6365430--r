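## Seeded simulator: a strain collection with a known phylogeny, two
## "subspecies" clades, a pseudogene-eroded subclade (the dairy cremoris
## phenotype analogue), clade- and niche-specific accessory marker OGs, and
## plasmid contigs at elevated sequencing coverage. Every pipeline stage can
## be checked against the planted ground truth. Core genes evolve by
## Jukes-Cantor substitution; accessory gene sequences are drawn unrelated
## so the similarity graph separates them without tuning.

.stop_codons <- c("TAA", "TAG", "TGA")
.bases <- c("A", "C", "G", "T")

## Random in-frame coding sequence without stop codons.
.random_cds <- function(length_bp) {
  stopifnot(length_bp %% 3 == 0)
  s <- sample(.bases, length_bp, replace = TRUE)
  repeat {
    codons <- paste0(s[c(TRUE, FALSE, FALSE)], s[c(FALSE, TRUE, FALSE)],
                     s[c(FALSE, FALSE, TRUE)])
    bad <- which(codons %in% .stop_codons)
    if (!length(bad)) break
    for (b in bad) s[3 * b - 2] <- sample(.bases, 1L)
  }
  paste(s, collapse = "")
}

.translate_cds <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(gc[codons], collapse = "")
}

#' Simulate a Yule strain phylogeny
#'
#' Pure-birth topology (a uniformly chosen leaf splits until `n` leaves
#' exist) with independent shifted-exponential branch lengths
#' (`min_branch + Exp(1)`) rescaled so the deepest root-to-tip path has
#' length 1. The shift keeps every edge long enough to leave a sequence
#' footprint at realistic rates; an exactly-zero internal edge would make
#' the planted topology statistically unidentifiable no matter the
#' inference method. The two sides of the first split
#' define the clade labels "A" (the side holding the alphabetically first
#' strain) and "B", the analogue of the two subspecies; for `n >= 4` the
#' topology is conditioned (by resampling) on both sides holding at least
#' two leaves, so that each "subspecies" is represented by a scorable
#' class.
#'
#' @param n number of strains (>= 2).
#' @param seed RNG seed (NULL = use current RNG state).
#' @param min_branch lower bound of each branch before depth normalization,
#'   in units of the unit-mean exponential draw.
#' @return rooted `phylo` with tips `s01`, `s02`, ... and attribute
#'   `clades`, a named "A"/"B" vector over the tips.
#' @export
simulate_tree <- function(n, seed = NULL, min_branch = 0.25) {
  if (n < 2L) stop("need at least 2 strains")
  min_side <- if (n >= 4L) 2L else 1L
  with_seed(seed, {
    repeat {
      parent <- c(NA_integer_, 1L, 1L)
      is_leaf <- c(FALSE, TRUE, TRUE)
      while (sum(is_leaf) < n) {
        leaves <- which(is_leaf)
        split <- leaves[sample.int(length(leaves), 1L)]
        is_leaf[split] <- FALSE
        parent <- c(parent, split, split)
        is_leaf <- c(is_leaf, TRUE, TRUE)
      }
      ## leaves descending from the root's two children
      anc2 <- sum(vapply(which(is_leaf), function(v) {
        while (parent[v] > 1L) v <- parent[v]
        v == 2L
      }, logical(1)))
      if (min(anc2, n - anc2) >= min_side) break
    }
    nn <- length(parent)
    elen <- setNames(min_branch + rexp(nn - 1L), as.character(2:nn))
    depth <- numeric(nn)
    for (v in 2:nn) depth[v] <- depth[parent[v]] + elen[as.character(v)]
    scale <- 1 / max(depth[is_leaf])
    leaves <- which(is_leaf)
    internals <- c(1L, setdiff(which(!is_leaf), 1L))
    ntip <- length(leaves)
    node_map <- integer(nn)
    node_map[leaves] <- seq_len(ntip)
    node_map[internals] <- ntip + seq_along(internals)
    edge <- cbind(node_map[parent[2:nn]], node_map[2:nn])
    tr <- list(edge = edge, edge.length = unname(elen) * scale,
               tip.label = sprintf("s%02d", seq_len(ntip)), Nnode = nn - ntip)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    kids <- tr$edge[tr$edge[, 1L] == ntip + 1L, 2L]
    side1 <- .tips_under(tr, kids[1L])
    side2 <- .tips_under(tr, kids[2L])
    if (min(side2) < min(side1)) { tmp <- side1; side1 <- side2; side2 <- tmp }
    clades <- setNames(ifelse(tr$tip.label %in% side1, "A", "B"),
                       tr$tip.label)
    attr(tr, "clades") <- clades
    tr
  })
}

## Tip labels below a node.
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .tips_under, tree = tree))
}

#' Evolve gene sequences along a tree by Jukes-Cantor substitution
#'
#' The root carries uniform random in-frame sequences free of stop codons;
#' along a branch of length d every site substitutes with probability
#' p = 3/4 (1 - exp(-4 d rate / 3)), the new base uniform among the other
#' three, and substitutions creating stop codons are resampled.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_genes number of genes.
#' @param length_bp gene length (multiple of 3).
#' @param rate expected substitutions per site over one unit of branch
#'   length (i.e. over the total tree depth when the tree is unit-depth).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return list of length `n_genes`; element g is a named character vector
#'   (tip label -> sequence).
#' @export
evolve_sequences <- function(tree, n_genes, length_bp, rate, seed = NULL) {
  stopifnot(length_bp %% 3 == 0, rate >= 0, n_genes >= 1)
  with_seed(seed, {
    total <- n_genes * length_bp
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- strsplit(.random_cds(total), "")[[1L]]
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      seqs[[child]] <- .mutate_jc(seqs[[par]], tr$edge.length[e] * rate)
    }
    lapply(seq_len(n_genes), function(g) {
      span <- ((g - 1L) * length_bp + 1L):(g * length_bp)
      setNames(vapply(seq_len(ntip), function(t)
        paste(seqs[[t]][span], collapse = ""), character(1)),
        tr$tip.label)
    })
  })
}

## One JC branch on a character vector of bases; in-frame, stop codons are
## resampled.
.mutate_jc <- function(s, d) {
  if (d <= 0) return(s)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(s)) < p)
  if (!length(hit)) return(s)
  out <- s
  for (i in hit) out[i] <- sample(setdiff(.bases, s[i]), 1L)
  repeat {
    cod_start <- 3 * (unique((hit - 1L) %/% 3L)) + 1L
    codons <- paste0(out[cod_start], out[cod_start + 1L], out[cod_start + 2L])
    bad <- cod_start[codons %in% .stop_codons]
    if (!length(bad)) break
    for (cs in bad) {
      in_codon <- intersect(hit, cs:(cs + 2L))
      i <- in_codon[1L]              # at least one hit site made the stop
      out[i] <- sample(setdiff(.bases, s[i]), 1L)
    }
  }
  out
}

#' Simulator configuration
#'
#' Defaults describe the standard validation scenario: 12 strains, 30 core
#' OGs of 300 bp, substitution rate 0.05 expected substitutions/site over
#' the unit tree depth, 3 clade and 3 niche marker OGs, pseudogenization of
#' 30% of (strain, core OG) pairs inside the pseudogene-eroded subclade,
#' and 5 plasmid OGs on dedicated contigs at 5x chromosomal coverage.
#'
#' @param n_strains number of strains (>= 4 for a meaningful subclade).
#' @param seed mandatory RNG seed for the whole dataset.
#' @param n_core_ogs single-copy core OGs evolving along the tree.
#' @param gene_length_bp gene length, a multiple of 3.
#' @param subst_rate expected substitutions/site over the unit tree depth.
#' @param n_clade_markers accessory OGs carried by exactly one clade.
#' @param n_niche_markers accessory OGs carried by exactly the dairy
#'   strains.
#' @param pseudo_clade tip labels of the pseudogene-eroded subclade; NULL
#'   picks the smaller child subtree inside clade A.
#' @param pseudo_fraction fraction of (pseudo-clade strain, core OG) pairs
#'   whose member is truncated, in `[0, 1]`.
#' @param niche_crossover fraction of strains outside the pseudo-clade that
#'   are labeled dairy anyway (dairy "lactis" analogues).
#' @param plasmid_strains tip labels carrying the plasmid; NULL = the dairy
#'   strains.
#' @param n_plasmid_ogs OGs on the plasmid contig.
#' @param coverage_multiplier plasmid contig depth relative to the
#'   chromosome (>= 1).
#' @param base_depth chromosomal mean read depth.
#' @param depth_noise multiplicative depth noise (sd as a fraction of the
#'   mean; 0 = noiseless).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 12L, seed, n_core_ogs = 30L,
                       gene_length_bp = 300L, subst_rate = 0.05,
                       n_clade_markers = 3L, n_niche_markers = 3L,
                       pseudo_clade = NULL, pseudo_fraction = 0.3,
                       niche_crossover = 0.25, plasmid_strains = NULL,
                       n_plasmid_ogs = 5L, coverage_multiplier = 5,
                       base_depth = 50, depth_noise = 0) {
  stopifnot(n_strains >= 2L, n_core_ogs >= 1L, gene_length_bp %% 3 == 0,
            subst_rate >= 0, n_clade_markers >= 0L, n_niche_markers >= 0L,
            pseudo_fraction >= 0, pseudo_fraction <= 1,
            niche_crossover >= 0, niche_crossover <= 1,
            n_plasmid_ogs >= 0L, coverage_multiplier >= 1,
            base_depth > 0, depth_noise >= 0)
  if (missing(seed)) stop("a seed is mandatory")
  structure(as.list(environment()), class = "sim_config")
}

#' Plant clade/niche/plasmid structure onto a simulated tree
#'
#' Assigns the "subspecies" clades from the first split, chooses the
#' pseudogene-eroded subclade and the dairy niche (the subclade plus a
#' crossover fraction of the remaining strains), plants marker OGs whose
#' presence vectors equal the clade and niche indicators exactly, selects
#' the plasmid carriers, and draws the pseudogenized (strain, core OG)
#' pairs with their truncation fractions (uniform 30-70% of the protein).
#'
#' @param config `sim_config`.
#' @param tree tree from [simulate_tree()] (with the `clades` attribute).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return ground-truth list: `labels` (data.frame strain/clade/niche/
#'   phenotype), `marker_ogs` (list clade/niche of family ids), `plasmid_ogs`,
#'   `plasmid_strains`, `pseudo_pairs` (data.frame strain, family, fraction),
#'   `family_carriers` (named list family id -> carrier strains),
#'   `accessory_seqs` (named list family id -> nt sequence).
#' @export
plant_structure <- function(config, tree, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  clades <- attr(tree, "clades")
  if (is.null(clades)) stop("tree lacks the clades attribute")
  strains <- sort(names(clades))
  cladeA <- strains[clades[strains] == "A"]
  with_seed(seed, {
    pseudo_clade <- config$pseudo_clade
    if (is.null(pseudo_clade)) pseudo_clade <- .default_subclade(tree, cladeA)
    if (!all(pseudo_clade %in% strains))
      stop("pseudo_clade contains unknown strains")
    rest <- setdiff(strains, pseudo_clade)
    n_cross <- round(config$niche_crossover * length(rest))
    dairy <- sort(c(pseudo_clade,
                    if (n_cross > 0) sample(rest, n_cross) else character(0)))
    plasmid_strains <- config$plasmid_strains
    if (is.null(plasmid_strains)) plasmid_strains <- dairy
    if (!all(plasmid_strains %in% strains))
      stop("plasmid_strains contains unknown strains")
    fam <- function(prefix, k) sprintf("fam_%s_%03d", prefix, seq_len(k))
    core_fams <- fam("core", config$n_core_ogs)
    clade_fams <- fam("cladem", config$n_clade_markers)
    niche_fams <- fam("nichem", config$n_niche_markers)
    plasmid_fams <- fam("plasm", config$n_plasmid_ogs)
    carriers <- c(
      setNames(rep(list(strains), length(core_fams)), core_fams),
      setNames(rep(list(cladeA), length(clade_fams)), clade_fams),
      setNames(rep(list(dairy), length(niche_fams)), niche_fams),
      setNames(rep(list(sort(plasmid_strains)), length(plasmid_fams)),
               plasmid_fams))
    acc_fams <- c(clade_fams, niche_fams, plasmid_fams)
    accessory_seqs <- setNames(
      lapply(acc_fams, function(f) .random_cds(config$gene_length_bp)),
      acc_fams)
    grid <- expand.grid(strain = pseudo_clade, family = core_fams,
                        stringsAsFactors = FALSE)
    n_pseudo <- floor(config$pseudo_fraction * nrow(grid))
    sel <- if (n_pseudo > 0) sort(sample.int(nrow(grid), n_pseudo)) else
      integer(0)
    pseudo_pairs <- grid[sel, , drop = FALSE]
    pseudo_pairs$fraction <- if (n_pseudo > 0) runif(n_pseudo, 0.3, 0.7) else
      numeric(0)
    rownames(pseudo_pairs) <- NULL
    list(labels = data.frame(
           strain = strains,
           clade = unname(clades[strains]),
           niche = ifelse(strains %in% dairy, "dairy", "non_dairy"),
           phenotype = ifelse(strains %in% pseudo_clade, "cremoris",
                              "lactis"),
           stringsAsFactors = FALSE),
         pseudo_clade = sort(pseudo_clade),
         marker_ogs = list(clade = clade_fams, niche = niche_fams),
         plasmid_ogs = plasmid_fams,
         plasmid_strains = sort(plasmid_strains),
         pseudo_pairs = pseudo_pairs,
         family_carriers = carriers,
         accessory_seqs = accessory_seqs)
  })
}

## Default pseudogene-eroded subclade: the smaller child subtree of the
## clade-A ancestor (the whole clade when it has a single leaf).
.default_subclade <- function(tree, cladeA) {
  if (length(cladeA) <= 1L) return(cladeA)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  anc <- kids[vapply(kids, function(k)
    setequal(.tips_under(tree, k), cladeA), logical(1))]
  sub_kids <- tree$edge[tree$edge[, 1L] == anc, 2L]
  sides <- lapply(sub_kids, .tips_under, tree = tree)
  sizes <- lengths(sides)
  pick <- which(sizes == min(sizes))
  if (length(pick) > 1L)
    pick <- pick[order(vapply(sides[pick], min, character(1)))[1L]]
  sort(sides[[pick]])
}

#' Simulate a complete strain collection with ground truth
#'
#' Runs [simulate_tree()], [evolve_sequences()] and [plant_structure()]
#' (sub-seeded from `config$seed`), lays genes onto contigs (chromosomal
#' contig `c1`; plasmid contig `p1` for carriers, 200 bp intergenic
#' spacing), truncates the proteins of the pseudogenized pairs, and builds
#' the coverage table with the plasmid contig at
#' `coverage_multiplier x base_depth`.
#'
#' @param config `sim_config`.
#' @return object of class `lactopan_sim`: list with `config`, `tree`,
#'   `truth`, `genes` (gene data.frame across all strains; `intact` holds
#'   the planted truth), `coverage`, `strain_table`, `traits` (list of named
#'   label vectors `clade` and `niche`), `families` (named list family id ->
#'   member gene ids).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_strains, seed = config$seed)
  core_seqs <- evolve_sequences(tree, config$n_core_ogs,
                                config$gene_length_bp, config$subst_rate,
                                seed = config$seed + 1L)
  truth <- plant_structure(config, tree, seed = config$seed + 2L)
  core_fams <- sprintf("fam_core_%03d", seq_len(config$n_core_ogs))
  names(core_seqs) <- core_fams
  strains <- truth$labels$strain
  spacing <- 200L
  gene_rows <- list()
  cov_rows <- list()
  with_seed(config$seed + 3L, {
    for (s in strains) {
      chrom_fams <- c(core_fams,
                      intersect(truth$marker_ogs$clade,
                                names(Filter(function(cc) s %in% cc,
                                             truth$family_carriers))),
                      intersect(truth$marker_ogs$niche,
                                names(Filter(function(cc) s %in% cc,
                                             truth$family_carriers))))
      plas_fams <- truth$plasmid_ogs[vapply(
        truth$plasmid_ogs, function(f)
          s %in% truth$family_carriers[[f]], logical(1))]
      place <- function(fams, contig) {
        pos <- 0L
        rows <- lapply(fams, function(f) {
          nt <- if (startsWith(f, "fam_core_")) core_seqs[[f]][s] else
            truth$accessory_seqs[[f]]
          aa <- .translate_cds(nt)
          intact <- "intact"
          hit <- truth$pseudo_pairs$strain == s &
            truth$pseudo_pairs$family == f
          if (any(hit)) {
            frac <- truth$pseudo_pairs$fraction[which(hit)[1L]]
            aa <- substr(aa, 1L, max(1L, round(frac * nchar(aa))))
            intact <- "pseudo"
          }
          start <- pos
          pos <<- pos + nchar(nt) + spacing
          data.frame(gene_id = paste(s, f, sep = "_"), strain = s,
                     contig = contig, start = start,
                     end = start + nchar(nt), strand = "+",
                     nt_seq = unname(nt), aa_seq = aa, intact = intact,
                     stringsAsFactors = FALSE)
        })
        list(rows = rows, span = pos + spacing)
      }
      chrom <- place(chrom_fams, "c1")
      gene_rows <- c(gene_rows, chrom$rows)
      noise <- function() if (config$depth_noise > 0)
        max(0.1, 1 + stats::rnorm(1L, 0, config$depth_noise)) else 1
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        strain = s, contig = "c1", length_bp = chrom$span,
        mean_depth = config$base_depth * noise(),
        stringsAsFactors = FALSE)
      if (length(plas_fams)) {
        plas <- place(plas_fams, "p1")
        gene_rows <- c(gene_rows, plas$rows)
        cov_rows[[length(cov_rows) + 1L]] <- data.frame(
          strain = s, contig = "p1", length_bp = plas$span,
          mean_depth = config$base_depth * config$coverage_multiplier *
            noise(),
          stringsAsFactors = FALSE)
      }
    }
  })
  genes <- do.call(rbind, gene_rows)
  coverage <- do.call(rbind, cov_rows)
  families <- split(genes$gene_id,
                    sub("^s[0-9]+_", "", genes$gene_id))
  chrom_bp <- vapply(strains, function(s)
    coverage$length_bp[coverage$strain == s & coverage$contig == "c1"],
    numeric(1))
  plas_bp <- vapply(strains, function(s) {
    v <- coverage$length_bp[coverage$strain == s & coverage$contig == "p1"]
    if (length(v)) v else 0
  }, numeric(1))
  strain_table <- data.frame(
    strain = strains,
    genotype = ifelse(truth$labels$clade == "A", "cremoris", "lactis"),
    phenotype = truth$labels$phenotype,
    origin = "simulated",
    niche = truth$labels$niche,
    genome_size_mb = round((chrom_bp + plas_bp) / 1e6, 4),
    protein_count = as.integer(table(genes$strain)[strains]),
    plasmid_kb = round(plas_bp / 1000, 2),
    status = "draft",
    stringsAsFactors = FALSE)
  structure(list(
    config = config, tree = tree, truth = truth, genes = genes,
    coverage = coverage, strain_table = strain_table,
    traits = list(clade = setNames(truth$labels$clade, strains),
                  niche = setNames(truth$labels$niche, strains)),
    families = families), class = "lactopan_sim")
}

#' @export
print.lactopan_sim <- function(x, ...) {
  cat("simulated dataset:", nrow(x$strain_table), "strains,",
      length(x$families), "gene families,",
      nrow(x$truth$pseudo_pairs), "pseudogenized pairs\n")
  invisible(x)
}

#' Ground-truth presence matrix of a simulated dataset
#'
#' The tri-state matrix implied by the planted structure, bypassing
#' clustering: family carriers are present, pseudogenized pairs are pseudo,
#' everything else absent.
#'
#' @param sim `lactopan_sim`.
#' @return `presence_matrix` with columns = planted family ids.
#' @export
sim_presence_matrix <- function(sim) {
  strains <- sort(sim$strain_table$strain)
  fams <- sort(names(sim$truth$family_carriers))
  m <- matrix(STATE_ABSENT, length(strains), length(fams),
              dimnames = list(strains, fams))
  for (f in fams) m[sim$truth$family_carriers[[f]], f] <- STATE_PRESENT
  pp <- sim$truth$pseudo_pairs
  for (k in seq_len(nrow(pp))) m[pp$strain[k], pp$family[k]] <- STATE_PSEUDO
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Per-core-OG alignment blocks of a simulated dataset
#'
#' Simulated core genes are ungapped and equal-length within a family, so
#' the raw sequences are already aligned blocks suitable for
#' [build_supermatrix()].
#'
#' @param sim `lactopan_sim`.
#' @return named list family id -> named character vector (strain -> nt).
#' @export
sim_core_alignments <- function(sim) {
  core <- sort(grep("^fam_core_", names(sim$families), value = TRUE))
  setNames(lapply(core, function(f) {
    sel <- sim$genes$gene_id %in% sim$families[[f]]
    setNames(sim$genes$nt_seq[sel], sim$genes$strain[sel])
  }), core)
}

#' Write a simulated dataset to disk
#'
#' Emits per-strain nucleotide and protein FASTA (`genes/<strain>.fna`,
#' `.faa`), the strain table, the coverage table, the clade and niche trait
#' tables, the true tree in Newick, the ground truth as JSON, and a
#' manifest. Byte-identical across runs with the same config.
#'
#' @param sim `lactopan_sim`.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
emit_dataset <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  gdir <- file.path(outdir, "genes")
  dir.create(gdir, showWarnings = FALSE)
  paths <- c(strains = file.path(outdir, "strains.tsv"),
             coverage = file.path(outdir, "coverage.tsv"),
             trait_clade = file.path(outdir, "trait_clade.tsv"),
             trait_niche = file.path(outdir, "trait_niche.tsv"),
             tree = file.path(outdir, "tree_true.nwk"),
             truth = file.path(outdir, "truth.json"))
  write_strain_table(sim$strain_table, paths["strains"])
  write_coverage_table(sim$coverage, paths["coverage"])
  write_trait_table(sim$traits$clade, paths["trait_clade"])
  write_trait_table(sim$traits$niche, paths["trait_niche"])
  write_newick(sim$tree, paths["tree"])
  truth_json <- list(
    labels = sim$truth$labels,
    pseudo_clade = sim$truth$pseudo_clade,
    marker_ogs = sim$truth$marker_ogs,
    plasmid_ogs = sim$truth$plasmid_ogs,
    plasmid_strains = sim$truth$plasmid_strains,
    pseudo_pairs = sim$truth$pseudo_pairs,
    family_carriers = sim$truth$family_carriers)
  write_atomic(paths["truth"], function(tmp)
    jsonlite::write_json(truth_json, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  for (s in sim$strain_table$strain) {
    g <- sim$genes[sim$genes$strain == s, , drop = FALSE]
    g <- g[order(g$gene_id), , drop = FALSE]
    write_gene_fasta(g, file.path(gdir, paste0(s, ".fna")),
                     file.path(gdir, paste0(s, ".faa")))
    paths[paste0("genes_", s)] <- file.path(gdir, paste0(s, ".fna"))
  }
  invisible(paths)
}
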