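## Stage orchestration: each stage reads its inputs from `outdir`, validates
## them, and writes its outputs atomically (temp file + rename), so a rerun
## with unchanged inputs and config is byte-identical. A YAML config file
## holds every tunable; all stochastic stages take explicit seeds.

.default_config <- function() {
  list(
    simulate = list(n_strains = 12L, seed = 1L, n_core_ogs = 30L,
                    gene_length_bp = 300L, subst_rate = 0.05,
                    n_clade_markers = 3L, n_niche_markers = 3L,
                    pseudo_fraction = 0.3, niche_crossover = 0.25,
                    n_plasmid_ogs = 5L, coverage_multiplier = 5,
                    base_depth = 50, depth_noise = 0),
    orthology = list(inflation = 1.5, min_norm_score = 0.4,
                     min_coverage = 0.5, prune_threshold = 1e-5,
                     max_iter = 100L, tol = 1e-6),
    pancore = list(n_permutations = 500L, seed = 1L),
    phylogeny = list(model = "p", outgroup = NULL, length_fraction = 0.8),
    plasmid = list(min_ratio = 1.5, min_length_bp = 2000L),
    traits = list(n_perm = 999L, seed = 1L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over the defaults; unknown sections or
#' keys are rejected rather than silently ignored.
#'
#' @param path YAML config path, or NULL for the defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad_sec <- setdiff(names(user), names(cfg))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(user)) {
    bad_key <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad_key))
      stop("unknown key(s) in section ", sec, ": ",
           paste(bad_key, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.need <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' is missing required input: ", path)
  path
}

#' Run one pipeline stage
#'
#' Stages and their artifacts under `outdir`:
#' \describe{
#'   \item{simulate}{ground-truth dataset under `data/`}
#'   \item{cluster}{similarity graph + MCL -> `og_table.tsv`}
#'   \item{pancore}{`presence_matrix.tsv`, `pan_core_curves.tsv`}
#'   \item{tree}{`supermatrix.phy`, `supermatrix_columns.tsv`, `tree.nwk`
#'     (rerooted when an outgroup is configured)}
#'   \item{plasmid}{`contig_calls.tsv`, `plasmid_ogs.txt`}
#'   \item{gtm}{`gtm_<trait>.tsv` per trait table found}
#'   \item{report}{`report.json` headline numbers}
#' }
#' A `run_manifest.json` (stage, config hash, seeds, package version) is
#' refreshed after every stage.
#'
#' @param stage one of simulate, cluster, pancore, tree, plasmid, gtm,
#'   report.
#' @param config configuration list from [load_config()].
#' @param outdir working directory for the run.
#' @return named vector of the stage's output paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "cluster", "pancore", "tree",
                                "plasmid", "gtm", "report"),
                      config = load_config(), outdir) {
  stage <- match.arg(stage)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  data_dir <- file.path(outdir, "data")
  out <- switch(
    stage,
    simulate = {
      sc <- config$simulate
      cfg <- sim_config(n_strains = sc$n_strains, seed = sc$seed,
                        n_core_ogs = sc$n_core_ogs,
                        gene_length_bp = sc$gene_length_bp,
                        subst_rate = sc$subst_rate,
                        n_clade_markers = sc$n_clade_markers,
                        n_niche_markers = sc$n_niche_markers,
                        pseudo_fraction = sc$pseudo_fraction,
                        niche_crossover = sc$niche_crossover,
                        n_plasmid_ogs = sc$n_plasmid_ogs,
                        coverage_multiplier = sc$coverage_multiplier,
                        base_depth = sc$base_depth,
                        depth_noise = sc$depth_noise)
      emit_dataset(simulate_dataset(cfg), data_dir)
    },
    cluster = {
      genes <- .load_genes(data_dir, "cluster")
      oc <- config$orthology
      graph <- build_similarity_graph(genes,
                                      min_norm_score = oc$min_norm_score,
                                      min_coverage = oc$min_coverage)
      part <- mcl_cluster(graph, inflation = oc$inflation,
                          prune_threshold = oc$prune_threshold,
                          max_iter = oc$max_iter, tol = oc$tol)
      genes <- call_pseudogenes(genes, part,
                                config$phylogeny$length_fraction)
      strains <- read_strain_table(.need(file.path(data_dir, "strains.tsv"),
                                         "cluster"))$strain
      ogs <- clusters_to_ogs(part, genes, strains = sort(strains))
      p <- file.path(outdir, "og_table.tsv")
      write_og_table(ogs, genes, p)
      c(og_table = p)
    },
    pancore = {
      ogs <- read_og_table(.need(file.path(outdir, "og_table.tsv"),
                                 "pancore"))
      pm <- build_presence_matrix(ogs)
      curves <- pan_core_curves(pm,
                                n_permutations = config$pancore$n_permutations,
                                seed = config$pancore$seed)
      p1 <- file.path(outdir, "presence_matrix.tsv")
      p2 <- file.path(outdir, "pan_core_curves.tsv")
      write_presence_matrix(pm, p1)
      write_curves(curves, p2)
      c(presence_matrix = p1, curves = p2)
    },
    tree = {
      ogs <- read_og_table(.need(file.path(outdir, "og_table.tsv"), "tree"))
      genes <- .load_genes(data_dir, "tree")
      core <- select_single_copy_core(ogs)
      nt <- setNames(genes$nt_seq, genes$gene_id)
      g_strain <- setNames(genes$strain, genes$gene_id)
      aln <- setNames(lapply(core, function(id) {
        og <- ogs$ogs[[match(id, vapply(ogs$ogs, `[[`, character(1),
                                        "og_id"))]]
        m <- unlist(og$members, use.names = FALSE)
        setNames(nt[m], g_strain[m])
      }), core)
      aln <- Filter(function(b) length(unique(nchar(b))) == 1L, aln)
      if (!length(aln))
        stop("no equal-length single-copy core blocks; supply aligned input")
      sm <- build_supermatrix(aln)
      d <- p_distance_matrix(sm, model = config$phylogeny$model)
      tr <- nj_tree(d)
      og_cfg <- config$phylogeny$outgroup
      if (!is.null(og_cfg)) tr <- reroot_tree(tr, og_cfg)
      p1 <- file.path(outdir, "supermatrix.phy")
      p2 <- file.path(outdir, "supermatrix_columns.tsv")
      p3 <- file.path(outdir, "tree.nwk")
      write_supermatrix(sm, p1, p2)
      write_newick(tr, p3)
      c(supermatrix = p1, columns = p2, tree = p3)
    },
    plasmid = {
      cov <- read_coverage_table(.need(file.path(data_dir, "coverage.tsv"),
                                       "plasmid"))
      ogs <- read_og_table(.need(file.path(outdir, "og_table.tsv"),
                                 "plasmid"))
      genes <- .load_genes(data_dir, "plasmid")
      calls <- classify_contigs(coverage_ratios(cov),
                                min_ratio = config$plasmid$min_ratio,
                                min_length_bp = config$plasmid$min_length_bp)
      pf <- plasmid_og_fraction(ogs, genes, calls)
      p1 <- file.path(outdir, "contig_calls.tsv")
      p2 <- file.path(outdir, "plasmid_ogs.txt")
      write_contig_calls(calls, p1)
      write_atomic(p2, function(tmp) writeLines(pf$plasmid_ogs, tmp))
      c(calls = p1, plasmid_ogs = p2)
    },
    gtm = {
      pm <- read_presence_matrix(.need(file.path(outdir,
                                                 "presence_matrix.tsv"),
                                       "gtm"))
      trait_files <- list.files(data_dir, pattern = "^trait_.*\\.tsv$",
                                full.names = TRUE)
      if (!length(trait_files))
        stop("stage 'gtm' found no trait_*.tsv under ", data_dir)
      res <- character(0)
      for (tf in sort(trait_files)) {
        trait <- sub("^trait_(.*)\\.tsv$", "\\1", basename(tf))
        labels <- read_trait_table(tf)
        r <- rank_discriminating_ogs(pm, labels,
                                     n_perm = config$traits$n_perm,
                                     seed = config$traits$seed)
        p <- file.path(outdir, paste0("gtm_", trait, ".tsv"))
        write_tsv(r, p)
        res[trait] <- p
      }
      res
    },
    report = {
      pm <- read_presence_matrix(.need(file.path(outdir,
                                                 "presence_matrix.tsv"),
                                       "report"))
      curves <- read.delim(.need(file.path(outdir, "pan_core_curves.tsv"),
                                 "report"))
      plas <- readLines(.need(file.path(outdir, "plasmid_ogs.txt"),
                              "report"))
      gtm_files <- list.files(outdir, pattern = "^gtm_.*\\.tsv$",
                              full.names = TRUE)
      top <- lapply(setNames(gtm_files,
                             sub("^gtm_(.*)\\.tsv$", "\\1",
                                 basename(gtm_files))),
                    function(f) utils::head(read.delim(f), 5L))
      rep <- list(
        n_strains = nrow(pm),
        pangenome_ogs = ncol(pm),
        core_ogs = length(core_and_group_ogs(pm, rownames(pm))$core),
        plasmid_ogs = length(plas),
        plasmid_fraction = length(plas) / ncol(pm),
        pan_final = curves$pan_mean[nrow(curves)],
        core_final = curves$core_mean[nrow(curves)],
        top_discriminating = top)
      p <- file.path(outdir, "report.json")
      write_atomic(p, function(tmp)
        jsonlite::write_json(rep, tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE))
      c(report = p)
    })
  manifest <- file.path(outdir, "run_manifest.json")
  prev <- if (file.exists(manifest))
    jsonlite::read_json(manifest, simplifyVector = TRUE) else
      list(stages = list())
  prev$config_hash <- .config_hash(config)
  prev$package_version <- as.character(utils::packageVersion("lactopan"))
  prev$stages[[stage]] <- as.list(out)
  write_atomic(manifest, function(tmp)
    jsonlite::write_json(prev, tmp, auto_unbox = TRUE, pretty = TRUE))
  invisible(out)
}

## Read every per-strain gene FASTA pair under data_dir/genes.
.load_genes <- function(data_dir, stage) {
  gdir <- .need(file.path(data_dir, "genes"), stage)
  fna <- sort(list.files(gdir, pattern = "\\.fna$", full.names = TRUE))
  if (!length(fna))
    stop("stage '", stage, "' found no gene FASTA under ", gdir)
  do.call(rbind, lapply(fna, function(f) {
    s <- sub("\\.fna$", "", basename(f))
    read_gene_fasta(f, sub("\\.fna$", ".faa", f), s)
  }))
}

#' Run the full pipeline
#'
#' All stages in order: simulate (unless `outdir/data` already holds a
#' dataset), cluster, pancore, tree, plasmid, gtm, report.
#'
#' @param config configuration list from [load_config()].
#' @param outdir working directory for the run.
#' @return named list of per-stage output paths, invisibly.
#' @export
run_pipeline <- function(config = load_config(), outdir) {
  stages <- c("simulate", "cluster", "pancore", "tree", "plasmid", "gtm",
              "report")
  if (dir.exists(file.path(outdir, "data", "genes")))
    stages <- setdiff(stages, "simulate")
  res <- lapply(setNames(stages, stages), function(st)
    run_stage(st, config, outdir))
  invisible(res)
}
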