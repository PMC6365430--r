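## Plasmid contig classification from relative read coverage. Multi-copy
## replicons sequence deeper than the chromosome; the chromosomal baseline
## is the length-weighted median depth of a strain's contigs, which a few
## short high-copy contigs cannot shift.

#' Per-contig coverage ratios
#'
#' For each strain the baseline is the length-weighted median of its contig
#' depths; each contig's ratio is its mean depth over that baseline. A zero
#' baseline leaves every ratio of the strain undefined (NA).
#'
#' @param cov coverage data.frame from [read_coverage_table()] (one or more
#'   strains).
#' @return the input with `baseline` and `ratio` columns appended.
#' @export
coverage_ratios <- function(cov) {
  if (nrow(cov) == 0L) stop("coverage table is empty")
  out <- cov
  out$baseline <- NA_real_
  out$ratio <- NA_real_
  for (s in unique(cov$strain)) {
    sel <- cov$strain == s
    base <- weighted_median(cov$mean_depth[sel], cov$length_bp[sel])
    out$baseline[sel] <- base
    if (!is.na(base) && base > 0)
      out$ratio[sel] <- cov$mean_depth[sel] / base
  }
  out
}

#' Classify contigs as plasmid or chromosome
#'
#' A contig is called `plasmid` when its coverage ratio reaches `min_ratio`,
#' it is at least `min_length_bp` long and it is not flagged as a repeat
#' element; `unclassified` exactly when a filter fired (short contig, repeat
#' flag, or undefined ratio from a zero baseline); `chromosome` otherwise.
#' Repeat flags stand in for the manual curation that removes rRNA
#' clusters, transposable elements and phages, whose coverage is inflated
#' for reasons other than plasmid copy number.
#'
#' @param ratios data.frame from [coverage_ratios()].
#' @param min_ratio minimum coverage ratio for a plasmid call.
#' @param min_length_bp minimum contig length considered classifiable.
#' @param repeat_flags character vector of contig ids to set aside.
#' @return the input with `call` ("plasmid"/"chromosome"/"unclassified") and
#'   `reason` columns appended.
#' @export
classify_contigs <- function(ratios, min_ratio = 1.5, min_length_bp = 2000L,
                             repeat_flags = character()) {
  stopifnot(all(c("ratio", "length_bp") %in% names(ratios)))
  call <- character(nrow(ratios))
  reason <- character(nrow(ratios))
  for (k in seq_len(nrow(ratios))) {
    if (is.na(ratios$ratio[k])) {
      call[k] <- "unclassified"; reason[k] <- "zero_baseline"
    } else if (ratios$contig[k] %in% repeat_flags) {
      call[k] <- "unclassified"; reason[k] <- "repeat"
    } else if (ratios$length_bp[k] < min_length_bp) {
      call[k] <- "unclassified"; reason[k] <- "short"
    } else if (ratios$ratio[k] >= min_ratio) {
      call[k] <- "plasmid"; reason[k] <- "elevated_coverage"
    } else {
      call[k] <- "chromosome"; reason[k] <- ""
    }
  }
  ratios$call <- call
  ratios$reason <- reason
  ratios
}

#' Plasmid-origin OGs and the plasmid fraction of the pangenome
#'
#' An OG is of plasmid origin when at least half of its member genes lie on
#' plasmid-called contigs (ties count as plasmid). Every member gene must
#' map to a called contig.
#'
#' @param ogs `og_set`.
#' @param genes gene data.frame (columns `gene_id`, `strain`, `contig`).
#' @param calls classified contigs from [classify_contigs()].
#' @return list with `plasmid_ogs` (character vector of OG ids) and
#'   `fraction` (plasmid OGs / total OGs).
#' @export
plasmid_og_fraction <- function(ogs, genes, calls) {
  key <- paste(calls$strain, calls$contig, sep = "\r")
  call_of <- setNames(calls$call, key)
  gkey <- paste(genes$strain, genes$contig, sep = "\r")
  unmapped <- which(!(gkey %in% key))
  if (length(unmapped))
    stop("gene(s) on contigs without a coverage call, e.g. ",
         genes$gene_id[unmapped[1L]])
  gene_call <- setNames(call_of[gkey], genes$gene_id)
  plasmid <- vapply(ogs$ogs, function(og) {
    members <- unlist(og$members, use.names = FALSE)
    n_plasmid <- sum(gene_call[members] == "plasmid")
    n_plasmid >= length(members) / 2
  }, logical(1))
  ids <- vapply(ogs$ogs, `[[`, character(1), "og_id")
  list(plasmid_ogs = sort(ids[plasmid]),
       fraction = sum(plasmid) / length(ids))
}

#' Write contig calls as TSV
#' @param calls data.frame from [classify_contigs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_contig_calls <- function(calls, path) {
  write_tsv(calls[, c("strain", "contig", "length_bp", "mean_depth",
                      "ratio", "call", "reason")], path)
}
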