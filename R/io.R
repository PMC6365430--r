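## Readers and writers for the external plain-text formats: strain metadata
## tables, contig coverage tables, gene FASTA pairs and binary trait tables.
## All tables are UTF-8 TSV with a header row.

.genotype_levels <- c("lactis", "cremoris", "other")
.phenotype_levels <- c("lactis", "cremoris", "diacetylactis", "unknown")
.niche_levels <- c("dairy", "non_dairy", "unknown")
.status_levels <- c("complete", "draft")

#' Read a strain metadata table
#'
#' Expected columns: `strain`, `genotype`, `phenotype`, `origin`,
#' `genome_size_mb`, `protein_count`, `plasmid_kb`, `status`, and optionally
#' `niche` (`dairy`/`non_dairy`/`unknown`). The niche is taken from that
#' explicit column when present and is otherwise set to `"unknown"`; it is
#' never guessed from the free-text origin, because dairy/non-dairy
#' assignment of environmental isolates is a curation decision.
#'
#' @param path path to a TSV file with header.
#' @return data.frame with one row per strain, columns as above (niche always
#'   present), character columns unfactored.
#' @export
read_strain_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  req <- c("strain", "genotype", "phenotype", "origin",
           "genome_size_mb", "protein_count", "plasmid_kb", "status")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("strain table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  dup <- unique(x$strain[duplicated(x$strain)])
  if (length(dup))
    stop("duplicate strain ids in ", path, ": ", paste(dup, collapse = ", "))
  for (col in c("genome_size_mb", "protein_count", "plasmid_kb")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in row ", bad[1L],
           " (strain ", x$strain[bad[1L]], ")")
    x[[col]] <- v
  }
  if (is.null(x$niche)) x$niche <- rep("unknown", nrow(x))
  .strain_coerce(x)
}

.strain_coerce <- function(x) {
  x$status <- tolower(x$status)
  x$genotype <- tolower(x$genotype)
  x$phenotype <- ifelse(is.na(x$phenotype) | x$phenotype == "",
                        "unknown", tolower(x$phenotype))
  x$niche <- ifelse(is.na(x$niche) | x$niche == "", "unknown", x$niche)
  for (spec in list(c("genotype"), c("phenotype"), c("niche"), c("status"))) {
    col <- spec[[1L]]
    lv <- get(paste0(".", col, "_levels"))
    bad <- setdiff(unique(x[[col]]), lv)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(x$genome_size_mb <= 0)) stop("genome_size_mb must be > 0")
    if (any(x$protein_count <= 0)) stop("protein_count must be > 0")
    if (any(x$plasmid_kb < 0)) stop("plasmid_kb must be >= 0")
  }
  cols <- c("strain", "genotype", "phenotype", "origin", "niche",
            "genome_size_mb", "protein_count", "plasmid_kb", "status")
  x[, cols]
}

#' Write a strain metadata table
#'
#' Inverse of [read_strain_table()]; a written table re-reads value-identical.
#'
#' @param strains data.frame as returned by [read_strain_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_strain_table <- function(strains, path) {
  write_tsv(strains, path)
}

#' Summary statistics over a strain table
#'
#' Arithmetic means of genome size and protein count after excluding the
#' given strains, plus the size extremes computed separately for draft and
#' for complete assemblies. Means are reported with commercial rounding
#' (size to 2 decimals, proteins to integer); extremes are reported as
#' printed in the input.
#'
#' @param strains data.frame from [read_strain_table()].
#' @param exclude character vector of strain ids to drop before summarizing.
#' @return list with `n`, `mean_size_mb`, `mean_proteins`, `max_draft_size`,
#'   `min_draft_size`, `max_complete_size`, `min_complete_size`. Draft or
#'   complete fields are `NA` when no strain of that status remains.
#' @export
strain_summary_stats <- function(strains, exclude = character()) {
  x <- strains[!(strains$strain %in% exclude), , drop = FALSE]
  if (nrow(x) == 0L) stop("no strains left after exclusion")
  dr <- x$genome_size_mb[x$status == "draft"]
  co <- x$genome_size_mb[x$status == "complete"]
  ext <- function(v, f) if (length(v)) f(v) else NA_real_
  list(
    n = nrow(x),
    mean_size_mb = round_half_up(mean(x$genome_size_mb), 2),
    mean_proteins = round_half_up(mean(x$protein_count), 0),
    max_draft_size = ext(dr, max),
    min_draft_size = ext(dr, min),
    max_complete_size = ext(co, max),
    min_complete_size = ext(co, min)
  )
}

#' Read a contig coverage table
#'
#' Expected columns: `strain`, `contig`, `length`, `depth` (mean read depth
#' per base, from any mapper).
#'
#' @param path path to a TSV file with header.
#' @return data.frame with columns `strain`, `contig`, `length_bp`,
#'   `mean_depth`.
#' @export
read_coverage_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "contig", "length", "depth")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("coverage table missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(strain = as.character(x$strain),
                    contig = as.character(x$contig),
                    length_bp = as.integer(x$length),
                    mean_depth = as.numeric(x$depth),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(is.na(out$length_bp)) || any(out$length_bp <= 0))
      stop("contig length must be a positive integer")
    if (any(is.na(out$mean_depth)) || any(out$mean_depth < 0))
      stop("mean depth must be >= 0")
  }
  out
}

#' Write a contig coverage table
#' @param cov data.frame as returned by [read_coverage_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coverage_table <- function(cov, path) {
  write_tsv(data.frame(strain = cov$strain, contig = cov$contig,
                       length = cov$length_bp, depth = cov$mean_depth),
            path)
}

## Parse "gene_id|contig|start|end|strand" FASTA headers.
.parse_gene_headers <- function(headers, path) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("malformed FASTA header in ", path, ": ", headers[bad[1L]])
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 3L]))
  end <- suppressWarnings(as.integer(m[, 4L]))
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer coordinates in FASTA headers of ", path)
  if (any(start < 0L) || any(start >= end))
    stop("coordinates must satisfy 0 <= start < end (half-open) in ", path)
  if (!all(m[, 5L] %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  data.frame(gene_id = m[, 1L], contig = m[, 2L], start = start, end = end,
             strand = m[, 5L], stringsAsFactors = FALSE)
}

#' Read a paired nucleotide/protein gene FASTA into gene records
#'
#' Both files must carry headers of the form
#' `gene_id|contig|start|end|strand` (0-based half-open coordinates) and
#' identical gene-id sets. An internal stop (`*` before the last position)
#' in the protein sequence marks the gene as a pseudogene; length-based
#' pseudogene calls are made later, per orthologous group, by
#' [call_pseudogenes()].
#'
#' @param nt_path FASTA of nucleotide gene sequences.
#' @param aa_path FASTA of the corresponding protein sequences.
#' @param strain_id strain these genes belong to.
#' @return data.frame with columns `gene_id`, `strain`, `contig`, `start`,
#'   `end`, `strand`, `nt_seq`, `aa_seq`, `intact` ("intact"/"pseudo").
#' @export
read_gene_fasta <- function(nt_path, aa_path, strain_id) {
  nt <- Biostrings::readBStringSet(nt_path)
  aa <- Biostrings::readBStringSet(aa_path)
  hn <- .parse_gene_headers(names(nt), nt_path)
  ha <- .parse_gene_headers(names(aa), aa_path)
  if (anyDuplicated(hn$gene_id) || anyDuplicated(ha$gene_id))
    stop("duplicate gene ids in FASTA for strain ", strain_id)
  if (!setequal(hn$gene_id, ha$gene_id))
    stop("gene ids differ between nt and aa FASTA for strain ", strain_id,
         " (e.g. ",
         paste(utils::head(c(setdiff(hn$gene_id, ha$gene_id),
                             setdiff(ha$gene_id, hn$gene_id)), 3L),
               collapse = ", "), ")")
  aa_seq <- as.character(aa)[match(hn$gene_id, ha$gene_id)]
  core <- sub("\\*$", "", aa_seq)            # trailing stop is not a defect
  intact <- ifelse(grepl("*", core, fixed = TRUE), "pseudo", "intact")
  data.frame(gene_id = hn$gene_id, strain = strain_id, contig = hn$contig,
             start = hn$start, end = hn$end, strand = hn$strand,
             nt_seq = as.character(nt), aa_seq = aa_seq, intact = intact,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write gene records as a nucleotide/protein FASTA pair
#' @param genes data.frame as returned by [read_gene_fasta()].
#' @param nt_path,aa_path output FASTA paths.
#' @return invisibly, the two paths.
#' @export
write_gene_fasta <- function(genes, nt_path, aa_path) {
  hdr <- paste(genes$gene_id, genes$contig, genes$start, genes$end,
               genes$strand, sep = "|")
  write_atomic(nt_path, function(tmp)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(genes$nt_seq, hdr)), tmp))
  write_atomic(aa_path, function(tmp)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(genes$aa_seq, hdr)), tmp))
  invisible(c(nt_path, aa_path))
}

#' Read a binary trait table
#'
#' Two columns, `strain` and `label`; empty labels or the literal `NA`
#' become missing.
#'
#' @param path path to a TSV file with header.
#' @return named character vector of labels (NA = missing), names = strains.
#' @export
read_trait_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("strain", "label") %in% names(x)))
    stop("trait table must have columns strain, label")
  if (anyDuplicated(x$strain))
    stop("duplicate strain ids in trait table ", path)
  lab <- x$label
  lab[lab == "" | lab == "NA"] <- NA_character_
  setNames(lab, x$strain)
}

#' Write a binary trait table
#' @param labels named character vector (names = strains, NA = missing).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trait_table <- function(labels, path) {
  write_tsv(data.frame(strain = names(labels),
                       label = ifelse(is.na(labels), "NA", labels)),
            path)
}

#' Path to the bundled Lactococcus lactis strain table
#'
#' The 44-strain metadata table (43 *L. lactis* strains plus the
#' *Lactococcus* sp. outgroup P7266) with genotype, phenotype, origin,
#' curated dairy/non-dairy niche, genome size, protein count, plasmid
#' content and assembly status.
#'
#' @return path to the installed TSV file.
#' @export
lactis_strain_table <- function() {
  system.file("extdata", "lactis_strains.tsv", package = "lactopan",
              mustWork = TRUE)
}
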