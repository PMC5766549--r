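#' Read and write the phenotype table
#'
#' Tab-separated dialect with a header: `id`, `herd_date`, `parity_class`,
#' `dim_class`, then one column per trait. Missing trait values are `NA`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = NA,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in c("id", "herd_date", "parity_class", "dim_class")) {
    if (!cn %in% names(df)) abort(paste0("Phenotype file lacks column: ", cn))
    df[[cn]] <- as.character(df[[cn]])
  }
  tibble::as_tibble(df)
}

#' @rdname read_phenotypes
#' @param phenotypes Tibble as produced by [simulate_phenotypes()].
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- as.data.frame(phenotypes)
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Gene annotation readers and writer
#'
#' BED input is 0-based half-open and is normalised to 1-based inclusive
#' intervals on read; GFF3 input is already 1-based inclusive. The writer
#' emits BED (so `start - 1`, `end`).
#'
#' @param path File path.
#' @return Tibble `gene`, `chr`, `start`, `end` (1-based inclusive).
#' @export
read_annotation_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chr", "start", "end", "gene"),
                   colClasses = c("character", "integer", "integer", "character"))
  tibble::tibble(
    gene = df$gene,
    chr = suppressWarnings(as.integer(df$chr)),
    start = df$start + 1L,
    end = df$end
  )
}

#' @rdname read_annotation_bed
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @export
read_annotation_gff3 <- function(path, feature_type = "gene") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 9
  parts <- parts[ok]
  rows <- lapply(parts, function(p) {
    if (p[3] != feature_type) return(NULL)
    attrs <- p[9]
    id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attrs)
    if (identical(id, attrs)) {
      id <- sub(".*(?:^|;)gene_id=([^;]+).*", "\\1", attrs)
    }
    tibble::tibble(
      gene = id, chr = suppressWarnings(as.integer(p[1])),
      start = as.integer(p[4]), end = as.integer(p[5])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort(paste0("No '", feature_type, "' features in ", path))
  out
}

#' @rdname read_annotation_bed
#' @param genes Annotation tibble (1-based inclusive).
#' @export
write_annotation_bed <- function(genes, path) {
  df <- data.frame(chr = genes$chr, start = genes$start - 1L,
                   end = genes$end, gene = genes$gene)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One category per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of gene-id vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a TF catalog (one gene symbol per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_tf_list
#' @param tf_catalog Character vector of TF gene ids.
#' @export
write_tf_list <- function(tf_catalog, path) {
  writeLines(tf_catalog, path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits PLINK `genotypes.bed/.bim/.fam`, `phenotypes.tsv`, `genes.bed`,
#' `gene_sets.gmt`, `tf_catalog.txt` and a `truth.json` sidecar with the
#' simulation ground truth. All writers are deterministic, so a fixed seed
#' yields byte-identical files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(cohort$genotypes, file.path(dir, "genotypes"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_annotation_bed(cohort$annotation$genes, file.path(dir, "genes.bed"))
  write_gmt(cohort$annotation$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tf_list(cohort$annotation$tf_catalog, file.path(dir, "tf_catalog.txt"))
  truth <- list(
    traits = cohort$truth$traits,
    qtl = cohort$truth$qtl,
    seed = cohort$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
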