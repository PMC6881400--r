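# TSV readers/writers with schema validation, and the pipeline driver.

stop_io <- function(...) stop(..., call. = FALSE)

validate_samples <- function(samples, count_cols) {
  need <- c("sample_id", "accession", "stage", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_io("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop_io("duplicate sample_id in sample sheet")
  bad <- setdiff(samples$sample_id, count_cols)
  if (length(bad)) stop_io("orphan samples not in count table: ", paste(head(bad), collapse = ", "))
  ok <- samples$accession %in% c("M", "T", "MxT", "TxM")
  if (!all(ok)) stop_io("unknown accession label(s): ",
                        paste(unique(samples$accession[!ok]), collapse = ", "))
  invisible(TRUE)
}

validate_counts <- function(mat, what = "count table") {
  if (anyDuplicated(rownames(mat))) stop_io(what, ": duplicate gene ids")
  bad <- which(mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_io(sprintf("%s: non-integer or negative count at gene %s, sample %s",
                    what, rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  invisible(TRUE)
}

validate_allelic <- function(allelic, samples) {
  cn <- colnames(allelic)
  m <- grepl("\\.M_allele$", cn); t_ <- grepl("\\.T_allele$", cn)
  if (!all(m | t_)) stop_io("allelic columns must end in .M_allele or .T_allele: ",
                            paste(head(cn[!(m | t_)]), collapse = ", "))
  libs_m <- sub("\\.M_allele$", "", cn[m]); libs_t <- sub("\\.T_allele$", "", cn[t_])
  orphan <- c(setdiff(libs_m, libs_t), setdiff(libs_t, libs_m))
  if (length(orphan)) stop_io("allelic column without partner allele column for library: ",
                              paste(orphan, collapse = ", "))
  hyb <- samples$sample_id[samples$accession %in% c("MxT", "TxM")]
  bad <- setdiff(libs_m, hyb)
  if (length(bad)) stop_io("allelic libraries not in hybrid sample sheet: ",
                           paste(head(bad), collapse = ", "))
  invisible(TRUE)
}

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (names(df)[1] != "gene_id") stop_io(what, ": first column must be gene_id (", path, ")")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop_io(what, ": missing values in ", path)
  mat
}

#' Read a gene x sample count table (TSV, first column gene_id)
#' @param path file path.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  mat <- read_tsv_matrix(path, "count table")
  validate_counts(mat)
  storage.mode(mat) <- "integer"
  mat
}

#' Read an allele-resolved count table (columns <lib>.M_allele / <lib>.T_allele)
#' @param path file path.
#' @param samples optional sample sheet for library validation.
#' @return integer matrix.
#' @export
read_allelic <- function(path, samples = NULL) {
  mat <- read_tsv_matrix(path, "allelic count table")
  validate_counts(mat, "allelic count table")
  if (!is.null(samples)) validate_allelic(mat, samples)
  storage.mode(mat) <- "integer"
  mat
}

#' Read a sample sheet (sample_id, accession, stage, replicate)
#' @param path file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "accession", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_io("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a homoeolog pair table (at_gene, dt_gene)
#' @param path file path.
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("at_gene", "dt_gene") %in% names(df)))
    stop_io("pair table needs columns at_gene, dt_gene")
  if (any(df$at_gene == df$dt_gene)) stop_io("pair table: at_gene equals dt_gene")
  df
}

#' Read a homology graph (edge list + node labels)
#' @param edges_path TSV with two gene-id columns.
#' @param nodes_path TSV with columns gene, genome.
#' @return list(edges, nodes).
#' @export
read_graph <- function(edges_path, nodes_path) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE, comment.char = "#")
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(edges) < 2) stop_io("edge list needs two columns")
  if (!all(c("gene", "genome") %in% names(nodes)))
    stop_io("node table needs columns gene, genome")
  list(edges = edges, nodes = nodes)
}

# write a matrix as TSV with a parameter comment header
write_tsv_matrix <- function(mat, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tsv_df <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Emits counts.tsv, allelic.tsv, samples.tsv, truth.tsv and pairs.tsv with
#' a parameter/seed comment header in each file.
#'
#' @param sim a \code{\link{simulate_ase}} result.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("seed=%d n_genes=%d dispersion=%g allelic_fraction=%g",
                 sim$params$seed, sim$params$n_genes, sim$params$dispersion,
                 sim$params$allelic_fraction)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             allelic = file.path(dir, "allelic.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             pairs = file.path(dir, "pairs.tsv"))
  write_tsv_matrix(sim$counts, paths["counts"], hdr)
  write_tsv_matrix(sim$allelic, paths["allelic"], hdr)
  write_tsv_df(sim$samples, paths["samples"], hdr)
  write_tsv_df(sim$truth, paths["truth"], hdr)
  write_tsv_df(sim$pairs, paths["pairs"], hdr)
  invisible(paths)
}
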