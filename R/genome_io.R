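#' Read a gene / TSS table
#'
#' Reads a table of genes with a single transcription start site (TSS) point
#' per gene. Two formats are supported:
#'
#' * `"bed6"`: standard BED6 (`chrom, start, end, name, score, strand`) where
#'   `start` is the 0-based TSS coordinate and `end == start + 1`;
#' * `"tsv"`: a headered TSV with columns `gene_id, chrom, tss, strand`.
#'
#' All coordinates are 0-based, half-open throughout the package. The TSS is
#' stored as a single point; for minus-strand genes the input must already
#' give the TSS point (no gene-body inference is performed).
#'
#' @param path path to the file.
#' @param format `"auto"` (guessed from the extension), `"bed6"` or `"tsv"`.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `tss` (integer),
#'   `strand` (`"+"` or `"-"`), one row per gene.
#' @export
read_gene_table <- function(path, format = c("auto", "bed6", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed6" else "tsv"
  }
  if (format == "bed6") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "character",
                                           "character", "character",
                                           "character", "character"))
    start_num <- suppressWarnings(as.numeric(df$start))
    bad <- which(is.na(start_num) | start_num != floor(start_num))
    if (length(bad) > 0)
      stop("non-integer TSS coordinate at line ", bad[1], ": ", df$start[bad[1]])
    end_num <- suppressWarnings(as.numeric(df$end))
    bad <- which(is.na(end_num) | end_num != start_num + 1)
    if (length(bad) > 0)
      stop("BED6 gene record must have end == start + 1 (line ", bad[1], ")")
    genes <- data.frame(gene_id = df$name, chrom = df$chrom,
                        tss = as.integer(start_num), strand = df$strand,
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df)))
      stop("TSV gene table needs columns: ", paste(need, collapse = ", "))
    tss_num <- suppressWarnings(as.numeric(df$tss))
    bad <- which(is.na(tss_num) | tss_num != floor(tss_num))
    if (length(bad) > 0)
      stop("non-integer TSS coordinate at line ", bad[1] + 1L)
    genes <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                        tss = as.integer(tss_num), strand = df$strand,
                        stringsAsFactors = FALSE)
  }
  validate_gene_table(genes)
}

#' Validate a gene table
#'
#' Checks the invariants of a gene table: unique gene ids, non-negative TSS
#' coordinates, strand in `{+, -}`.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @return the validated data.frame (invisibly modified: row names dropped).
#' @export
validate_gene_table <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("invalid strand '", genes$strand[bad[1]], "' at line ", bad[1],
         " (must be + or -)")
  if (any(genes$tss < 0))
    stop("negative TSS coordinate at line ", which(genes$tss < 0)[1])
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene_id in gene table: ", dup[1])
  rownames(genes) <- NULL
  genes
}

#' Write a gene table
#'
#' @param genes gene table as returned by [read_gene_table()].
#' @param path output path.
#' @param format `"bed6"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, format = c("bed6", "tsv")) {
  format <- match.arg(format)
  genes <- validate_gene_table(genes)
  if (format == "bed6") {
    out <- data.frame(genes$chrom, genes$tss, genes$tss + 1L, genes$gene_id,
                      0L, genes$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(genes[, c("gene_id", "chrom", "tss", "strand")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix
#'
#' Reads a genes-by-tissues expression matrix from a TSV whose header names
#' the tissues and whose first column holds gene ids (the layout of the
#' released 218-tissue expression profiles this kind of model is trained on).
#' Values must be non-negative expression units (e.g. RPKM). Genes absent
#' from a gene table are retained; filtering happens at join time.
#'
#' @param path path to the TSV.
#' @return numeric matrix, rownames = gene ids, colnames = tissue names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("expression matrix needs at least one tissue column")
  tissues <- header[-1]
  if (any(!nzchar(tissues))) stop("empty tissue name in header")
  if (anyDuplicated(tissues)) stop("duplicate tissue name in header")
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (any(nf != length(header)))
    stop("ragged row in expression matrix at line ",
         which(nf != length(header))[1])
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character",
                                         rep("numeric", length(tissues))))
  if (anyDuplicated(df[[1]])) stop("duplicate gene id in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- tissues
  if (any(!is.finite(m))) stop("non-finite expression value")
  if (any(m < 0))
    stop("negative expression value for gene ",
         rownames(m)[which(m < 0, arr.ind = TRUE)[1, 1]])
  m
}

#' Write an expression matrix
#'
#' @param m numeric matrix with gene rownames and tissue colnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-line / experiment to tissue mapping
#'
#' Accepts either a 2-column TSV (`experiment<TAB>tissue`, optional header
#' line starting with `#`) or `key=value` lines. Used to pick, for each
#' chromatin-contact experiment, the closest tissue column of the expression
#' matrix.
#'
#' @param path path to the mapping file.
#' @param expression optional expression matrix; if given, every mapped
#'   tissue must be one of its columns.
#' @return named character vector: `names` = experiments, values = tissues.
#' @export
read_tissue_mapping <- function(path, expression = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty tissue mapping: ", path)
  if (all(grepl("=", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "=", fixed = TRUE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
  }
  if (any(lengths(parts) != 2))
    stop("malformed tissue-mapping line: ", lines[which(lengths(parts) != 2)[1]])
  map <- vapply(parts, function(p) trimws(p[2]), character(1))
  names(map) <- vapply(parts, function(p) trimws(p[1]), character(1))
  if (anyDuplicated(names(map))) stop("duplicate experiment in tissue mapping")
  if (!is.null(expression)) {
    missing <- setdiff(map, colnames(expression))
    if (length(missing) > 0)
      stop("mapped tissue not in expression matrix: ", missing[1])
  }
  map
}

#' Log-transform an expression value into the regression target
#'
#' The regressor is trained on log expression; the target is
#' `ln(x + pseudocount)`. The pseudocount keeps zero-expression genes finite
#' and is a documented configuration choice (default `1e-4`), not something
#' inferred from data.
#'
#' @param x non-negative expression value(s).
#' @param pseudocount positive pseudocount added before the log.
#' @return `log(x + pseudocount)`; strictly increasing in `x`.
#' @seealso [inverse_transform_target()]
#' @export
transform_target <- function(x, pseudocount = 1e-4) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive scalar")
  if (any(!is.finite(x))) stop("non-finite expression value")
  if (any(x < 0)) stop("negative expression value")
  log(x + pseudocount)
}

#' Invert the target transform
#'
#' @param t log-space target value(s).
#' @inheritParams transform_target
#' @return expression value `exp(t) - pseudocount`.
#' @export
inverse_transform_target <- function(t, pseudocount = 1e-4) {
  exp(t) - pseudocount
}
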