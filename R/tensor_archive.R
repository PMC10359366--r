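#' Build a tensor archive for a set of genes
#'
#' Runs [build_gene_tensor()] for every gene and collects the results,
#' together with the gene table and the geometry metadata (`F`, `K`,
#' resolution, flattening layout, per-gene fallback flags), into a single
#' archive object. Tensors are archived because they are the expensive part
#' of the pipeline (at full scale, tens of thousands per cell line); the
#' regressor is refit many times from one archive.
#'
#' @param genes gene table.
#' @param cs a [contact_set()].
#' @param predictor a [signal_predictor()].
#' @param basis a [decay_basis()] (default `decay_basis()`).
#' @param linear_scope,min_count,anchor_mode see [select_spatial_regions()].
#' @param verbose log progress counts.
#' @return object of class `tensor_archive`.
#' @export
build_tensor_archive <- function(genes, cs, predictor,
                                 basis = decay_basis(),
                                 linear_scope = 20000L, min_count = 2L,
                                 anchor_mode = "point", verbose = TRUE) {
  genes <- validate_gene_table(genes)
  tensors <- vector("list", nrow(genes))
  fallback <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    t <- build_gene_tensor(genes[i, ], cs, predictor, basis,
                           linear_scope = linear_scope,
                           min_count = min_count, anchor_mode = anchor_mode)
    tensors[[i]] <- t
    fallback[i] <- t$fallback
  }
  names(tensors) <- genes$gene_id
  if (verbose)
    message("built ", length(tensors), " tensors (",
            sum(fallback), " fallback, ",
            round(100 * mean(fallback), 1), "% fallback rate)")
  structure(list(tensors = tensors, genes = genes,
                 n_tracks = predictor$n_tracks, K = basis$K,
                 resolution = cs$resolution,
                 layout = "track-major",
                 feature_names = tensor_feature_names(predictor$n_tracks,
                                                      basis$K),
                 fallback = stats::setNames(fallback, genes$gene_id)),
            class = "tensor_archive")
}

#' @export
print.tensor_archive <- function(x, ...) {
  cat("Tensor archive:", length(x$tensors), "genes,", x$n_tracks,
      "tracks x", 2 * x$K + 1, "columns, contact resolution", x$resolution,
      "bp, fallback rate", round(100 * mean(x$fallback), 1), "%\n")
  invisible(x)
}

#' Write / read a tensor archive
#'
#' The archive is serialized with R's native RDS format (version 2, so it
#' is stable across R sessions); `read_tensor_archive(write_tensor_archive(x))`
#' reproduces `x` exactly, including all metadata and fallback flags.
#'
#' @param archive a [build_tensor_archive()] result.
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly (write); the archive (read).
#' @export
write_tensor_archive <- function(archive, path) {
  stopifnot(inherits(archive, "tensor_archive"))
  if (anyDuplicated(names(archive$tensors)))
    stop("duplicate gene key in archive: ",
         names(archive$tensors)[duplicated(names(archive$tensors))][1])
  saveRDS(archive, path, version = 2)
  invisible(path)
}

#' @rdname write_tensor_archive
#' @export
read_tensor_archive <- function(path) {
  if (!file.exists(path)) stop("tensor archive not found: ", path)
  archive <- readRDS(path)
  if (!inherits(archive, "tensor_archive"))
    stop("not a tensor archive: ", path)
  if (anyDuplicated(names(archive$tensors)))
    stop("duplicate gene key in archive")
  archive
}

#' Extract one gene's tensor from an archive
#'
#' @param archive a `tensor_archive`.
#' @param gene_id gene identifier.
#' @return the gene's `feature_tensor`.
#' @export
archive_tensor <- function(archive, gene_id) {
  t <- archive$tensors[[gene_id]]
  if (is.null(t)) stop("gene not in archive: ", gene_id)
  t
}

#' Flattened feature matrix from an archive
#'
#' Rows are genes, columns the track-major flattened tensor entries. With
#' `spatial = FALSE` the spatial columns are removed entirely (not zeroed)
#' and the recorded layout shrinks accordingly — this is the baseline arm
#' without spatial information.
#'
#' @param archive a `tensor_archive`.
#' @param gene_ids genes to include (default: all, archive order).
#' @param spatial keep the spatial column?
#' @return numeric matrix `genes x features` with dimnames.
#' @export
feature_matrix <- function(archive, gene_ids = NULL, spatial = TRUE) {
  stopifnot(inherits(archive, "tensor_archive"))
  if (is.null(gene_ids)) gene_ids <- names(archive$tensors)
  missing <- setdiff(gene_ids, names(archive$tensors))
  if (length(missing) > 0) stop("gene not in archive: ", missing[1])
  rows <- lapply(gene_ids, function(g) flatten_tensor(archive$tensors[[g]]))
  m <- do.call(rbind, rows)
  rownames(m) <- gene_ids
  colnames(m) <- archive$feature_names
  if (!spatial)
    m <- m[, !grepl("\\.sp$", colnames(m)), drop = FALSE]
  m
}
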