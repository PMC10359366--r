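#' Build a contact set from a data frame of binned pairs
#'
#' A contact set holds intra-chromosomal chromatin contacts (ChIA-PET or
#' Hi-C style) binned at a fixed resolution, with an integer observation
#' count per pair. Anchors are normalized so `start1 <= start2`, and
#' identical pairs are de-duplicated by summing their counts (contact
#' matrices are symmetric; dumps of them vary in orientation).
#'
#' @param df data.frame with columns `chrom, start1, end1, start2, end2,
#'   count` (one chromosome column: contacts are intra-chromosomal).
#' @param resolution bin width in bp; every anchor must be one bin wide and
#'   start on a multiple of the resolution.
#' @return an object of class `contact_set`.
#' @export
contact_set <- function(df, resolution) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start1", "end1", "start2", "end2", "count")
  if (!all(need %in% names(df)))
    stop("contact data.frame needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0 ||
      resolution != floor(resolution))
    stop("resolution must be a positive integer (bp)")
  resolution <- as.integer(resolution)
  df <- df[, need]
  if (nrow(df) > 0) {
    w1 <- df$end1 - df$start1
    w2 <- df$end2 - df$start2
    bad <- which(w1 != resolution | w2 != resolution)
    if (length(bad) > 0)
      stop("anchor width != resolution (", resolution, " bp) at row ", bad[1])
    bad <- which(df$start1 %% resolution != 0 | df$start2 %% resolution != 0)
    if (length(bad) > 0)
      stop("bin start not a multiple of the resolution at row ", bad[1])
    bad <- which(!is.finite(df$count) | df$count < 1 |
                   df$count != floor(df$count))
    if (length(bad) > 0)
      stop("count must be a positive integer at row ", bad[1])
    # normalize orientation: anchor1 is the leftmost bin
    swap <- df$start1 > df$start2
    if (any(swap)) {
      tmp <- df$start1[swap]
      df$start1[swap] <- df$start2[swap]
      df$start2[swap] <- tmp
      tmp <- df$end1[swap]
      df$end1[swap] <- df$end2[swap]
      df$end2[swap] <- tmp
    }
    # de-duplicate identical pairs by summing counts
    key <- paste(df$chrom, df$start1, df$start2, sep = ":")
    if (anyDuplicated(key)) {
      cnt <- tapply(df$count, key, sum)
      df <- df[!duplicated(key), ]
      df$count <- as.vector(cnt[paste(df$chrom, df$start1, df$start2,
                                      sep = ":")])
    }
    df <- df[order(df$chrom, df$start1, df$start2), ]
    rownames(df) <- NULL
  }
  structure(list(resolution = resolution, contacts = df,
                 by_chrom = split(seq_len(nrow(df)), df$chrom)),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("Contact set:", nrow(x$contacts), "intra-chromosomal contacts on",
      length(x$by_chrom), "chromosome(s) at", x$resolution, "bp resolution\n")
  invisible(x)
}

#' Read binned contacts from a BEDPE file
#'
#' Expects at least 7 tab-separated columns: `chrom1, start1, end1, chrom2,
#' start2, end2, count` (0-based half-open bins, raw integer counts in
#' column 7). Only intra-chromosomal rows are kept; inter-chromosomal rows
#' are dropped with a logged count, or rejected when `trans = "error"` —
#' the spatial regions of this model are defined per gene on the gene's own
#' chromosome.
#'
#' @param path BEDPE path.
#' @param resolution bin width in bp (the `HiC_resolution` of the
#'   experiment); every anchor must match it.
#' @param trans `"drop"` (default) or `"error"` for inter-chromosomal rows.
#' @return a [contact_set()].
#' @export
read_bedpe <- function(path, resolution, trans = c("drop", "error")) {
  trans <- match.arg(trans)
  if (!file.exists(path)) stop("BEDPE not found: ", path)
  if (length(readLines(path, n = 1L)) == 0) {
    # an empty file is a legal (contact-free) experiment
    return(contact_set(data.frame(chrom = character(0), start1 = integer(0),
                                  end1 = integer(0), start2 = integer(0),
                                  end2 = integer(0), count = integer(0)),
                       resolution))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("BEDPE needs >= 7 columns (count in column 7)")
  names(df)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "count")
  inter <- df$chrom1 != df$chrom2
  if (any(inter)) {
    if (trans == "error")
      stop("inter-chromosomal contact at row ", which(inter)[1])
    message("read_bedpe: dropped ", sum(inter), " inter-chromosomal contact(s)")
    df <- df[!inter, , drop = FALSE]
  }
  contact_set(data.frame(chrom = df$chrom1, start1 = df$start1,
                         end1 = df$end1, start2 = df$start2, end2 = df$end2,
                         count = df$count, stringsAsFactors = FALSE),
              resolution)
}

#' Write a contact set back to BEDPE
#'
#' @param cs a [contact_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(cs, path) {
  stopifnot(inherits(cs, "contact_set"))
  d <- cs$contacts
  out <- data.frame(d$chrom, d$start1, d$end1, d$chrom, d$start2, d$end2,
                    d$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Query contacts anchored in an interval
#'
#' Returns every contact with at least one anchor overlapping the half-open
#' interval `[start, end)` (strict half-open overlap: `anchor_start < end`
#' and `anchor_end > start`). A contact is returned once even if both
#' anchors overlap. An unknown chromosome yields an empty result, not an
#' error, since contact experiments routinely lack coverage on some
#' chromosomes.
#'
#' @param cs a [contact_set()].
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open, `start < end`.
#' @return data.frame of matching contacts (possibly 0 rows).
#' @export
query_anchored <- function(cs, chrom, start, end) {
  stopifnot(inherits(cs, "contact_set"))
  if (!(start < end)) stop("query interval must satisfy start < end")
  idx <- cs$by_chrom[[chrom]]
  empty <- cs$contacts[0, , drop = FALSE]
  if (is.null(idx)) return(empty)
  d <- cs$contacts[idx, , drop = FALSE]
  hit <- (d$start1 < end & d$end1 > start) | (d$start2 < end & d$end2 > start)
  out <- d[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
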