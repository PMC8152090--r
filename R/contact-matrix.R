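#' Binned chromatin contact matrix
#'
#' Container for a symmetric, non-negative contact count matrix for one
#' chromosome at a fixed bin size, together with the genomic metadata needed
#' to map bin indices back to coordinates.
#'
#' @param counts numeric matrix of contact counts; must be square, finite and
#'   non-negative. Dense inputs that are only approximately symmetric are
#'   symmetrized as `(X + t(X)) / 2`; a warning is issued if the maximal
#'   relative asymmetry exceeds `1e-6`.
#' @param chrom chromosome identifier, e.g. `"chr1"`.
#' @param bin_size bin width in base pairs (positive integer).
#' @param start_offset genomic coordinate (bp) of the left edge of bin 0.
#'
#' @return An object of class `contact_matrix`: a list with elements
#'   `counts`, `chrom`, `bin_size`, `start_offset` and `n_bins`. Bin indices
#'   are 0-based to match genomic coordinate conventions.
#' @export
#' @examples
#' m <- contact_matrix(matrix(c(10, 4, 4, 8), 2), "chr1", 25000)
#' m$n_bins
contact_matrix <- function(counts, chrom = "chr1", bin_size = 1L,
                           start_offset = 0L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square, got ", nrow(counts), "x", ncol(counts))
  }
  if (nrow(counts) < 2L) stop("contact matrix needs at least 2 bins")
  if (any(!is.finite(counts))) stop("contact matrix contains NaN/Inf values")
  if (any(counts < 0)) stop("contact matrix contains negative counts")
  if (bin_size < 1) stop("bin_size must be a positive integer")
  if (start_offset < 0) stop("start_offset must be non-negative")
  asym <- max(abs(counts - t(counts)))
  scale <- max(abs(counts), 1e-300)
  if (asym / scale > 1e-6) {
    warning("input matrix asymmetric (max relative deviation ",
            format(asym / scale, digits = 3), "); symmetrizing as (X + t(X))/2")
  }
  counts <- (counts + t(counts)) / 2
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, chrom = as.character(chrom),
         bin_size = as.integer(bin_size),
         start_offset = as.integer(start_offset),
         n_bins = nrow(counts)),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  nz <- sum(x$counts[upper.tri(x$counts, diag = TRUE)] != 0)
  tot <- x$n_bins * (x$n_bins + 1) / 2
  cat(sprintf("Contact matrix: %s, %d bins of %s bp (offset %d)\n",
              x$chrom, x$n_bins, format(x$bin_size, big.mark = ","),
              x$start_offset))
  cat(sprintf("  non-zero upper-triangle entries: %d / %d (%.1f%%)\n",
              nz, tot, 100 * nz / tot))
  invisible(x)
}

# coerce a contact_matrix or plain matrix to a plain numeric matrix
as_counts <- function(x) {
  if (inherits(x, "contact_matrix")) x$counts else as.matrix(x)
}

#' Read a contact matrix from a text file
#'
#' Supports the two plain-text layouts in common use for single-chromosome
#' dumps: sparse triples (`start1 TAB start2 TAB count`, upper or either
#' triangle, missing pairs are zero) and whitespace-delimited dense square
#' matrices.
#'
#' @param path file to read.
#' @param format `"triple"` or `"dense"`.
#' @param bin_size bin width in bp (required for triple format).
#' @param chrom chromosome identifier stored in the result.
#' @param start_offset coordinate of bin 0's left edge; triple coordinates
#'   must be `start_offset + i * bin_size` for integer `i >= 0`.
#' @param n_bins matrix dimension; if `NULL` (triple format) it is inferred
#'   from the largest coordinate seen.
#' @param coords `"bp"` if triple coordinates are bin left edges in base
#'   pairs (the usual dump dialect), `"bin"` if they are 0-based bin indices.
#'
#' @details Triple files may list a pair as `(i, j)`, `(j, i)`, or both; when
#' both orientations are present their counts must agree. Listing the same
#' orientation twice is an error. Dense inputs are symmetrized on load (see
#' [contact_matrix()]).
#'
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("triple", "dense"),
                                bin_size = NULL, chrom = "chr1",
                                start_offset = 0L, n_bins = NULL,
                                coords = c("bp", "bin")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    x <- as.matrix(utils::read.table(path, header = FALSE))
    if (is.null(bin_size)) bin_size <- 1L
    return(contact_matrix(x, chrom, bin_size, start_offset))
  }
  if (is.null(bin_size)) stop("bin_size is required for triple format")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty triple file: ", path)
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 0L) != 3L)
  if (length(bad)) {
    stop("malformed triple at line ", bad[1L], ": expected 3 fields, got ",
         length(parts[[bad[1L]]]))
  }
  rec <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 3L, byrow = TRUE)
  bad <- which(!stats::complete.cases(rec))
  if (length(bad)) stop("malformed triple at line ", bad[1L], ": non-numeric field")
  if (any(rec[, 3L] < 0)) {
    stop("negative count at line ", which(rec[, 3L] < 0)[1L])
  }
  if (coords == "bp") {
    off <- rec[, 1:2, drop = FALSE] - start_offset
    idx <- off / bin_size
    ong <- abs(idx - round(idx)) < 1e-9 & off >= 0
    if (any(!ong)) {
      stop("coordinate not on the bin grid at line ", which(!apply(ong, 1, all))[1L],
           " (bin_size ", bin_size, ", offset ", start_offset, ")")
    }
    idx <- round(idx)
  } else {
    idx <- rec[, 1:2, drop = FALSE]
    if (any(idx != round(idx)) || any(idx < 0)) {
      stop("bin indices must be non-negative integers")
    }
  }
  i <- pmin(idx[, 1L], idx[, 2L])
  j <- pmax(idx[, 1L], idx[, 2L])
  if (is.null(n_bins)) n_bins <- max(j) + 1L
  if (max(j) + 1L > n_bins) stop("coordinate exceeds declared n_bins")
  key <- paste(idx[, 1L], idx[, 2L])
  if (anyDuplicated(key)) {
    stop("duplicate entry for pair at line ", which(duplicated(key))[1L])
  }
  # both orientations may appear, but then must agree
  ukey <- paste(i, j)
  dup <- duplicated(ukey)
  if (any(dup)) {
    for (kk in unique(ukey[dup])) {
      v <- rec[ukey == kk, 3L]
      if (max(v) - min(v) > 1e-9 * max(abs(v), 1)) {
        stop("conflicting counts for mirrored pair (", kk, ")")
      }
    }
  }
  x <- matrix(0, n_bins, n_bins)
  x[cbind(i + 1L, j + 1L)] <- rec[, 3L]
  x[cbind(j + 1L, i + 1L)] <- rec[, 3L]
  contact_matrix(x, chrom, bin_size, start_offset)
}

#' Write a contact matrix to a text file
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @param format `"triple"` writes only non-zero upper-triangle entries as
#'   `start1 TAB start2 TAB count` with bp coordinates; `"dense"` writes the
#'   full square matrix, whitespace-delimited.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path, format = c("triple", "dense")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "contact_matrix"))
  if (format == "dense") {
    utils::write.table(m$counts, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  df <- data.frame(
    s1 = m$start_offset + (ut[, 1L] - 1L) * m$bin_size,
    s2 = m$start_offset + (ut[, 2L] - 1L) * m$bin_size,
    count = m$counts[ut])
  utils::write.table(format(df, scientific = FALSE, trim = TRUE,
                            digits = 15),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write TAD intervals as BED
#'
#' Coordinates follow the BED convention: 0-based, half-open. A TAD covering
#' inclusive bins `[start_bin, end_bin]` becomes the interval
#' `[offset + start_bin * bin_size, offset + (end_bin + 1) * bin_size)`; the
#' name column carries the cluster id.
#'
#' @param tads data frame with columns `start_bin`, `end_bin`, `cluster_id`
#'   (as returned by [clusters_to_tads()]).
#' @param path output file.
#' @param chrom,bin_size,start_offset genomic metadata of the source matrix.
#' @return `path`, invisibly.
#' @export
write_tads_bed <- function(tads, path, chrom = "chr1", bin_size = 1L,
                           start_offset = 0L) {
  stopifnot(all(c("start_bin", "end_bin", "cluster_id") %in% names(tads)))
  if (any(tads$start_bin > tads$end_bin) || any(tads$start_bin < 0)) {
    stop("invalid TAD intervals")
  }
  ord <- order(tads$start_bin)
  tads <- tads[ord, , drop = FALSE]
  if (nrow(tads) > 1L &&
      any(tads$start_bin[-1L] <= tads$end_bin[-nrow(tads)])) {
    stop("overlapping TAD intervals")
  }
  bed <- data.frame(
    chrom = chrom,
    start = start_offset + tads$start_bin * bin_size,
    end = start_offset + (tads$end_bin + 1L) * bin_size,
    name = tads$cluster_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals into TAD intervals on the bin grid
#'
#' Inverse of [write_tads_bed()] for interval files whose bounds lie on the
#' bin grid.
#'
#' @inheritParams write_tads_bed
#' @param path BED file (first four columns: chrom, start, end, name).
#' @return data frame with `start_bin`, `end_bin`, `cluster_id`.
#' @export
read_tads_bed <- function(path, chrom = "chr1", bin_size = 1L,
                          start_offset = 0L) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  bed <- bed[bed[, 1L] == chrom, , drop = FALSE]
  data.frame(
    start_bin = as.integer((bed[, 2L] - start_offset) / bin_size),
    end_bin = as.integer((bed[, 3L] - start_offset) / bin_size) - 1L,
    cluster_id = bed[, 4L])
}

#' Mark bins overlapping intervals from a BED file
#'
#' Builds a per-bin 0/1 indicator of binding events (ChIP-seq peaks,
#' accessible motif sites, ...) for enrichment analyses: a bin is marked if
#' its half-open span `[left, right)` overlaps any interval by at least 1 bp.
#'
#' @param path BED-like file; columns 1-3 are chrom, start, end (0-based,
#'   half-open). Intervals on other chromosomes are skipped with a warning.
#' @param chrom,bin_size,start_offset,n_bins bin grid of the paired matrix.
#' @return integer vector of length `n_bins` with values in `{0, 1}`.
#' @export
read_bed_annotation <- function(path, chrom, bin_size, n_bins,
                                start_offset = 0L) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (any(bed[, 3L] <= bed[, 2L])) {
    stop("interval with start >= end at line ", which(bed[, 3L] <= bed[, 2L])[1L])
  }
  other <- bed[, 1L] != chrom
  if (any(other)) {
    warning(sum(other), " interval(s) on other chromosomes skipped")
    bed <- bed[!other, , drop = FALSE]
  }
  ind <- integer(n_bins)
  if (nrow(bed)) {
    # first and last bin overlapped by each interval, clipped to the grid
    b0 <- pmax(0, floor((bed[, 2L] - start_offset) / bin_size))
    b1 <- pmin(n_bins - 1, floor((bed[, 3L] - 1 - start_offset) / bin_size))
    for (r in seq_along(b0)) {
      if (b1[r] >= 0 && b0[r] <= n_bins - 1 && b0[r] <= b1[r]) {
        ind[(b0[r]:b1[r]) + 1L] <- 1L
      }
    }
  }
  ind
}
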