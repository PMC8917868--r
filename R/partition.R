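## Genome partitioning from peak calls and per-partition RPKM
## quantification.  Coordinates follow the GRanges convention (1-based,
## closed) in memory and the BED convention (0-based, half-open) on disk;
## rtracklayer performs the conversion at the IO boundary.

#' Partition the genome from per-experiment peak calls
#'
#' The union of all peaks is cut at every peak boundary from every
#' experiment (the disjoint covered segments).  Covered segments shorter
#' than `min_size` are then merged: scanning left to right, a short segment
#' merges into the contiguous preceding covered segment if one exists,
#' otherwise into the contiguous following one; an isolated short segment is
#' kept and padded symmetrically to `min_size`, clipped at chromosome ends.
#' The result covers exactly the per-base union of all peaks (up to the
#' padding of isolated short segments).
#'
#' @param peak_sets A list of [GenomicRanges::GRanges] peak sets (one per
#'   experiment), or a single GRanges.
#' @param min_size Minimum partition size in bp (default 200).
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   clip padded segments.
#' @return A `GRanges` of partitions, sorted, non-overlapping, with a
#'   metadata column `region_id` ("P1", "P2", ...) and a logical `clipped`
#'   flag for segments padded but clipped at a chromosome end.
#' @export
partition_genome <- function(peak_sets, min_size = 200L, seqlengths = NULL) {
  if (min_size < 1) stopf("min_size must be >= 1")
  if (is(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  peaks <- suppressWarnings(do.call(c, unname(lapply(peak_sets, function(g) {
    g <- GenomicRanges::granges(g)
    if (any(IRanges::width(g) < 1)) stopf("malformed interval: start >= end")
    g
  }))))
  if (!length(peaks)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$region_id <- character(0)
    S4Vectors::mcols(out)$clipped <- logical(0)
    return(out)
  }
  GenomicRanges::strand(peaks) <- "*"
  segs <- GenomicRanges::disjoin(peaks)           # covered segments cut at all boundaries
  segs <- GenomicRanges::sort(segs)
  blocks <- GenomicRanges::reduce(peaks)          # contiguous covered blocks
  hit <- GenomicRanges::findOverlaps(segs, blocks, select = "first")

  out_list <- list()
  for (b in unique(hit)) {
    s <- segs[hit == b]
    st <- GenomicRanges::start(s); en <- GenomicRanges::end(s)
    i <- 1L
    keep_st <- c(); keep_en <- c()
    for (i in seq_along(s)) {
      w <- en[i] - st[i] + 1L
      if (w >= min_size || length(s) == 1L) {
        keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i])
      } else if (length(keep_st)) {
        keep_en[length(keep_en)] <- en[i]          # merge into predecessor
      } else if (i < length(s)) {
        st[i + 1L] <- st[i]                        # merge into follower
      } else {
        keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i])
      }
    }
    ## predecessor merges can still leave the first kept segment short if the
    ## block is shorter than min_size overall; re-check isolated case
    chrom <- as.character(GenomicRanges::seqnames(s)[1])
    for (j in seq_along(keep_st)) {
      w <- keep_en[j] - keep_st[j] + 1L
      clipped <- FALSE
      if (w < min_size && length(keep_st) == 1L) {
        pad <- min_size - w
        left <- pad %/% 2L; right <- pad - left
        keep_st[j] <- keep_st[j] - left
        keep_en[j] <- keep_en[j] + right
        if (keep_st[j] < 1L) { keep_st[j] <- 1L; clipped <- TRUE }
        lim <- if (!is.null(seqlengths) && chrom %in% names(seqlengths))
          seqlengths[[chrom]] else NA
        if (!is.na(lim) && keep_en[j] > lim) { keep_en[j] <- lim; clipped <- TRUE }
      }
      out_list[[length(out_list) + 1L]] <-
        data.frame(chrom = chrom, start = keep_st[j], end = keep_en[j],
                   clipped = clipped)
    }
  }
  df <- do.call(rbind, out_list)
  out <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  out <- GenomicRanges::sort(out)
  ord <- GenomicRanges::order(out)
  S4Vectors::mcols(out)$region_id <- paste0("P", seq_along(out))
  S4Vectors::mcols(out)$clipped <- df$clipped[ord]
  out
}

#' RPKM quantification of read placements over a partition set
#'
#' Each read is counted in the partition containing its 5' end (strand
#' aware: the `start` of a `+`/`*` read, the `end` of a `-` read).  RPKM for
#' region r and experiment e is
#' `count(r, e) * 1e9 / (width_bp(r) * total_mapped(e))`.
#'
#' @param reads Named list of `GRanges`, one per experiment (strand used for
#'   the 5'-end rule).
#' @param partitions `GRanges` from [partition_genome()] with a `region_id`
#'   column.
#' @param total_mapped Named numeric vector of total mapped reads per
#'   experiment; must be positive.  Defaults to `lengths(reads)`.
#' @return A numeric matrix (partitions x experiments) of RPKM values, row
#'   names = region ids.  Reads on chromosomes absent from the partitions
#'   are skipped with a warning.
#' @export
quantify_rpkm <- function(reads, partitions, total_mapped = NULL) {
  if (is.null(names(reads)))
    names(reads) <- paste0("experiment", seq_along(reads))
  if (is.null(total_mapped))
    total_mapped <- vapply(reads, length, 0L)
  if (any(total_mapped <= 0)) stopf("total_mapped must be positive")
  widths <- GenomicRanges::width(partitions)
  out <- matrix(0, length(partitions), length(reads),
                dimnames = list(S4Vectors::mcols(partitions)$region_id,
                                names(reads)))
  known <- GenomicRanges::seqnames(partitions)
  for (e in seq_along(reads)) {
    g <- reads[[e]]
    neg <- as.logical(GenomicRanges::strand(g) == "-")
    pos5 <- ifelse(neg, GenomicRanges::end(g), GenomicRanges::start(g))
    pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                  IRanges::IRanges(pos5, width = 1))
    unknown <- !(as.character(GenomicRanges::seqnames(pts)) %in%
                   as.character(unique(known)))
    if (any(unknown)) {
      warnf("%d read(s) on chromosomes absent from the partition set in %s; skipped",
            sum(unknown), names(reads)[e])
      pts <- pts[!unknown]
    }
    cnt <- GenomicRanges::countOverlaps(partitions, pts)
    nm <- names(reads)[e]
    tm <- if (!is.null(names(total_mapped)) && nm %in% names(total_mapped))
      total_mapped[[nm]] else total_mapped[[e]]
    out[, e] <- cnt * 1e9 / (widths * tm)
  }
  out
}

#' Read a MACS2 narrowPeak or BED file as peaks
#'
#' @param path Path to a BED3/BED6 or narrowPeak (BED6+4) file.
#' @return A `GRanges`.
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L)
  ncol <- length(strsplit(first, "\t")[[1]])
  if (ncol >= 10) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    rtracklayer::import(path, format = "BED", extraCols = extra)
  } else {
    rtracklayer::import(path, format = "BED")
  }
}

#' Write a partition set as BED4 (region id in the name column)
#'
#' @param partitions `GRanges` with `region_id` metadata.
#' @param path Output path.
#' @export
write_partitions <- function(partitions, path) {
  g <- GenomicRanges::granges(partitions)
  S4Vectors::mcols(g)$name <- S4Vectors::mcols(partitions)$region_id
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}
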