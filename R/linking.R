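## Nearest-TSS linking of genome partitions to genes, DNA x RNA linked
## metaclusters (LMs), and spatial x temporal joint-membership matrices.

#' Validate / normalize a gene-model table
#'
#' Gene models are plain data.frames with columns `gene_id`, `chrom`, `tss`
#' (1-based position) and `strand` (`+`/`-`).
#' @noRd
check_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes)))
    stopf("gene models need columns: %s", paste(need, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  genes
}

#' Nearest gene to each region by TSS distance
#'
#' For every region, the gene on the same chromosome minimizing the absolute
#' distance between the region midpoint and the gene TSS, provided that
#' distance does not exceed `max_distance`; ties are broken by the
#' lexicographically smaller gene id.
#'
#' @param regions `GRanges` with a `region_id` metadata column.
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param max_distance Maximum midpoint-to-TSS distance in bp (default 1e6).
#' @return Data.frame: `region_id`, `gene_id` (`NA` when no gene is within
#'   range or the chromosome carries no genes), `distance`.
#' @export
nearest_gene <- function(regions, genes, max_distance = 1e6) {
  genes <- check_gene_models(genes)
  mid <- floor((GenomicRanges::start(regions) + GenomicRanges::end(regions)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out_gene <- rep(NA_character_, length(regions))
  out_dist <- rep(NA_real_, length(regions))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    ## order by tss then gene_id so that equidistant flanking genes resolve
    ## to the lexicographically smaller id deterministically
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    pos <- findInterval(mid[idx], g$tss)
    for (j in seq_along(idx)) {
      cand <- unique(pmin(pmax(c(pos[j], pos[j] + 1L), 1L), nrow(g)))
      dd <- abs(mid[idx[j]] - g$tss[cand])
      keep <- which(dd == min(dd))
      if (length(keep) > 1)
        keep <- keep[order(g$gene_id[cand[keep]])][1]
      if (dd[keep] <= max_distance) {
        out_gene[idx[j]] <- g$gene_id[cand[keep]]
        out_dist[idx[j]] <- dd[keep]
      }
    }
  }
  data.frame(region_id = S4Vectors::mcols(regions)$region_id,
             gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}

#' Link DNA and RNA metaclusters through nearest genes
#'
#' Every region is assigned its nearest gene (midpoint-to-TSS, capped at
#' `max_distance`); each (region, gene) pair lands in the bin
#' `(RNA metacluster of the gene, DNA metacluster of the region)`.  All
#' `k_rna * k_dna` bins are enumerated; empty bins are retained.  Pairs whose
#' gene carries no RNA metacluster are dropped and counted.
#'
#' @param region_mc Data.frame mapping `item` (region id) to `metacluster`
#'   (DNA), as from [assign_items_to_metaclusters()].
#' @param gene_mc Data.frame mapping `item` (gene id) to `metacluster` (RNA).
#' @param regions `GRanges` with `region_id`.
#' @param genes Gene-model data.frame.
#' @param k_rna,k_dna Total metacluster counts (default: max label seen).
#' @param max_distance Linking window in bp (default 1e6).
#' @return An `lm_map` object: `pairs` (data.frame `rna_mc`, `dna_mc`,
#'   `region_id`, `gene_id`, `distance`), `counts` (`k_rna x k_dna` matrix),
#'   `k_rna`, `k_dna`, `n_bins`, `n_dropped`.
#' @export
link_soms <- function(region_mc, gene_mc, regions, genes,
                      k_rna = NULL, k_dna = NULL, max_distance = 1e6) {
  k_rna <- as.integer(k_rna %||% max(gene_mc$metacluster))
  k_dna <- as.integer(k_dna %||% max(region_mc$metacluster))
  nn <- nearest_gene(regions, genes, max_distance)
  dna_of <- setNames(region_mc$metacluster, region_mc$item)
  rna_of <- setNames(gene_mc$metacluster, gene_mc$item)
  if (!all(nn$region_id %in% names(dna_of)))
    stopf("every region must carry a DNA metacluster")
  linked <- nn[!is.na(nn$gene_id), , drop = FALSE]
  has_rna <- linked$gene_id %in% names(rna_of)
  n_dropped <- sum(!has_rna)
  linked <- linked[has_rna, , drop = FALSE]
  pairs <- data.frame(rna_mc = as.integer(rna_of[linked$gene_id]),
                      dna_mc = as.integer(dna_of[linked$region_id]),
                      region_id = linked$region_id,
                      gene_id = linked$gene_id,
                      distance = linked$distance,
                      stringsAsFactors = FALSE)
  counts <- matrix(0L, k_rna, k_dna,
                   dimnames = list(paste0("R", seq_len(k_rna)),
                                   paste0("D", seq_len(k_dna))))
  if (nrow(pairs)) {
    tab <- table(factor(pairs$rna_mc, levels = seq_len(k_rna)),
                 factor(pairs$dna_mc, levels = seq_len(k_dna)))
    counts[] <- as.integer(tab)
  }
  structure(list(pairs = pairs, counts = counts, k_rna = k_rna,
                 k_dna = k_dna, n_bins = k_rna * k_dna,
                 n_dropped = n_dropped),
            class = "lm_map")
}

#' @export
print.lm_map <- function(x, ...) {
  cat(sprintf("Linked metacluster map: %d x %d = %d LMs, %d (region, gene) pairs\n",
              x$k_rna, x$k_dna, x$n_bins, nrow(x$pairs)))
  invisible(x)
}

#' Joint membership of genes in two clusterings
#'
#' Count matrix of genes shared between each spatial metacluster and each
#' full-RNA metacluster, over the shared gene universe; rows and columns are
#' ordered by average-linkage hierarchical clustering (1 - Pearson) of the
#' count vectors.
#'
#' @param spatial_mc Data.frame `item` -> `metacluster` (spatial clustering).
#' @param full_mc Data.frame `item` -> `metacluster` (full clustering).
#' @return List with `counts` (spatial x full matrix), `fraction`
#'   (rows divided by spatial cluster sizes) and `row_order` / `col_order`.
#' @export
joint_membership <- function(spatial_mc, full_mc) {
  sp <- setNames(spatial_mc$metacluster, spatial_mc$item)
  fu <- setNames(full_mc$metacluster, full_mc$item)
  shared <- intersect(names(sp), names(fu))
  ks <- sort(unique(spatial_mc$metacluster))
  kf <- sort(unique(full_mc$metacluster))
  counts <- matrix(0L, length(ks), length(kf),
                   dimnames = list(paste0("sR", ks), paste0("R", kf)))
  if (length(shared)) {
    tab <- table(factor(sp[shared], levels = ks),
                 factor(fu[shared], levels = kf))
    counts[] <- as.integer(tab)
  }
  sizes <- as.vector(table(factor(spatial_mc$metacluster, levels = ks)))
  frac <- counts / ifelse(sizes == 0, 1, sizes)
  row_order <- order_by_similarity(counts)
  col_order <- order_by_similarity(t(counts))
  list(counts = counts, fraction = frac,
       row_order = row_order, col_order = col_order)
}

## leaf order of the average-linkage (1 - Pearson) tree over matrix rows;
## degenerate cases fall back to the natural order
order_by_similarity <- function(m) {
  if (nrow(m) < 3 || ncol(m) < 2) return(seq_len(nrow(m)))
  cc <- suppressWarnings(cor(t(m)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hclust(as.dist(1 - cc), method = "average")$order
}
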