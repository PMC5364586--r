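#' Build CpG clusters from probed site coordinates
#'
#' Groups probed CpG sites into clusters by flanking-region overlap: each site
#' extends `flank_bp` bases up- and downstream, and two adjacent sites belong
#' to the same cluster when their flanking regions share at least one base
#' (merging is transitive along a chromosome).  Clusters retaining fewer than
#' `min_probes` sites are discarded.  The resulting intervals are the unit
#' features for reference fitting, simulation, and inference.
#'
#' Coordinates are 0-based.  Two sites at distance `d` merge iff
#' `d <= 2 * flank_bp`; the emitted cluster interval is half-open,
#' `[max(0, min(pos) - flank_bp), max(pos) + flank_bp)`.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based integer) and
#'   optionally `probe_id`.  Must be sorted by position within each
#'   chromosome, with each chromosome forming one contiguous block.
#' @param flank_bp flanking region size in bases (default 100).
#' @param min_probes minimum number of probed sites per cluster (default 3).
#' @return data.frame with columns `cluster_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `site_count`, sorted and non-overlapping within
#'   each chromosome.
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = c(1000L, 1150L, 1300L))
#' build_clusters(sites)
#' @export
build_clusters <- function(sites, flank_bp = 100L, min_probes = 3L) {
  validate_sites(sites)
  if (nrow(sites) == 0L) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      site_count = integer(), stringsAsFactors = FALSE))
  }
  flank_bp <- as.integer(flank_bp)
  # 1-based closed flank intervals; merge only true overlaps (gap <= 2*flank)
  fl <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = pmax(sites$pos - flank_bp, 0L) + 1L,
                     end = sites$pos + flank_bp + 1L))
  red <- GenomicRanges::reduce(fl, min.gapwidth = 0L)
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(pts, red)
  grp <- S4Vectors::subjectHits(hit)
  cnt <- tabulate(grp, nbins = length(red))
  pos_min <- rep(NA_integer_, length(red))
  pos_max <- rep(NA_integer_, length(red))
  agg_min <- tapply(sites$pos, grp, min)
  agg_max <- tapply(sites$pos, grp, max)
  idx <- as.integer(names(agg_min))
  pos_min[idx] <- as.integer(agg_min)
  pos_max[idx] <- as.integer(agg_max)
  keep <- which(cnt >= min_probes)
  chrom <- as.character(GenomicRanges::seqnames(red))[keep]
  start <- pmax(pos_min[keep] - flank_bp, 0L)
  end <- pos_max[keep] + flank_bp
  data.frame(cluster_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = chrom, start = start, end = end,
             site_count = cnt[keep], stringsAsFactors = FALSE)
}

validate_sites <- function(sites, path = NULL) {
  where <- if (is.null(path)) "site table" else path
  if (!all(c("chrom", "pos") %in% names(sites)))
    stop(where, ": site table needs columns 'chrom' and 'pos'", call. = FALSE)
  if (nrow(sites) == 0L) return(invisible(sites))
  if (any(sites$pos < 0L))
    stop(where, ": column 'pos': negative coordinate", call. = FALSE)
  blocks <- rle(as.character(sites$chrom))$values
  if (anyDuplicated(blocks))
    stop(where, ": chromosome blocks are not contiguous; ",
         "sort sites by (chrom, pos)", call. = FALSE)
  bad <- which(diff(sites$pos) <= 0 &
                 sites$chrom[-1] == sites$chrom[-nrow(sites)])
  if (length(bad))
    stop(where, ": line ", bad[1] + 2L, ", column 'pos': sites are not ",
         "sorted (or not unique) within chromosome '",
         sites$chrom[bad[1]], "'", call. = FALSE)
  invisible(sites)
}

#' Cluster-level methylation from array site levels
#'
#' Averages the per-site methylation levels of one cluster.  The cluster value
#' is `NA` when strictly more than half of the sites are missing; with an even
#' number of sites, exactly half missing still yields a value.
#'
#' @param levels numeric vector of site methylation levels in `[0, 1]`, `NA`
#'   allowed; one entry per probed site of the cluster.
#' @return the mean of the non-`NA` levels, or `NA`.
#' @examples
#' cluster_level_from_array(c(0.2, 0.8, NA))   # 0.5
#' cluster_level_from_array(c(0.2, NA, NA))    # NA
#' @export
cluster_level_from_array <- function(levels) {
  n_na <- sum(is.na(levels))
  if (n_na * 2L > length(levels)) return(NA_real_)
  mean(levels, na.rm = TRUE)
}

#' Cluster-level methylation from bisulfite counts
#'
#' The methylation level of a cluster in sequencing data is the ratio of
#' methylated to total cytosines mapped to it, reported as `NA` when the
#' total is below a usability floor (default 30 cytosines).
#'
#' @param m methylated cytosine count(s), `0 <= m <= n`.
#' @param n total cytosine count(s).
#' @param min_total minimum total count for a usable level (default 30).
#' @return numeric vector of levels in `[0, 1]`, `NA` where `n < min_total`.
#' @examples
#' cluster_level_from_counts(15, 30)  # 0.5
#' cluster_level_from_counts(10, 29)  # NA
#' @export
cluster_level_from_counts <- function(m, n, min_total = 30L) {
  if (any(m < 0 | n < 0 | m > n))
    stop("counts must satisfy 0 <= m <= n", call. = FALSE)
  ifelse(n >= min_total, m / n, NA_real_)
}

#' Aggregate site-level array data to cluster level
#'
#' Maps each probed site to its containing cluster and applies
#' [cluster_level_from_array()] per cluster and sample.  Sites outside every
#' cluster are ignored; the missingness rule counts only the sites a cluster
#' actually contains.
#'
#' @param sites site table (`chrom`, `pos`), one row per row of `site_levels`.
#' @param site_levels numeric matrix (sites x samples) of levels, `NA` allowed.
#' @param clusters cluster table from [build_clusters()].
#' @return matrix (clusters x samples) of cluster methylation levels with
#'   `rownames` set to `cluster_id`.
#' @export
aggregate_array_levels <- function(sites, site_levels, clusters) {
  site_levels <- as.matrix(site_levels)
  stopifnot(nrow(sites) == nrow(site_levels))
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  cl <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start + 1L,
                                                clusters$end))
  hit <- GenomicRanges::findOverlaps(pts, cl)
  out <- matrix(NA_real_, nrow(clusters), ncol(site_levels),
                dimnames = list(clusters$cluster_id, colnames(site_levels)))
  qh <- S4Vectors::queryHits(hit)
  sh <- S4Vectors::subjectHits(hit)
  sp <- split(qh, sh)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    out[i, ] <- apply(site_levels[sp[[nm]], , drop = FALSE], 2,
                      cluster_level_from_array)
  }
  out
}
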