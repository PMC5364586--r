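# Tabular formats: everything is TSV with a header row; genomic coordinates
# follow the BED convention (0-based, half-open); missing values serialize as
# the literal string "NA".  Numeric round-trips are bit-exact ("%.17g").

io_stop <- function(path, line, column, msg) {
  stop(sprintf("%s: line %d, column '%s': %s", path, line, column, msg),
       call. = FALSE)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) stop(path, ": no such file", call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = colClasses,
                   comment.char = "#")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read and write CpG site tables
#'
#' A site table has columns `chrom`, `pos` (0-based) and optionally
#' `probe_id`, sorted by position within contiguous chromosome blocks.
#' Unsorted or duplicated coordinates are rejected on read.
#'
#' @param path file path.
#' @param sites data.frame as returned by [read_sites()].
#' @return `read_sites()` returns the validated data.frame; the writers
#'   return `path` invisibly.
#' @export
read_sites <- function(path) {
  df <- read_tsv(path, c("chrom", "pos"))
  if (nrow(df)) {
    pos <- suppressWarnings(as.integer(df$pos))
    bad <- which(is.na(pos))
    if (length(bad))
      io_stop(path, bad[1] + 1L, "pos", "not an integer coordinate")
    df$pos <- pos
  }
  validate_sites(df, path = path)
  df
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  write_tsv(sites, path)
}

#' Read and write cluster tables
#'
#' Cluster tables carry `cluster_id`, `chrom`, `start`, `end` (0-based
#' half-open) and `site_count`.  [write_clusters_bed()] exports a BED5 file
#' (`chrom`, `start`, `end`, `name`, `score` = site count).
#'
#' @param path file path.
#' @param clusters data.frame from [build_clusters()].
#' @export
read_clusters <- function(path) {
  df <- read_tsv(path, c("cluster_id", "chrom", "start", "end", "site_count"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$site_count <- as.integer(df$site_count)
  bad <- which(!(df$start < df$end))
  if (length(bad)) io_stop(path, bad[1] + 1L, "end", "start must be < end")
  df
}

#' @rdname read_clusters
#' @export
write_clusters <- function(clusters, path) write_tsv(clusters, path)

#' @rdname read_clusters
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    clusters$cluster_id, clusters$site_count)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write sequencing-style cluster count profiles
#'
#' A count profile has columns `cluster_id`, `meth_count`, `total_count`
#' with `0 <= meth_count <= total_count`; it is the inference input for one
#' plasma sample.
#'
#' @param path file path.
#' @param profile data.frame with the three columns above.
#' @export
read_seq_profile <- function(path) {
  df <- read_tsv(path, c("cluster_id", "meth_count", "total_count"))
  for (col in c("meth_count", "total_count")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) io_stop(path, bad[1] + 1L, col, "not an integer count")
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) io_stop(path, bad[1] + 1L, col, "negative or missing count")
    df[[col]] <- v
  }
  bad <- which(df$meth_count > df$total_count)
  if (length(bad))
    io_stop(path, bad[1] + 1L, "meth_count",
            "methylated count exceeds total count")
  if (anyDuplicated(df$cluster_id))
    stop(path, ": duplicated cluster_id", call. = FALSE)
  df
}

#' @rdname read_seq_profile
#' @export
write_seq_profile <- function(profile, path) {
  stopifnot(all(c("cluster_id", "meth_count", "total_count") %in%
                  names(profile)))
  if (any(profile$meth_count > profile$total_count))
    stop("meth_count exceeds total_count", call. = FALSE)
  write_tsv(profile[c("cluster_id", "meth_count", "total_count")], path)
}

#' Read and write array-style methylation level matrices
#'
#' A level matrix stores per-cluster methylation levels in `[0, 1]` (or `NA`)
#' for a collection of reference samples: first column `cluster_id`, then one
#' column per sample.  Sample class membership lives in a separate two-column
#' manifest (`sample_id`, `class_label`).
#'
#' @param path file path.
#' @param levels numeric matrix (clusters x samples) with `rownames` =
#'   cluster ids and `colnames` = sample ids.
#' @param manifest data.frame with columns `sample_id`, `class_label`.
#' @return `read_level_matrix()` returns such a matrix.
#' @export
read_level_matrix <- function(path) {
  df <- read_tsv(path, "cluster_id")
  ids <- df$cluster_id
  m <- as.matrix(df[setdiff(names(df), "cluster_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    io_stop(path, bad[1, 1] + 1L, colnames(m)[bad[1, 2]],
            "methylation level outside [0, 1]")
  m
}

#' @rdname read_level_matrix
#' @export
write_level_matrix <- function(levels, path) {
  body <- matrix(fmt_num(levels), nrow(levels), ncol(levels),
                 dimnames = list(NULL, colnames(levels)))
  df <- data.frame(cluster_id = rownames(levels), body,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname read_level_matrix
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path, c("sample_id", "class_label"))
  df$sample_id <- as.character(df$sample_id)
  df$class_label <- as.character(df$class_label)
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicated sample_id", call. = FALSE)
  df
}

#' @rdname read_level_matrix
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(manifest[c("sample_id", "class_label")], path)
}

#' Serialize a fitted reference panel
#'
#' Panels round-trip bit-exactly through a TSV with `#key=value` header lines
#' (class names, selection cutoff) followed by one row per cluster: interval,
#' site count, methylation range, selection flag, and the per-class beta
#' parameters `alpha_<class>` / `beta_<class>`.
#'
#' @param panel a `meth_panel` from [build_panel()].
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "meth_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#class_names=%s", paste(panel$class_names, collapse = ",")),
    sprintf("#mr_cutoff=%s", fmt_num(panel$mr_cutoff)),
    sprintf("#min_samples=%d", panel$min_samples)), con)
  cl <- panel$clusters
  df <- data.frame(cluster_id = cl$cluster_id, chrom = cl$chrom,
                   start = cl$start, end = cl$end,
                   site_count = cl$site_count,
                   mr = fmt_num(panel$mr[cl$cluster_id]),
                   selected = as.integer(cl$cluster_id %in% panel$selected),
                   stringsAsFactors = FALSE)
  for (i in seq_along(panel$class_names)) {
    cn <- panel$class_names[i]
    df[[paste0("alpha_", cn)]] <- fmt_num(panel$alpha[cl$cluster_id, i])
    df[[paste0("beta_", cn)]] <- fmt_num(panel$beta[cl$cluster_id, i])
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, sub("^#", "", ln))
  }
  close(con)
  kv <- strsplit(hdr, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  class_names <- strsplit(meta[["class_names"]], ",", fixed = TRUE)[[1]]
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  K <- nrow(df)
  C <- length(class_names)
  alpha <- matrix(NA_real_, K, C,
                  dimnames = list(df$cluster_id, class_names))
  beta <- alpha
  for (i in seq_len(C)) {
    alpha[, i] <- df[[paste0("alpha_", class_names[i])]]
    beta[, i] <- df[[paste0("beta_", class_names[i])]]
  }
  new_meth_panel(
    clusters = df[c("cluster_id", "chrom", "start", "end", "site_count")],
    class_names = class_names,
    alpha = alpha, beta = beta,
    mr = setNames(df$mr, df$cluster_id),
    selected = df$cluster_id[df$selected == 1L],
    mr_cutoff = as.numeric(meta[["mr_cutoff"]]),
    min_samples = as.integer(meta[["min_samples"]]))
}
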