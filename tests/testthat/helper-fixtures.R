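# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# brute-force oracle for cluster building: merge all closed +/-flank
# intervals by position flooding, then count contained sites
oracle_clusters <- function(sites, flank = 100L, min_probes = 3L) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    pos <- sort(sites$pos[sites$chrom == ch])
    grp <- cumsum(c(1L, as.integer(diff(pos) > 2L * flank)))
    for (g in split(pos, grp)) {
      if (length(g) < min_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = max(min(g) - flank, 0L), end = max(g) + flank,
        site_count = length(g), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), site_count = integer()))
  do.call(rbind, out)
}

random_site_table <- function(n_sites = 30L, n_chrom = 2L) {
  chrom <- sort(sample(sprintf("chr%d", seq_len(n_chrom)), n_sites,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(i)
    sort(sample.int(5000L, length(i)))))
  data.frame(chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# small synthetic reference + fitted panel, cached per session
small_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_reference(T_classes = 3L, K_total = 240L,
                                   pool_size = 40L, seed = 424L)
    cache
  }
})

small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- small_reference()
      cache <<- build_panel(ref$levels, ref$manifest, ref$clusters)
    }
    cache
  }
})

# scenario over the selected features of a panel, drawing from a reference
make_scenario <- function(ref, panel, ...) {
  sel <- panel$selected
  norm_ids <- ref$manifest$sample_id[ref$manifest$class_label == "normal"]
  pools <- lapply(panel$class_names[-1], function(cl)
    ref$levels[sel, ref$manifest$sample_id[ref$manifest$class_label == cl],
               drop = FALSE])
  names(pools) <- panel$class_names[-1]
  sim_scenario(ref$levels[sel, norm_ids, drop = FALSE], pools,
               ref$clusters, ...)
}

# Monte-Carlo oracle for the per-cluster marginal likelihood
mc_cluster_lik <- function(m, n, theta, normal, tumor, R = 1e5) {
  v <- rbeta(R, normal[1], normal[2])
  u <- rbeta(R, tumor[1], tumor[2])
  w <- dbinom(m, n, (1 - theta) * v + theta * u)
  list(mean = mean(w), se = sd(w) / sqrt(R))
}
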