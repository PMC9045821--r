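# Hierarchical clustering of single-molecule modification profiles and of
# raw event means: Ward's method on Euclidean distances throughout.

#' Cluster modification profiles
#'
#' Ward (ward.D2) hierarchical clustering on Euclidean distances between
#' full-length modification profiles. Reads that do not cover every site
#' are removed first.
#'
#' @param matrix `mod_profile_matrix`
#' @return a `mod_dendrogram`: list(hclust, reads, n)
#' @export
cluster_profiles <- function(matrix) {
  matrix <- filter_full_coverage(matrix)
  m <- matrix$probs
  if (nrow(m) < 2) stop("need at least 2 complete reads to cluster")
  rownames(m) <- NULL
  hc <- hclust(dist(m), method = "ward.D2")
  structure(list(hclust = hc, reads = matrix$reads, n = nrow(m)),
            class = "mod_dendrogram")
}

#' @export
print.mod_dendrogram <- function(x, ...) {
  cat(sprintf("mod_dendrogram: %d reads, Ward/Euclidean\n", x$n))
  invisible(x)
}

#' Per-sample cluster fractions at a dendrogram cut
#'
#' Cuts the dendrogram into N clusters and reports, for each sample, the
#' fraction of its reads falling in each cluster. Cluster ids are stable:
#' numbered by first appearance in dendrogram leaf order.
#'
#' @param dendro `mod_dendrogram`
#' @param N number of clusters (1 <= N <= number of reads)
#' @param sample_labels optional per-read sample labels (default the
#'   matrix's recorded samples)
#' @return list(assignments = data.frame(read_id, sample, cluster),
#'   fractions = sample x cluster matrix with rows summing to 1)
#' @export
cluster_fractions <- function(dendro, N, sample_labels = NULL) {
  if (N < 1 || N > dendro$n) stop("N must lie in [1, #reads]")
  raw <- cutree(dendro$hclust, k = N)
  # relabel by first appearance along the leaf order
  leaf_seq <- raw[dendro$hclust$order]
  relabel <- setNames(seq_along(unique(leaf_seq)), unique(leaf_seq))
  cluster <- unname(relabel[as.character(raw)])
  sample <- sample_labels %||% dendro$reads$sample
  sample[is.na(sample)] <- "all"
  assignments <- data.frame(read_id = dendro$reads$read_id, sample = sample,
                            cluster = cluster, stringsAsFactors = FALSE)
  tab <- table(sample, factor(cluster, levels = seq_len(N)))
  fractions <- sweep(unclass(tab), 1, rowSums(tab), "/")
  list(assignments = assignments, fractions = fractions)
}

#' Standardized event-mean matrix over a reference region
#'
#' The raw-signal cross-check for closely spaced modification clusters:
#' for each read the whole-read signal is z-standardized and event means
#' are assigned to reference slots along the maximum expected accuracy
#' path (multi-event slots averaged); reads missing any slot in the region
#' are dropped; the pooled matrix is standardized by column and clustered
#' with Ward/Euclidean like the probability profiles.
#'
#' @param reads list of `event_seq`
#' @param table `kmer_table`
#' @param branch_map contig `branch_map`
#' @param region c(start, end): reference slot window to extract
#' @param params `hmm_params`
#' @param sample label for the reads
#' @return list(matrix = reads x slots standardized event means,
#'   reads = data.frame(read_id, sample), region, dendrogram)
#' @export
event_mean_matrix <- function(reads, table, branch_map, region,
                              params = hmm_params(), sample = NA_character_) {
  region <- as.integer(region)
  slots_wanted <- region[1]:region[2]
  cache <- new.env(parent = emptyenv())
  rows <- list(); ids <- character(0); kept <- integer(0)
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    key <- paste(read$start, read$end)
    if (is.null(cache[[key]]))
      cache[[key]] <- slot_model(branch_map, table, c(read$start, read$end), params)
    model <- cache[[key]]
    res <- tryCatch({
      nrm <- normalize_events(read, model)
      post <- forward_backward(nrm$read, model, want_gamma = FALSE)
      if (post$failed) stop("alignment failed")
      post
    }, error = function(e) NULL)
    if (is.null(res)) next
    # whole-read standardization of the raw event means
    z <- (read$means - mean(read$means)) / sd(read$means)
    path <- mea_path(res)
    mt <- path$kind == "match"
    slot_means <- tapply(z[path$event[mt]], path$slot[mt], mean)
    got <- as.integer(names(slot_means))
    if (!all(slots_wanted %in% got)) next
    rows[[length(rows) + 1L]] <- as.numeric(slot_means[as.character(slots_wanted)])
    ids <- c(ids, read$read_id)
    kept <- c(kept, ri)
  }
  if (!length(rows)) stop("no reads cover the requested region completely")
  if (length(sample) > 1) sample <- sample[kept]
  m <- do.call(rbind, rows)
  m <- scale(m)          # column standardization: mean 0, sd 1
  attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  colnames(m) <- slots_wanted
  dendro <- if (nrow(m) >= 2) {
    structure(list(hclust = hclust(dist(m), method = "ward.D2"),
                   reads = data.frame(read_id = ids, sample = sample,
                                      stringsAsFactors = FALSE),
                   n = nrow(m)), class = "mod_dendrogram")
  } else NULL
  list(matrix = m,
       reads = data.frame(read_id = ids, sample = sample, stringsAsFactors = FALSE),
       region = region, dendrogram = dendro)
}

#' Event means assigned to one kmer above a posterior threshold
#'
#' Collects normalized event means whose posterior alignment probability to
#' the given kmer exceeds `min_prob`; suitable for a kernel density overlay
#' against the kmer's model Gaussian.
#'
#' @param posteriors list of `posterior_table` (from normalized reads)
#' @param kmer the kmer string (extended alphabet)
#' @param normalized_reads the corresponding normalized `event_seq` list
#' @param min_prob posterior threshold (default 0.5)
#' @return numeric vector of event means (possibly empty)
#' @export
events_per_kmer <- function(posteriors, kmer, normalized_reads, min_prob = 0.5) {
  out <- numeric(0)
  for (i in seq_along(posteriors)) {
    post <- posteriors[[i]]
    if (post$failed) next
    g <- post$gamma
    model <- post$model
    is_kmer <- vapply(seq_len(nrow(g)), function(t)
      model$variants[[g$slot[t]]][g$variant[t]] == kmer, logical(1))
    if (!any(is_kmer)) next
    # per-event posterior mass on this kmer, summed over slots
    mass <- tapply(g$prob[is_kmer], g$event[is_kmer], sum)
    ev <- as.integer(names(mass))[mass > min_prob]
    out <- c(out, normalized_reads[[i]]$means[ev])
  }
  out
}
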