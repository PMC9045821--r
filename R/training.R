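# Supervised iterative estimation of modified/canonical emission Gaussians
# from labelled read sets. Labels are per-dataset: every callable site is
# treated as modified in the "modified" set and canonical in the "canonical"
# set, so each read aligns against a label-fixed (single-variant) model.

#' Training configuration
#'
#' @param rounds training iterations (default 30)
#' @param reads_per_class reads used from each labelled set per round
#'   (default 500)
#' @param mad_scaling `"raw"` (sd = raw MAD, default) or `"consistent"`
#'   (MAD x 1.4826, the Gaussian-consistent estimator)
#' @param min_pool minimum pooled events for a kmer to be re-estimated in a
#'   round; below this the previous parameters are carried forward
#' @param sd_floor lower bound on a trained level_sd (pA)
#' @param seed optional RNG seed used when subsampling reads
#' @return a `training_config` list
#' @export
training_config <- function(rounds = 30L, reads_per_class = 500L,
                            mad_scaling = c("raw", "consistent"),
                            min_pool = 10L, sd_floor = 0.05, seed = NULL) {
  if (rounds < 0) stop("rounds must be >= 0")
  if (reads_per_class < 1) stop("reads_per_class must be >= 1")
  structure(list(rounds = as.integer(rounds),
                 reads_per_class = as.integer(reads_per_class),
                 mad_scaling = match.arg(mad_scaling),
                 min_pool = as.integer(min_pool), sd_floor = sd_floor,
                 seed = seed),
            class = "training_config")
}

# Collapse a branch map to a single fixed label per site: "modified" keeps
# only the modification character at every callable site, "canonical" only
# the reference base. The result has exactly one variant per slot.
label_branch_map <- function(branch_map, label = c("modified", "canonical")) {
  label <- match.arg(label)
  bm <- branch_map
  if (label == "modified" && nrow(bm$sites)) {
    for (i in seq_len(nrow(bm$sites)))
      bm$allowed[[bm$sites$position[i]]] <- bm$sites$mod_char[i]
  } else {
    chars <- strsplit(bm$seq, "")[[1]]
    for (i in seq_len(nrow(bm$sites)))
      bm$allowed[[bm$sites$position[i]]] <- chars[bm$sites$position[i]]
  }
  k <- bm$k
  n_slots <- length(bm$slots)
  ch <- vapply(bm$allowed, `[[`, "", 1)
  full <- paste(ch, collapse = "")
  bm$slots <- lapply(seq_len(n_slots), function(j) substr(full, j, j + k - 1L))
  bm
}

# Normalized event means per kmer from one read's MEA path. After the
# initial distribution-matching normalization and alignment, the per-read
# affine transform is re-fitted against the model levels of the assigned
# kmers (trimmed least squares over matched (level, raw mean) pairs), which
# removes most of the residual per-read scale error before pooling.
pool_read_events <- function(read, model, min_gamma = 0.5) {
  nrm <- normalize_events(read, model)
  post <- forward_backward(nrm$read, model, want_gamma = FALSE)
  if (post$failed) return(NULL)
  path <- post$mea_path
  # only confidently assigned events enter the pools: an event whose slot
  # assignment carries little posterior mass is likely contamination from a
  # neighbouring kmer
  m <- path$kind == "match" & !is.na(path$prob) & path$prob >= min_gamma
  if (!any(m)) return(NULL)
  kmers <- vapply(path$slot[m], function(j) model$variants[[j]][1], "")
  x_raw <- read$means[path$event[m]]
  lv <- model$mu[model$v_off[path$slot[m]] + 1L]
  shift <- nrm$shift; scale <- nrm$scale
  res <- x_raw - (shift + scale * lv)
  keep <- abs(res) <= quantile(abs(res), 0.9)
  if (sum(keep) >= 8 && length(unique(lv[keep])) > 2) {
    fit <- stats::lsfit(lv[keep], x_raw[keep])
    if (is.finite(fit$coefficients[2]) && fit$coefficients[2] > 0) {
      shift <- unname(fit$coefficients[1])
      scale <- unname(fit$coefficients[2])
    }
  }
  list(kmer = kmers, mean = (x_raw - shift) / scale)
}

#' Train modification-branch emission Gaussians
#'
#' Iterative supervised training. Each round aligns every read against its
#' label-fixed model (modified reads carry the modification character at
#' every callable site, canonical reads the reference base), takes the
#' maximum expected accuracy event-to-kmer assignments, pools normalized
#' event means per kmer, and re-estimates mean = median and sd = MAD of the
#' pool for every kmer touching a modification branch point. Kmers outside
#' branch points are never touched; a branch kmer whose pool is smaller than
#' `cfg$min_pool` keeps its previous parameters (with a warning).
#'
#' @param modified_reads,canonical_reads lists of `event_seq` (fully
#'   modified / fully canonical labelled sets)
#' @param table starting `kmer_table` (canonical + derived branch kmers)
#' @param branch_map the contig's `branch_map`
#' @param cfg `training_config`
#' @param params `hmm_params`
#' @return list(table = trained `kmer_table`, log = per-round data.frame
#'   with max |delta mean|, mean pool size, and n kmers updated)
#' @export
train_emissions <- function(modified_reads, canonical_reads, table, branch_map,
                            cfg = training_config(), params = hmm_params()) {
  if (cfg$rounds == 0L) return(list(table = table, log = data.frame()))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  take <- function(reads) {
    if (length(reads) > cfg$reads_per_class) reads[seq_len(cfg$reads_per_class)]
    else reads
  }
  modified_reads <- take(modified_reads)
  canonical_reads <- take(canonical_reads)

  # kmers eligible for re-estimation: all variants of branched slots
  branched <- lengths(branch_map$slots) > 1
  branch_kmers <- unique(unlist(branch_map$slots[branched]))
  mad_const <- if (cfg$mad_scaling == "raw") 1 else 1.4826

  bm_mod <- label_branch_map(branch_map, "modified")
  bm_can <- label_branch_map(branch_map, "canonical")

  log_rows <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    model_cache_mod <- new.env(parent = emptyenv())
    model_cache_can <- new.env(parent = emptyenv())
    get_model <- function(bm, cache, interval) {
      key <- paste(interval, collapse = "-")
      if (is.null(cache[[key]]))
        cache[[key]] <- slot_model(bm, table, interval, params)
      cache[[key]]
    }
    chunks <- c(
      lapply(modified_reads, function(read)
        pool_read_events(read, get_model(bm_mod, model_cache_mod, c(read$start, read$end)))),
      lapply(canonical_reads, function(read)
        pool_read_events(read, get_model(bm_can, model_cache_can, c(read$start, read$end))))
    )
    chunks <- chunks[!vapply(chunks, is.null, TRUE)]
    all_kmers <- unlist(lapply(chunks, `[[`, "kmer"))
    all_means <- unlist(lapply(chunks, `[[`, "mean"))
    keep <- all_kmers %in% branch_kmers
    pools <- split(all_means[keep], all_kmers[keep])

    idx <- match(branch_kmers, table$kmer)
    deltas <- numeric(0); nupd <- 0L; pool_sizes <- integer(0); starved <- character(0)
    for (t in seq_along(branch_kmers)) {
      u <- branch_kmers[t]
      x <- pools[[u]]
      pool_sizes <- c(pool_sizes, length(x))
      if (length(x) < cfg$min_pool) { starved <- c(starved, u); next }
      new_mu <- median(x)
      new_sd <- max(mad(x, constant = mad_const), cfg$sd_floor)
      deltas <- c(deltas, abs(new_mu - table$level_mean[idx[t]]))
      table$level_mean[idx[t]] <- new_mu
      table$level_sd[idx[t]] <- new_sd
      table$provenance[idx[t]] <- "trained"
      nupd <- nupd + 1L
    }
    if (length(starved))
      warning(sprintf("round %d: %d branch kmer(s) with < %d events kept previous parameters",
                      r, length(starved), cfg$min_pool), call. = FALSE)
    log_rows[[r]] <- data.frame(round = r, n_updated = nupd,
                                max_delta_mean = if (length(deltas)) max(deltas) else 0,
                                mean_pool = mean(pool_sizes))
  }
  list(table = table, log = do.call(rbind, log_rows))
}
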