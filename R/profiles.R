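# Reads-by-sites modification probability matrices and classification
# metrics for calls against known states.

#' Construct a modification profile matrix
#'
#' @param probs numeric matrix, reads x sites, values in \[0,1\] or NA
#'   (missing = site not covered by the read)
#' @param reads data.frame(read_id, sample) or a character vector of ids
#' @param sites data.frame with contig, position (ordered); extra columns
#'   kept
#' @param meta optional per-read provenance (shift, scale, loglik)
#' @return a `mod_profile_matrix`
#' @export
mod_profile_matrix <- function(probs, reads, sites, meta = NULL) {
  probs <- as.matrix(probs)
  if (is.character(reads)) reads <- data.frame(read_id = reads,
                                               sample = NA_character_,
                                               stringsAsFactors = FALSE)
  if (!"sample" %in% names(reads)) reads$sample <- NA_character_
  if (nrow(probs) != nrow(reads)) stop("probs rows != reads")
  if (ncol(probs) != nrow(sites)) stop("probs cols != sites")
  if (any(!is.na(probs))) {
    rng <- range(probs, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("probabilities must lie in [0,1]")
  }
  o <- order(sites$contig, sites$position)
  structure(list(probs = probs[, o, drop = FALSE],
                 reads = reads[, c("read_id", "sample"), drop = FALSE],
                 sites = sites[o, , drop = FALSE], meta = meta),
            class = "mod_profile_matrix")
}

#' @export
print.mod_profile_matrix <- function(x, ...) {
  cat(sprintf("mod_profile_matrix: %d reads x %d sites, %.1f%% missing\n",
              nrow(x$probs), ncol(x$probs),
              100 * mean(is.na(x$probs))))
  invisible(x)
}

#' Call modification profiles for a set of reads
#'
#' Aligns each read with the variable-order HMM and decodes per-site
#' modification probabilities. Sites outside a read's mapped interval are
#' missing (NA). Reads whose alignment fails are dropped with a message.
#'
#' @param reads list of `event_seq`
#' @param table trained `kmer_table`
#' @param branch_map contig `branch_map`
#' @param sites `mod_sites`
#' @param params `hmm_params`
#' @param sample label recorded for these reads
#' @return `mod_profile_matrix` with per-read provenance (shift, scale,
#'   log-likelihood, full_length flag) in `$meta`
#' @export
call_reads <- function(reads, table, branch_map, sites, params = hmm_params(),
                       sample = NA_character_) {
  use <- sites[sites$callable & sites$contig == branch_map$contig, , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(reads))
  meta <- vector("list", length(reads))
  ok <- logical(length(reads))
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    key <- paste(read$start, read$end)
    if (is.null(cache[[key]]))
      cache[[key]] <- slot_model(branch_map, table, c(read$start, read$end), params)
    model <- cache[[key]]
    res <- tryCatch({
      nrm <- normalize_events(read, model)
      post <- forward_backward(nrm$read, model, want_mea = FALSE)
      if (post$failed) stop("no admissible alignment path")
      list(p = decode_site_probabilities(post, branch_map, use),
           shift = nrm$shift, scale = nrm$scale, loglik = post$loglik)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("read %s dropped: %s", read$read_id, conditionMessage(res)))
      next
    }
    rows[[i]] <- res$p
    meta[[i]] <- data.frame(read_id = read$read_id, shift = res$shift,
                            scale = res$scale, loglik = res$loglik,
                            full_length = read$start <= DEAD_ZONE_5PRIME + 1L,
                            stringsAsFactors = FALSE)
    ok[i] <- TRUE
  }
  probs <- do.call(rbind, rows[ok])
  if (is.null(probs)) probs <- matrix(NA_real_, 0, nrow(use))
  ids <- vapply(reads[ok], `[[`, "", "read_id")
  mod_profile_matrix(probs,
                     data.frame(read_id = ids, sample = sample,
                                stringsAsFactors = FALSE),
                     use, meta = do.call(rbind, meta[ok]))
}

#' Keep only reads covering every modification site
#'
#' @param matrix `mod_profile_matrix`
#' @return filtered matrix, row order preserved
#' @export
filter_full_coverage <- function(matrix) {
  keep <- complete.cases(matrix$probs)
  mod_profile_matrix(matrix$probs[keep, , drop = FALSE],
                     matrix$reads[keep, , drop = FALSE],
                     matrix$sites,
                     meta = if (is.null(matrix$meta)) NULL else
                       matrix$meta[keep, , drop = FALSE])
}

#' Per-site modification frequencies
#'
#' Fraction of non-missing probabilities strictly above the cutoff
#' (probability exactly at the cutoff counts as unmodified).
#'
#' @param matrix `mod_profile_matrix`
#' @param cutoff probability cutoff in (0,1), default 0.5
#' @return data.frame(contig, position, frequency, n); `frequency` is NA
#'   when a site has no calls (n = 0)
#' @export
site_frequencies <- function(matrix, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0,1)")
  n <- colSums(!is.na(matrix$probs))
  nmod <- colSums(matrix$probs > cutoff, na.rm = TRUE)
  data.frame(contig = matrix$sites$contig, position = matrix$sites$position,
             frequency = ifelse(n > 0, nmod / n, NA_real_), n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-based AUROC (Mann-Whitney with midranks)
#'
#' @param scores numeric scores
#' @param labels binary labels (TRUE/1 = positive)
#' @return AUROC in \[0,1\]; NA when one class is absent
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for modification calls
#'
#' Computes the ROC curve and AUROC (midrank), the precision-recall curve,
#' an equal-width-bin calibration table (predicted vs empirical modified
#' fraction) with the occupancy-weighted expected calibration error (`ece`),
#' the confusion matrix at the cutoff (strictly greater than counts as
#' modified), and balanced accuracy = (sensitivity + specificity) / 2.
#' When a `site` grouping is given, per-site balanced accuracies and their
#' average are included.
#'
#' @param probs modification probabilities
#' @param labels true states (TRUE/1 = modified)
#' @param cutoff probability cutoff (default 0.5)
#' @param bins number of equal-width calibration bins (default 10)
#' @param site optional per-observation site id for per-site balanced
#'   accuracy
#' @return a `metrics_bundle` list
#' @export
classification_metrics <- function(probs, labels, cutoff = 0.5, bins = 10L,
                                   site = NULL) {
  labels <- as.logical(labels)
  keep <- !is.na(probs) & !is.na(labels)
  probs <- probs[keep]; labels <- labels[keep]
  if (!is.null(site)) site <- site[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  single_class <- n1 == 0 || n0 == 0
  if (single_class)
    warning("single-class labels: AUROC undefined", call. = FALSE)

  thr <- sort(unique(probs), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probs >= t & labels), 0)
  fp <- vapply(thr, function(t) sum(probs >= t & !labels), 0)
  roc <- data.frame(threshold = c(Inf, thr),
                    tpr = c(0, if (n1) tp / n1 else NA), fpr = c(0, if (n0) fp / n0 else NA))
  pr <- data.frame(threshold = thr,
                   precision = ifelse(tp + fp > 0, tp / (tp + fp), NA),
                   recall = if (n1) tp / n1 else NA)

  brk <- seq(0, 1, length.out = bins + 1)
  bin <- cut(probs, brk, include.lowest = TRUE)
  calibration <- data.frame(bin = levels(bin),
                            predicted = as.numeric(tapply(probs, bin, mean)),
                            empirical = as.numeric(tapply(labels, bin, mean)),
                            n = as.integer(table(bin)))
  occupied <- !is.na(calibration$predicted)
  ece <- sum((abs(calibration$predicted - calibration$empirical) *
                calibration$n)[occupied]) / sum(calibration$n[occupied])

  pred <- probs > cutoff
  confusion <- matrix(c(sum(pred & labels), sum(pred & !labels),
                        sum(!pred & labels), sum(!pred & !labels)),
                      2, 2, dimnames = list(pred = c("modified", "canonical"),
                                            truth = c("modified", "canonical")))
  sens <- if (n1) confusion[1, 1] / n1 else NA
  spec <- if (n0) confusion[2, 2] / n0 else NA
  bundle <- list(auroc = if (single_class) NA_real_ else auroc(probs, labels),
                 roc = roc, pr = pr, calibration = calibration, ece = ece,
                 confusion = confusion, sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2, cutoff = cutoff)
  if (!is.null(site)) {
    ba <- vapply(split(seq_along(probs), site), function(ix) {
      l <- labels[ix]; p <- probs[ix] > cutoff
      s1 <- sum(l); s0 <- sum(!l)
      if (s1 == 0 || s0 == 0) return(NA_real_)
      (sum(p & l) / s1 + sum(!p & !l) / s0) / 2
    }, 0)
    bundle$site_balanced_accuracy <- ba
    bundle$average_balanced_accuracy <- mean(ba, na.rm = TRUE)
  }
  class(bundle) <- "metrics_bundle"
  bundle
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("metrics_bundle: AUROC %.3f, balanced accuracy %.3f at cutoff %.2f\n",
              x$auroc, x$balanced_accuracy, x$cutoff))
  invisible(x)
}
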