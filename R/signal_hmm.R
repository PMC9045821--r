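# Signal-space HMM: align a read's event sequence to a branchable reference
# window, decode per-site modification probabilities and the maximum expected
# accuracy event-to-kmer path.

#' HMM transition parameters
#'
#' Fixed transition probabilities of the event-alignment HMM. From a Match
#' state: stay (emit another event from the same kmer), step (next slot),
#' skip (jump a slot silently), insert_open (emit from the background
#' Gaussian); these must sum to 1. An open insert extends with probability
#' `insert_extend`, otherwise steps to the next slot. The background
#' (insert) emission is a broad Gaussian set from the canonical model levels
#' unless given explicitly.
#'
#' @param stay,step,skip,insert_open Match-state outgoing probabilities
#' @param insert_extend Insert self-transition probability
#' @param bg_mu,bg_sd background Gaussian (pA); `NULL` to derive from the
#'   kmer table (mean of canonical levels, 3x their spread)
#' @return an `hmm_params` list
#' @export
hmm_params <- function(stay = 0.3, step = 0.55, skip = 0.1, insert_open = 0.05,
                       insert_extend = 0.1, bg_mu = NULL, bg_sd = NULL) {
  p <- c(stay = stay, step = step, skip = skip, insert_open = insert_open)
  if (any(p <= 0) || any(p >= 1) || insert_extend <= 0 || insert_extend >= 1)
    stop("transition probabilities must lie in (0,1)")
  if (abs(sum(p) - 1) > 1e-8)
    stop("stay + step + skip + insert_open must sum to 1")
  structure(list(stay = stay, step = step, skip = skip,
                 insert_open = insert_open, insert_extend = insert_extend,
                 bg_mu = bg_mu, bg_sd = bg_sd),
            class = "hmm_params")
}

#' Construct an event sequence for one read
#'
#' Nanopore direct RNA reads are sequenced 3'->5'; events supplied in
#' sequencing order are reversed at construction so that all internal
#' processing runs in reference 5'->3' slot order.
#'
#' @param read_id read identifier
#' @param contig reference contig name
#' @param start,end mapped reference interval, 1-based inclusive
#' @param means event mean currents (pA)
#' @param spread,duration optional per-event spread (pA) and duration (s)
#' @param orientation `"3to5"` (sequencing order, default; reversed on
#'   construction) or `"5to3"`
#' @return an `event_seq` list
#' @export
event_seq <- function(read_id, contig, start, end, means,
                      spread = NULL, duration = NULL, orientation = "3to5") {
  means <- as.numeric(means)
  if (!length(means)) stop("a read needs at least one event")
  if (any(!is.finite(means))) stop("event means must be finite")
  if (start < 1 || end < start) stop("bad mapped interval")
  rev_it <- identical(orientation, "3to5")
  ord <- if (rev_it) rev(seq_along(means)) else seq_along(means)
  structure(list(read_id = read_id, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 means = means[ord],
                 spread = if (is.null(spread)) NULL else as.numeric(spread)[ord],
                 duration = if (is.null(duration)) NULL else as.numeric(duration)[ord]),
            class = "event_seq")
}

# ---------------------------------------------------------------------------
# Slot model: emission parameters + admissible variant transitions for a
# window of the branch map. Edges connect variants of consecutive slots that
# agree on their overlapping reference positions (the variable-order
# property); transition mass is split uniformly over the characters newly
# covered by the destination slot.

compatible_edges <- function(va, vb, overlap_a_from, overlap_b_len) {
  # va, vb: variant kmer strings of two slots; variant u of the source slot is
  # compatible with v of the destination slot when the source suffix equals
  # the destination prefix over the shared positions.
  k <- nchar(va[1])
  suf <- substr(va, overlap_a_from, k)
  pre <- substr(vb, 1, overlap_b_len)
  comp <- outer(suf, pre, "==")
  nsucc <- rowSums(comp)
  idx <- which(comp, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(from = integer(), to = integer(), lw = numeric()))
  o <- order(idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
             lw = -log(nsucc[idx[, 1]]))
}

#' Build the aligned slot model for a read window
#'
#' Collects, for slots `interval[1] .. interval[2] - k + 1` of the branch
#' map, the variant emission Gaussians and the admissible variant-to-variant
#' transitions used by the HMM.
#'
#' @param branch_map a `branch_map`
#' @param table a `kmer_table` containing every variant kmer
#' @param interval mapped reference interval c(start, end), 1-based
#'   inclusive; default the whole contig
#' @param params `hmm_params`
#' @return a `slot_model` list used by [forward_backward()]
#' @export
slot_model <- function(branch_map, table, interval = NULL, params = hmm_params()) {
  k <- branch_map$k
  L <- nchar(branch_map$seq)
  if (is.null(interval)) interval <- c(1L, L)
  s <- as.integer(interval[1]); e <- as.integer(interval[2])
  if (s < 1 || e > L || e - s + 1 < k) stop("mapped interval invalid or shorter than k")
  jmin <- s; jmax <- e - k + 1L
  slots <- branch_map$slots[jmin:jmax]
  S <- length(slots)
  nv <- lengths(slots)
  v_off <- c(0L, cumsum(nv))
  pars <- kmer_params(table, unlist(slots))
  step <- vector("list", S); skip <- vector("list", S)
  for (j in seq_len(S)) {
    if (j < S) step[[j]] <- compatible_edges(slots[[j]], slots[[j + 1]], 2L, k - 1L)
    if (j < S - 1) skip[[j]] <- compatible_edges(slots[[j]], slots[[j + 2]], 3L, k - 2L)
  }
  flat <- function(lst) {
    lst <- lapply(lst, function(d) if (is.null(d)) data.frame(from = integer(), to = integer(), lw = numeric()) else d)
    n <- vapply(lst, nrow, 0L)
    list(off = c(0L, cumsum(n)),
         from = as.integer(unlist(lapply(lst, `[[`, "from"))),
         to = as.integer(unlist(lapply(lst, `[[`, "to"))),
         lw = as.numeric(unlist(lapply(lst, `[[`, "lw"))))
  }
  st <- flat(step); sk <- flat(skip)
  canonical_levels <- pars$mu[v_off[-length(v_off)] + 1L]
  canon <- !grepl("[^ACGU]", table$kmer)
  bg_mu <- params$bg_mu %||% mean(table$level_mean[canon])
  bg_sd <- params$bg_sd %||% (3 * max(sd(table$level_mean[canon]), 1))
  structure(list(contig = branch_map$contig, k = k, interval = c(s, e),
                 slot_start = jmin, S = S, v_off = v_off,
                 mu = pars$mu, sd = pars$sd,
                 variants = slots,
                 st = st, sk = sk,
                 canonical_levels = canonical_levels,
                 params = params, bg = c(bg_mu, bg_sd)),
            class = "slot_model")
}

#' Normalize a read's events onto the model current scale
#'
#' Estimates a per-read affine distortion (shift in pA, dimensionless scale)
#' and returns the corrected read: normalized mean = (mean - shift) / scale.
#'
#' `method = "quantile"` (default) matches the sorted event means against
#' the quantiles of the model's predicted event distribution for the mapped
#' slots (the equal-weight Gaussian mixture over slot levels, which absorbs
#' the event-noise widening), by a trimmed least-squares line fit.
#' `method = "median_mad"` matches the median and MAD of the read's event
#' means to the median and MAD of the canonical model levels of the mapped
#' slots; it is simpler but biased upward in scale by the event noise.
#'
#' @param read an `event_seq`
#' @param model a `slot_model` for the read's mapped interval
#' @param method `"quantile"` or `"median_mad"`
#' @param trim central quantile range used by the quantile fit
#' @return list(shift, scale, read) with the normalized `event_seq`
#' @export
normalize_events <- function(read, model, method = c("quantile", "median_mad"),
                             trim = 0.05) {
  method <- match.arg(method)
  x <- read$means
  if (length(x) < 8) stop("need at least 8 events to normalize")
  if (mad(x, constant = 1) == 0) stop("constant event means; cannot normalize")
  lev <- model$canonical_levels
  if (mad(lev, constant = 1) == 0) stop("degenerate model levels")
  if (method == "median_mad") {
    scale <- mad(x, constant = 1) / mad(lev, constant = 1)
    shift <- median(x) - scale * median(lev)
  } else {
    # deterministic draw of the model's predicted event distribution:
    # per mapped slot, 7 Gaussian quantiles of the canonical variant
    sds <- model$sd[model$v_off[-length(model$v_off)] + 1L]
    qz <- qnorm((1:7 - 0.5) / 7)
    pred <- sort(as.vector(outer(qz, sds) + rep(lev, each = 7)))
    n <- length(x)
    probs <- (seq_len(n) - 0.5) / n
    keep <- probs >= trim & probs <= 1 - trim
    qx <- sort(x)[keep]
    qm <- quantile(pred, probs[keep], names = FALSE, type = 8)
    fit <- stats::lsfit(qm, qx)
    scale <- fit$coefficients[2]
    shift <- fit$coefficients[1] + 0 # intercept: x ~ shift + scale * model
    if (!is.finite(scale) || scale <= 0) stop("normalization failed: degenerate fit")
    names(scale) <- names(shift) <- NULL
  }
  read$means <- (x - shift) / scale
  list(shift = shift, scale = scale, read = read)
}

#' Forward-backward posterior decoding of one read
#'
#' Runs the variable-order HMM forward-backward recursion in log space and
#' returns the per-(event, slot, variant) posterior alignment mass together
#' with the read log-likelihood and the maximum expected accuracy path.
#' A read with no admissible path is returned as a failed alignment
#' (`failed = TRUE`), not an error.
#'
#' @param read normalized `event_seq` (see [normalize_events()])
#' @param model `slot_model` for the read's interval
#' @param gamma_min posterior mass below which entries are dropped from the
#'   sparse output (default 1e-10)
#' @param band_margin half-width (in slots) of the diagonal band around the
#'   linear event-to-slot interpolation; 0 disables banding. A banded
#'   alignment that fails is automatically retried unbanded.
#' @param want_gamma,want_mea compute the sparse posterior table / the MEA
#'   path (both by default; heavy callers disable what they do not need)
#' @return a `posterior_table`: list(read_id, loglik, failed, gamma, mea_path,
#'   mea_score, model)
#' @export
forward_backward <- function(read, model, gamma_min = 1e-10, band_margin = 40L,
                             want_gamma = TRUE, want_mea = TRUE) {
  p <- model$params
  run <- function(margin) {
    hmm_align_cpp(read$means, model$v_off, model$mu, model$sd,
                  model$st$off, model$st$from, model$st$to, model$st$lw,
                  model$sk$off, model$sk$from, model$sk$to, model$sk$lw,
                  c(p$stay, p$step, p$skip, p$insert_open, p$insert_extend),
                  model$bg, as.integer(margin), gamma_min, want_gamma, want_mea)
  }
  res <- run(band_margin)
  if (isTRUE(res$failed) && band_margin > 0) res <- run(0L)
  structure(list(read_id = read$read_id, loglik = res$loglik,
                 failed = isTRUE(res$failed),
                 gamma = res$gamma, mea_path = res$mea_path,
                 mea_score = res$mea_score,
                 n_events = length(read$means), model = model),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("posterior_table: read %s, %d events, loglik %.3f%s\n",
              x$read_id, x$n_events, x$loglik,
              if (x$failed) " (alignment FAILED)" else ""))
  invisible(x)
}

#' Decode per-site modification probabilities from a posterior table
#'
#' For each callable site, the probability of modification is the posterior
#' alignment mass on variants carrying the site's modification character
#' (over all slots covering the site), divided by the total mass on slots
#' covering the site. Sites not covered by the read (or with zero aligned
#' mass) are reported as `NA` (missing), never 0.
#'
#' @param post `posterior_table`
#' @param branch_map the `branch_map` the model was built from
#' @param sites `mod_sites` (callable rows used; others ignored)
#' @return named numeric vector of P(modified), names `contig:position`,
#'   `NA` for missing sites
#' @export
decode_site_probabilities <- function(post, branch_map, sites) {
  if (post$failed) stop("cannot decode a failed alignment")
  model <- post$model
  k <- model$k
  use <- sites[sites$callable & sites$contig == branch_map$contig, , drop = FALSE]
  out <- setNames(rep(NA_real_, nrow(use)),
                  paste0(use$contig, ":", use$position))
  g <- post$gamma
  # absolute slot index of each gamma entry
  abs_slot <- g$slot + model$slot_start - 1L
  for (i in seq_len(nrow(use))) {
    pos <- use$position[i]
    mc <- use$mod_char[i]
    cover <- which(abs_slot <= pos & abs_slot + k - 1L >= pos)
    if (!length(cover)) next
    denom <- sum(g$prob[cover])
    if (denom <= 0) next
    sl <- g$slot[cover]; va <- g$variant[cover]
    offset <- pos - (abs_slot[cover]) + 1L
    is_mod <- vapply(seq_along(cover), function(t) {
      substr(model$variants[[sl[t]]][va[t]], offset[t], offset[t]) == mc
    }, logical(1))
    out[i] <- sum(g$prob[cover][is_mod]) / denom
  }
  out
}

#' Maximum expected accuracy event-to-kmer path
#'
#' The admissible monotone path through the HMM maximizing the summed
#' posterior mass of its (event, slot, variant) Match assignments. Ties are
#' broken deterministically toward the smallest slot, then variant index.
#'
#' @param post `posterior_table`
#' @return data.frame(event, slot, variant, kind) with absolute slot indices;
#'   `kind` is "match" or "insert" (insert events carry no kmer assignment)
#' @export
mea_path <- function(post) {
  if (post$failed) stop("cannot extract a path from a failed alignment")
  path <- post$mea_path
  path$slot <- path$slot + post$model$slot_start - 1L
  path
}
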