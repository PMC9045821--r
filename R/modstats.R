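# Frequency-change and correlation statistics on modification profile
# matrices: per-site chi-square comparisons against replicated wild type,
# pairwise Spearman correlations between sites on the same molecule,
# Fisher-z comparison of correlations between samples, and Empirical
# Brown's method for combining dependent p-values.

site_counts <- function(matrix, cutoff = 0.5) {
  n <- colSums(!is.na(matrix$probs))
  nmod <- colSums(matrix$probs > cutoff, na.rm = TRUE)
  data.frame(contig = matrix$sites$contig, position = matrix$sites$position,
             n_mod = nmod, n = n, frequency = ifelse(n > 0, nmod / n, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

chisq_2x2_p <- function(a_mod, a_n, b_mod, b_n) {
  tab <- rbind(c(a_mod, a_n - a_mod), c(b_mod, b_n - b_mod))
  if (any(tab < 0) || a_n == 0 || b_n == 0) return(NA_real_)
  if (identical(tab[1, ], tab[2, ])) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  correct <- any(expected < 5)
  out <- suppressWarnings(chisq.test(tab, correct = correct))
  unname(out$p.value)
}

#' Per-site modification frequency change test
#'
#' For every site, 2x2 chi-square tests (modified/unmodified x sample)
#' compare each wild-type replicate against each experiment repeat. The
#' highest p-value over all pairs is kept (the most conservative comparison)
#' and corrected across sites per contig by Benjamini-Hochberg. A site is
#' flagged changed only when q < alpha, the minimum absolute frequency
#' difference over all pairs reaches the global cutoff (default 10%), and
#' that difference also exceeds the site's wild-type replicate range (batch
#' control). Continuity correction is applied automatically when any
#' expected cell count is below 5.
#'
#' @param expt_matrices list of >= 1 experiment `mod_profile_matrix`
#' @param wt_matrices list of wild-type replicate matrices (the study design
#'   uses 3)
#' @param alpha significance level (default 0.05)
#' @param global_cutoff minimum absolute frequency change (default 0.10)
#' @param cutoff probability cutoff for calling a molecule modified
#' @return data.frame, one row per site: frequencies, min |delta f|, max
#'   chi-square p, BH q, wt replicate range, pass flags and overall
#'   `changed`
#' @export
frequency_change_test <- function(expt_matrices, wt_matrices, alpha = 0.05,
                                  global_cutoff = 0.10, cutoff = 0.5) {
  if (inherits(expt_matrices, "mod_profile_matrix")) expt_matrices <- list(expt_matrices)
  if (inherits(wt_matrices, "mod_profile_matrix")) wt_matrices <- list(wt_matrices)
  wt <- lapply(wt_matrices, site_counts, cutoff = cutoff)
  ex <- lapply(expt_matrices, site_counts, cutoff = cutoff)
  ref <- wt[[1]][, c("contig", "position")]
  for (d in c(wt, ex))
    if (!identical(d[, c("contig", "position")], ref))
      stop("matrices do not share the same site set")
  n_sites <- nrow(ref)
  p_max <- delta_min <- wt_range <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    ps <- c(); dfs <- c()
    for (w in wt) for (x in ex) {
      ps <- c(ps, chisq_2x2_p(w$n_mod[i], w$n[i], x$n_mod[i], x$n[i]))
      dfs <- c(dfs, abs(w$frequency[i] - x$frequency[i]))
    }
    p_max[i] <- if (all(is.na(ps))) NA_real_ else max(ps, na.rm = TRUE)
    delta_min[i] <- if (all(is.na(dfs))) NA_real_ else min(dfs, na.rm = TRUE)
    wf <- vapply(wt, function(w) w$frequency[i], 0)
    wt_range[i] <- if (length(wf) > 1) max(dist(wf)) else 0
  }
  q <- rep(NA_real_, n_sites)
  for (ctg in unique(ref$contig)) {
    ix <- ref$contig == ctg
    q[ix] <- p.adjust(p_max[ix], method = "BH")
  }
  out <- data.frame(ref,
                    wt_frequency = rowMeans(do.call(cbind, lapply(wt, `[[`, "frequency"))),
                    expt_frequency = rowMeans(do.call(cbind, lapply(ex, `[[`, "frequency"))),
                    delta_min = delta_min, p_max = p_max, q = q,
                    wt_range = wt_range,
                    pass_q = !is.na(q) & q < alpha,
                    pass_global = !is.na(delta_min) & delta_min >= global_cutoff,
                    pass_wt_range = !is.na(delta_min) & delta_min >= wt_range,
                    stringsAsFactors = FALSE)
  out$changed <- out$pass_q & out$pass_global & out$pass_wt_range
  out
}

#' Pairwise Spearman correlation between modification sites
#'
#' Rank correlation of the per-read modification probabilities for every
#' pair of sites, on full-coverage reads. p-values from the two-sided
#' t-test t = rho * sqrt((n-2)/(1-rho^2)) with n-2 df; BH correction over
#' all pairs.
#'
#' @param matrix `mod_profile_matrix` (full-coverage filtering applied
#'   internally)
#' @return data.frame(site_i, site_j, rho, n, p, q); constant columns give
#'   NA rho/p (with one warning)
#' @export
pairwise_spearman <- function(matrix) {
  matrix <- filter_full_coverage(matrix)
  m <- matrix$probs
  n <- nrow(m)
  cols <- paste0(matrix$sites$contig, ":", matrix$sites$position)
  constant <- apply(m, 2, function(x) length(unique(x)) < 2)
  if (any(constant))
    warning("constant column(s): correlations undefined for ",
            paste(cols[constant], collapse = ", "), call. = FALSE)
  rho_mat <- suppressWarnings(cor(m, method = "spearman"))
  pairs <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[pairs]
  rho[constant[pairs[, 1]] | constant[pairs[, 2]]] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- ifelse(abs(rho) >= 1, 0, 2 * pt(-abs(tstat), df = n - 2))
  p[n < 4] <- NA_real_
  data.frame(site_i = cols[pairs[, 1]], site_j = cols[pairs[, 2]],
             rho = rho, n = n, p = p, q = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

fisher_z_p <- function(rho_a, n_a, rho_b, n_b) {
  z <- (atanh(rho_a) - atanh(rho_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  2 * pnorm(-abs(z))
}

#' Compare site-pair correlations between two samples
#'
#' Fisher z-transform test for a difference in Spearman correlation between
#' samples A (focal/experiment) and B (comparison, e.g. wild type), per
#' site pair, with BH correction over pairs within each repeat-by-repeat
#' comparison. With replicated inputs the reported difference is the one of
#' minimum magnitude and the reported q the maximum corrected p over all
#' A-repeat x B-repeat comparisons (the most conservative choice). A pair
#' is starred only when that q is below alpha and the pair's correlation is
#' also significantly different from zero in every focal-sample repeat.
#'
#' @param pairs_a,pairs_b output of [pairwise_spearman()] for each sample,
#'   or a list of such tables (replicates)
#' @param alpha significance level (default 0.05)
#' @return data.frame(site_i, site_j, rho_a, rho_b, delta_rho, p, q,
#'   q_zero_a, comparable, star)
#' @export
compare_correlations <- function(pairs_a, pairs_b, alpha = 0.05) {
  if (is.data.frame(pairs_a)) pairs_a <- list(pairs_a)
  if (is.data.frame(pairs_b)) pairs_b <- list(pairs_b)
  key <- paste(pairs_a[[1]]$site_i, pairs_a[[1]]$site_j)
  for (d in c(pairs_a, pairs_b))
    if (!identical(paste(d$site_i, d$site_j), key))
      stop("correlation tables do not share the same pair set")
  npair <- length(key)
  delta <- rep(NA_real_, npair); qmax <- rep(NA_real_, npair)
  comparable <- rep(TRUE, npair)
  for (a in pairs_a) for (b in pairs_b) {
    bad <- is.na(a$rho) | is.na(b$rho) | abs(a$rho) >= 1 | abs(b$rho) >= 1
    comparable <- comparable & !bad
    p <- ifelse(bad, NA_real_, fisher_z_p(a$rho, a$n, b$rho, b$n))
    qv <- p.adjust(p, method = "BH")
    d <- a$rho - b$rho
    upd <- !bad & (is.na(delta) | abs(d) < abs(delta))
    delta[upd] <- d[upd]
    qmax <- pmax(qmax, qv, na.rm = TRUE)
    qmax[bad] <- NA_real_
  }
  # zero test within the focal sample (all repeats must reject rho = 0)
  q_zero <- rep(-Inf, npair)
  for (a in pairs_a) {
    z0 <- atanh(pmin(pmax(a$rho, -1 + 1e-15), 1 - 1e-15)) * sqrt(a$n - 3)
    p0 <- 2 * pnorm(-abs(z0))
    q0 <- p.adjust(p0, method = "BH")
    q_zero <- pmax(q_zero, q0, na.rm = TRUE)
  }
  q_zero[!is.finite(q_zero)] <- NA_real_
  rho_a <- rowMeans(do.call(cbind, lapply(pairs_a, `[[`, "rho")))
  rho_b <- rowMeans(do.call(cbind, lapply(pairs_b, `[[`, "rho")))
  data.frame(site_i = pairs_a[[1]]$site_i, site_j = pairs_a[[1]]$site_j,
             rho_a = rho_a, rho_b = rho_b, delta_rho = delta,
             q = qmax, q_zero_a = q_zero, comparable = comparable,
             star = comparable & !is.na(qmax) & qmax < alpha &
               !is.na(q_zero) & q_zero < alpha,
             stringsAsFactors = FALSE)
}

#' Fisher z test for one pair of correlations
#'
#' Convenience closed form: two-sided p for the difference between two
#' correlations observed on independent samples of size `n_a` and `n_b`.
#'
#' @param rho_a,rho_b correlations
#' @param n_a,n_b sample sizes (> 3)
#' @return two-sided p-value
#' @export
fisher_z_test <- function(rho_a, n_a, rho_b, n_b) {
  if (any(abs(c(rho_a, rho_b)) >= 1)) stop("|rho| = 1: z transform infinite")
  if (n_a <= 3 || n_b <= 3) stop("need n > 3")
  fisher_z_p(rho_a, n_a, rho_b, n_b)
}

#' Fisher's method for combining independent p-values
#'
#' @param pvalues vector of p-values
#' @return combined p (upper chi-square tail with 2m df)
#' @export
fishers_method <- function(pvalues) {
  pvalues <- pmax(pvalues, .Machine$double.xmin)
  stat <- -2 * sum(log(pvalues))
  pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Empirical Brown's method for combining dependent p-values
#'
#' Extends Fisher's method to dependent tests. Each data column (the
#' per-read quantity underlying each test) is transformed to
#' w = -2 ln(empirical right-tail probability) through its empirical CDF;
#' the covariance of the transformed columns rescales the chi-square null:
#' with E = 2m and Var = 4m + 2 sum_{i<j} cov_ij, the combined statistic
#' sum(-2 ln p_i) / c is referred to a chi-square with f = 2E^2/Var degrees
#' of freedom, where c = Var/(2E). With `data = NULL` (or a single test)
#' the covariance is zero and the method reduces exactly to Fisher's.
#'
#' @param pvalues m p-values to combine
#' @param data reads x m matrix of the per-read quantities underlying each
#'   test (same column order), or NULL for independence
#' @return list(p, c, f, fisher_p)
#' @export
empirical_browns <- function(pvalues, data = NULL) {
  m <- length(pvalues)
  if (m < 1) stop("need at least one p-value")
  if (any(pvalues <= 0)) {
    warning("p-value(s) of 0 clipped to machine minimum", call. = FALSE)
    pvalues <- pmax(pvalues, .Machine$double.xmin)
  }
  stat <- -2 * sum(log(pvalues))
  expected <- 2 * m
  if (is.null(data) || m == 1) {
    cov_sum <- 0
  } else {
    data <- as.matrix(data)
    if (ncol(data) != m) stop("data must have one column per p-value")
    n <- nrow(data)
    w <- apply(data, 2, function(x) {
      right_tail <- (n - rank(x, ties.method = "max") + 1) / n
      -2 * log(right_tail)
    })
    cv <- cov(w)
    cov_sum <- sum(cv[upper.tri(cv)])
  }
  variance <- 4 * m + 2 * cov_sum
  f <- 2 * expected^2 / variance
  c_scale <- variance / (2 * expected)
  list(p = pchisq(stat / c_scale, df = f, lower.tail = FALSE),
       c = c_scale, f = f,
       fisher_p = pchisq(stat, df = 2 * m, lower.tail = FALSE))
}
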