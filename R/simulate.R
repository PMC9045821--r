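# Synthetic nanopore-signal generator with planted ground truth: reference,
# annotation, kmer model, event-level reads (stays/skips/inserts, per-read
# affine distortion, planted per-site modification states, subpopulation
# mixtures, copula-controlled pairwise correlation) and probability
# matrices that bypass the HMM.

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic study: a 300-nt contig
#' with 12 well-separated annotated sites, modified kmers shifted +3 pA at
#' 1 pA event noise (separations where calling is reliable but not
#' trivial), 500 reads per sample, geometric stays, rare skips and inserts,
#' and a mild per-read affine distortion. Two labelled samples mirror the
#' supervised training design: `modified` (every site modified on every
#' molecule, the fully modified positive) and `canonical` (in vitro
#' transcript-like, no modifications).
#'
#' @param seed RNG seed (reproducibility of the whole dataset)
#' @param contig_length reference length in nt
#' @param n_sites number of annotated sites
#' @param site_positions explicit positions (overrides n_sites); all must be
#'   beyond the 5' dead zone
#' @param k kmer length
#' @param level_range canonical kmer level range (pA), uniform
#' @param mod_shift modified-kmer level shift (pA)
#' @param noise_sd event noise around the kmer level (pA)
#' @param p_stay stay probability (extra events per slot ~ geometric)
#' @param p_skip probability a slot emits no event
#' @param p_insert probability of a background insert event after a slot
#' @param shift_range,scale_range per-read affine distortion (pA, unitless)
#' @param reads_per_sample reads per sample
#' @param samples named list: each sample is list(templates = matrix of
#'   per-site modification probabilities (populations x sites),
#'   weights = population mixture weights)
#' @param corr_targets optional data.frame(site_i, site_j, rho): target
#'   Spearman correlation between the binary states of two sites (Gaussian
#'   copula, calibrated so the binary correlation matches)
#' @param full_length_fraction fraction of reads covering the 5' terminus
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, contig_length = 300L, n_sites = 12L,
                       site_positions = NULL, k = 5L,
                       level_range = c(75, 125), mod_shift = 3, noise_sd = 1,
                       p_stay = 0.3, p_skip = 0.05, p_insert = 0.01,
                       shift_range = c(-5, 5), scale_range = c(0.95, 1.05),
                       reads_per_sample = 500L,
                       samples = NULL, corr_targets = NULL,
                       full_length_fraction = 1.0) {
  if (any(c(p_stay, p_skip, p_insert) < 0) || any(c(p_stay, p_skip, p_insert) >= 1))
    stop("event model probabilities must lie in [0,1)")
  if (full_length_fraction < 0 || full_length_fraction > 1)
    stop("full_length_fraction must lie in [0,1]")
  if (is.null(site_positions)) {
    lo <- DEAD_ZONE_5PRIME + 10L
    hi <- contig_length - k - 5L
    site_positions <- round(seq(lo, hi, length.out = n_sites))
  }
  site_positions <- as.integer(site_positions)
  if (any(site_positions <= DEAD_ZONE_5PRIME) || any(site_positions > contig_length))
    stop("site positions must lie beyond the 5' dead zone and inside the contig")
  n_sites <- length(site_positions)
  if (is.null(samples)) {
    samples <- list(
      modified = list(templates = matrix(1, 1, n_sites), weights = 1),
      canonical = list(templates = matrix(0, 1, n_sites), weights = 1)
    )
  }
  for (s in samples) {
    if (abs(sum(s$weights) - 1) > 1e-8) stop("population weights must sum to 1")
    if (ncol(as.matrix(s$templates)) != n_sites)
      stop("template width must equal the number of sites")
  }
  structure(list(seed = as.integer(seed), contig_length = as.integer(contig_length),
                 site_positions = site_positions, n_sites = n_sites, k = as.integer(k),
                 level_range = level_range, mod_shift = mod_shift, noise_sd = noise_sd,
                 p_stay = p_stay, p_skip = p_skip, p_insert = p_insert,
                 shift_range = shift_range, scale_range = scale_range,
                 reads_per_sample = as.integer(reads_per_sample),
                 samples = samples, corr_targets = corr_targets,
                 full_length_fraction = full_length_fraction),
            class = "sim_config")
}

# standard bivariate normal CDF P(X <= a, Y <= b; r) by 1-D quadrature
pbinorm <- function(a, b, r) {
  if (abs(r) < 1e-12) return(pnorm(a) * pnorm(b))
  f <- function(x) dnorm(x) * pnorm((b - r * x) / sqrt(1 - r^2))
  integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# latent Gaussian correlation giving binary (phi) correlation `target`
# between indicators 1{X > qnorm(1-p1)}, 1{Y > qnorm(1-p2)}
calibrate_latent_rho <- function(target, p1, p2) {
  if (target == 0) return(0)
  p11_target <- p1 * p2 + target * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  if (p11_target <= max(0, p1 + p2 - 1) || p11_target >= min(p1, p2))
    stop("correlation target infeasible for these site frequencies")
  g <- function(r) pbinorm(qnorm(p1), qnorm(p2), r) - p11_target
  uniroot(g, c(-0.999, 0.999), tol = 1e-9)$root
}

# Draw n x n_sites binary modification states with per-site frequencies
# `freqs` and optional calibrated pairwise dependence.
draw_site_states <- function(n, freqs, corr_targets = NULL) {
  m <- length(freqs)
  if (is.null(corr_targets) || !nrow(corr_targets)) {
    states <- matrix(rbinom(n * m, 1, rep(freqs, each = n)), n, m)
    return(states)
  }
  sigma <- diag(m)
  for (t in seq_len(nrow(corr_targets))) {
    i <- corr_targets$site_i[t]; j <- corr_targets$site_j[t]
    if (freqs[i] %in% c(0, 1) || freqs[j] %in% c(0, 1))
      stop("correlation targets need site frequencies strictly inside (0,1)")
    r <- calibrate_latent_rho(corr_targets$rho[t], freqs[i], freqs[j])
    sigma[i, j] <- sigma[j, i] <- r
  }
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("latent correlation matrix not positive definite"))
  z <- matrix(rnorm(n * m), n, m) %*% ch
  thresholds <- qnorm(1 - freqs)
  states <- matrix(0L, n, m)
  for (j in seq_len(m)) states[, j] <- as.integer(z[, j] > thresholds[j])
  # honor degenerate frequencies exactly
  states[, freqs == 1] <- 1L
  states[, freqs == 0] <- 0L
  states
}

sim_reference <- function(cfg) {
  chars <- sample(RNA_BASES, cfg$contig_length, replace = TRUE)
  setNames(paste(chars, collapse = ""), "sim")
}

sim_sites <- function(cfg, reference) {
  chars <- strsplit(reference[[1]], "")[[1]]
  sites <- data.frame(contig = names(reference)[1],
                      position = cfg$site_positions,
                      canonical = chars[cfg$site_positions],
                      mod_code = rep(c("Y", "Nm"), length.out = cfg$n_sites),
                      guide = "", mod_char = NA_character_,
                      callable = cfg$site_positions > DEAD_ZONE_5PRIME,
                      stringsAsFactors = FALSE)
  class(sites) <- c("mod_sites", "data.frame")
  sites
}

sim_kmer_table <- function(cfg, branch_map) {
  canon <- apply(expand.grid(rep(list(RNA_BASES), cfg$k),
                             stringsAsFactors = FALSE), 1, paste, collapse = "")
  levels <- runif(length(canon), cfg$level_range[1], cfg$level_range[2])
  tab <- kmer_table(canon, levels, rep(cfg$noise_sd, length(canon)))
  tab <- derive_branch_kmers(tab, branch_map)
  is_mod <- grepl("[^ACGU]", tab$kmer)
  tab$level_mean[is_mod] <- tab$level_mean[is_mod] + cfg$mod_shift
  tab
}

# Emit one read's events by walking slots 5'->3'. `kmers` is the realized
# per-slot kmer sequence (already carrying modification characters).
sim_read_events <- function(cfg, levels_by_slot, bg_mu, start_slot, n_slots) {
  means <- numeric(0)
  slot_of_event <- integer(0)
  for (j in seq.int(start_slot, n_slots)) {
    terminal <- j == start_slot || j == n_slots
    if (!terminal && runif(1) < cfg$p_skip) next      # slot silently skipped
    n_ev <- 1L + rgeom(1, 1 - cfg$p_stay)
    means <- c(means, rnorm(n_ev, levels_by_slot[j], cfg$noise_sd))
    slot_of_event <- c(slot_of_event, rep(j, n_ev))
    if (j < n_slots && runif(1) < cfg$p_insert) {
      means <- c(means, rnorm(1, bg_mu, 3 * cfg$noise_sd * 10))
      slot_of_event <- c(slot_of_event, NA_integer_)
    }
  }
  list(means = means, slots = slot_of_event)
}

#' Simulate an event-level dataset with planted truth
#'
#' For each sample and read: draw a subpopulation, draw per-site binary
#' modification states from its template (with copula dependence when
#' configured), walk the reference 5'->3' emitting stay/step/skip/insert
#' events from the true kmer Gaussians (modified kmers where the state is
#' modified), and apply a per-read affine distortion. Everything is
#' reproducible from `cfg$seed`.
#'
#' @param cfg `sim_config`
#' @param dir optional output directory; when given, writes reference
#'   FASTA, annotation TSV, true kmer table and one events TSV per sample
#' @return list(reference, sites, table (true model), branch_map, reads
#'   (named list per sample of `event_seq`), truth (per-read states),
#'   distortions (per-read shift/scale), config)
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  reference <- sim_reference(cfg)
  sites <- sim_sites(cfg, reference)
  sites <- assign_mod_chars(sites)$sites
  bm <- build_branch_map(reference, sites, k = cfg$k)
  table <- sim_kmer_table(cfg, bm)
  n_slots <- length(bm$slots)
  canon <- !grepl("[^ACGU]", table$kmer)
  bg_mu <- mean(table$level_mean[canon])
  ref_chars <- strsplit(reference[[1]], "")[[1]]
  L <- cfg$contig_length

  reads <- list(); truth_rows <- list(); dist_rows <- list()
  for (sname in names(cfg$samples)) {
    smp <- cfg$samples[[sname]]
    templates <- as.matrix(smp$templates)
    nr <- cfg$reads_per_sample
    pop <- sample.int(nrow(templates), nr, replace = TRUE, prob = smp$weights)
    # draw states population-by-population so copula targets hold within each
    states <- matrix(0L, nr, cfg$n_sites)
    for (p in unique(pop)) {
      ix <- which(pop == p)
      states[ix, ] <- draw_site_states(length(ix), templates[p, ], cfg$corr_targets)
    }
    out <- vector("list", nr)
    for (i in seq_len(nr)) {
      chars <- ref_chars
      on <- which(states[i, ] == 1L & sites$callable)
      chars[sites$position[on]] <- sites$mod_char[on]
      full_seq <- paste(chars, collapse = "")
      levels_by_slot <- kmer_params(table, substring(full_seq, 1:n_slots, cfg$k:L))$mu
      full_length <- runif(1) < cfg$full_length_fraction
      start <- if (full_length) 1L else
        sample.int(max(2L, L %/% 2L) - DEAD_ZONE_5PRIME, 1) + DEAD_ZONE_5PRIME
      ev <- sim_read_events(cfg, levels_by_slot, bg_mu, start, n_slots)
      scale <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
      shift <- runif(1, cfg$shift_range[1], cfg$shift_range[2])
      rid <- sprintf("%s_%04d", sname, i)
      out[[i]] <- event_seq(rid, names(reference)[1], start, L,
                            rev(ev$means * scale + shift), orientation = "3to5")
      dist_rows[[length(dist_rows) + 1L]] <-
        data.frame(read_id = rid, sample = sname, shift = shift, scale = scale,
                   full_length = full_length, stringsAsFactors = FALSE)
    }
    reads[[sname]] <- out
    tr <- as.data.frame(states)
    names(tr) <- paste0(sites$contig, ":", sites$position)
    truth_rows[[sname]] <- cbind(
      data.frame(read_id = sprintf("%s_%04d", sname, seq_len(nr)),
                 sample = sname, population = pop, stringsAsFactors = FALSE), tr)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  distortions <- do.call(rbind, dist_rows)
  rownames(distortions) <- NULL
  res <- list(reference = reference, sites = sites, table = table,
              branch_map = bm, reads = reads, truth = truth,
              distortions = distortions, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c(paste0(">", names(reference)[1]), reference[[1]]),
               file.path(dir, "reference.fasta"))
    write.table(sites[, c("contig", "position", "canonical", "mod_code", "guide")],
                file.path(dir, "annotation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_kmer_table(table, file.path(dir, "kmer_model.tsv"))
    for (sname in names(reads))
      write_events_tsv(reads[[sname]], file.path(dir, paste0("events_", sname, ".tsv")))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  res
}

#' Simulate a probability matrix directly (bypassing the HMM)
#'
#' Per-read per-site modification probabilities are drawn conditional on
#' the planted binary state: Beta(a1, b1) concentrated near 1 for modified
#' states, Beta(a0, b0) near 0 for canonical. With `prob_model = "exact"`
#' cells are the states themselves (point masses at 0/1). Planted
#' frequencies, subpopulations and copula correlations are preserved.
#'
#' @param cfg `sim_config`
#' @param prob_model `"beta"` or `"exact"`
#' @param beta_mod,beta_can Beta parameters (shape1, shape2) per state
#' @return list(matrices = named list of `mod_profile_matrix` per sample,
#'   truth, config)
#' @export
simulate_profile_matrix <- function(cfg = sim_config(), prob_model = c("beta", "exact"),
                                    beta_mod = c(10, 2), beta_can = c(2, 10)) {
  prob_model <- match.arg(prob_model)
  set.seed(cfg$seed)
  site_names <- paste0("sim:", cfg$site_positions)
  sites <- data.frame(contig = "sim", position = cfg$site_positions,
                      stringsAsFactors = FALSE)
  matrices <- list(); truth_rows <- list()
  for (sname in names(cfg$samples)) {
    smp <- cfg$samples[[sname]]
    templates <- as.matrix(smp$templates)
    nr <- cfg$reads_per_sample
    pop <- sample.int(nrow(templates), nr, replace = TRUE, prob = smp$weights)
    states <- matrix(0L, nr, cfg$n_sites)
    for (p in unique(pop)) {
      ix <- which(pop == p)
      states[ix, ] <- draw_site_states(length(ix), templates[p, ], cfg$corr_targets)
    }
    probs <- if (prob_model == "exact") {
      states + 0.0
    } else {
      matrix(ifelse(states == 1L,
                    rbeta(nr * cfg$n_sites, beta_mod[1], beta_mod[2]),
                    rbeta(nr * cfg$n_sites, beta_can[1], beta_can[2])),
             nr, cfg$n_sites)
    }
    ids <- sprintf("%s_%04d", sname, seq_len(nr))
    matrices[[sname]] <- mod_profile_matrix(
      probs, data.frame(read_id = ids, sample = sname, stringsAsFactors = FALSE),
      sites)
    tr <- as.data.frame(states)
    names(tr) <- site_names
    truth_rows[[sname]] <- cbind(
      data.frame(read_id = ids, sample = sname, population = pop,
                 stringsAsFactors = FALSE), tr)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(matrices = matrices, truth = truth, config = cfg)
}
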