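# Model space: reference, modification annotation, the extended modification
# alphabet, and the branchable kmer space the HMM aligns against.

# Default pool of single characters available as modification marks. Canonical
# bases (and T, which is normalized to U) are excluded. Lowercase letters
# first, then digits, then a declared ASCII extension list; assignment is
# deterministic in (contig, position) order so model files are reproducible.
MOD_CHAR_POOL <- c(
  letters,
  as.character(0:9),
  setdiff(LETTERS, c("A", "C", "G", "U", "T")),
  strsplit("!$%&()*+,-./:;<=>?@[]^_{|}~", "")[[1]]
)

#' Read a reference FASTA as named RNA character strings
#'
#' Sequences are uppercased and T is normalized to U.
#'
#' @param path path to a FASTA file (or a named character vector of
#'   sequences, which is passed through after normalization)
#' @return named character vector, one element per contig
#' @export
read_reference <- function(path) {
  if (is.character(path) && length(path) == 1 && file.exists(path)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (is.character(path) && !is.null(names(path))) {
    seqs <- path
  } else {
    stop("reference must be a FASTA path or a named character vector")
  }
  normalize_rna(seqs)
}

#' Load a modification annotation table
#'
#' Reads a TSV with columns `contig`, `position` (1-based), `canonical`,
#' `mod_code`, `guide` and validates it against the reference. Each row
#' becomes one modification site; sites within the first 15 nt of the 5'
#' end of a contig are flagged not callable (nanopore RNA sequencing runs
#' 3'->5' and never captures signal for those positions).
#'
#' @param path annotation TSV path
#' @param reference FASTA path or named character vector of contig sequences
#' @param dead_zone length of the 5' dead zone in nt (default 15)
#' @return a `mod_sites` data.frame: contig, position, canonical, mod_code,
#'   guide, mod_char (NA until [assign_mod_chars()]), callable; ordered by
#'   (contig, position)
#' @export
load_annotation <- function(path, reference, dead_zone = DEAD_ZONE_5PRIME) {
  ref <- read_reference(reference)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", quote = "")
  need <- c("contig", "position", "canonical", "mod_code", "guide")
  if (!all(need %in% names(tab)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) {
    out <- data.frame(contig = character(), position = integer(),
                      canonical = character(), mod_code = character(),
                      guide = character(), mod_char = character(),
                      callable = logical(), stringsAsFactors = FALSE)
    class(out) <- c("mod_sites", "data.frame")
    return(out)
  }
  tab$position <- as.integer(tab$position)
  tab$canonical <- normalize_rna(tab$canonical)
  missing_contig <- setdiff(unique(tab$contig), names(ref))
  if (length(missing_contig))
    stop("contig(s) not in reference: ", paste(missing_contig, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    L <- nchar(ref[[tab$contig[i]]])
    if (is.na(tab$position[i]) || tab$position[i] < 1 || tab$position[i] > L)
      stop(sprintf("position %s out of bounds for contig %s (length %d)",
                   tab$position[i], tab$contig[i], L))
    base <- substr(ref[[tab$contig[i]]], tab$position[i], tab$position[i])
    if (base != tab$canonical[i])
      stop(sprintf("canonical mismatch at %s:%d (annotation %s, reference %s)",
                   tab$contig[i], tab$position[i], tab$canonical[i], base))
  }
  key <- paste(tab$contig, tab$position)
  if (anyDuplicated(key))
    stop("duplicate (contig, position): ", key[duplicated(key)][1])
  out <- tab[order(tab$contig, tab$position), need, drop = FALSE]
  rownames(out) <- NULL
  out$mod_char <- NA_character_
  out$callable <- out$position > dead_zone
  class(out) <- c("mod_sites", "data.frame")
  out
}

#' Assign a distinct modification character to each site
#'
#' Each annotated site receives a single character from a fixed pool so that
#' kmers covering different sites never collide: modifications are modeled
#' independently, each covered by its own unique kmers. Assignment is
#' deterministic in (contig, position) order, unique within a contig, and
#' idempotent (already-assigned sites are kept and their characters retired
#' from the pool).
#'
#' @param sites `mod_sites` data.frame from [load_annotation()]
#' @param pool character pool to draw from (default lowercase letters, then
#'   digits, then an ASCII extension list)
#' @return list with `sites` (mod_char filled) and `alphabet`, a per-contig
#'   named list mapping mod_char -> canonical base
#' @export
assign_mod_chars <- function(sites, pool = MOD_CHAR_POOL) {
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  alphabet <- list()
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    used <- sites$mod_char[idx]
    used <- used[!is.na(used)]
    if (anyDuplicated(used)) stop("duplicate mod_char within contig ", ctg)
    avail <- setdiff(pool, used)
    for (i in idx) {
      if (is.na(sites$mod_char[i])) {
        if (!length(avail)) stop("modification character pool exhausted for contig ", ctg)
        sites$mod_char[i] <- avail[1]
        avail <- avail[-1]
      }
    }
    alphabet[[ctg]] <- setNames(sites$canonical[idx], sites$mod_char[idx])
  }
  class(sites) <- c("mod_sites", "data.frame")
  list(sites = sites, alphabet = alphabet)
}

#' Build the branchable kmer space for one contig
#'
#' For every reference position the allowed character set is the canonical
#' base, plus the site's modification character when the position is an
#' annotated callable site. Every kmer slot (window of k consecutive
#' positions) then lists all variant kmers formed by combinations of allowed
#' characters, giving 2^b variants for a slot covering b annotated positions.
#'
#' @param reference_contig contig sequence (character string) or a named
#'   length-1 character vector
#' @param sites `mod_sites` rows for this contig, mod_char assigned
#' @param k kmer length (default 5)
#' @param max_branch maximum number of ambiguous positions allowed in one
#'   slot (default 4, i.e. at most 16 variants)
#' @return a `branch_map`: list(contig, seq, k, allowed, slots, sites) where
#'   `slots[[j]]` is the character vector of variant kmers of slot j (the
#'   fully canonical variant first) and `allowed[[p]]` the allowed characters
#'   at position p
#' @export
build_branch_map <- function(reference_contig, sites, k = 5L, max_branch = 4L) {
  if (k < 1) stop("k must be >= 1")
  contig <- if (!is.null(names(reference_contig))) {
    names(reference_contig)[1]
  } else if (nrow(sites)) {
    unique(sites$contig)[1]
  } else "contig"
  seq <- normalize_rna(as.character(reference_contig)[1])
  L <- nchar(seq)
  if (L < k) stop("contig shorter than k")
  chars <- strsplit(seq, "")[[1]]
  if (nrow(sites) && contig %in% sites$contig)
    sites <- sites[sites$contig == contig, , drop = FALSE]
  use <- sites[sites$callable, , drop = FALSE]
  if (nrow(use) && any(is.na(use$mod_char)))
    stop("site without assigned mod_char; run assign_mod_chars() first")
  allowed <- as.list(chars)
  for (i in seq_len(nrow(use))) {
    p <- use$position[i]
    if (p > L) stop("site position beyond contig length")
    allowed[[p]] <- c(chars[p], use$mod_char[i])
  }
  n_slots <- L - k + 1L
  slots <- vector("list", n_slots)
  for (j in seq_len(n_slots)) {
    sets <- allowed[j:(j + k - 1L)]
    b <- sum(lengths(sets) > 1)
    if (b > max_branch)
      stop(sprintf("slot %d covers %d ambiguous positions (cap %d)", j, b, max_branch))
    if (b == 0) {
      slots[[j]] <- paste(unlist(sets), collapse = "")
    } else {
      grid <- expand.grid(sets, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      slots[[j]] <- do.call(paste0, grid)
    }
  }
  structure(list(contig = contig, seq = seq, k = as.integer(k),
                 allowed = allowed, slots = slots, sites = use),
            class = "branch_map")
}

#' @export
print.branch_map <- function(x, ...) {
  nv <- lengths(x$slots)
  cat(sprintf("branch_map: contig %s (%d nt), k=%d, %d slots, %d branched (%d sites)\n",
              x$contig, nchar(x$seq), x$k, length(x$slots), sum(nv > 1), nrow(x$sites)))
  invisible(x)
}

#' Load an ONT-style kmer level model table
#'
#' Whitespace/TSV table with columns kmer, level_mean, level_sd (header
#' optional). Kmers are normalized to the RNA alphabet (T -> U). The table
#' must cover every canonical kmer of its length.
#'
#' @param path file path
#' @return a `kmer_table` data.frame (kmer, level_mean, level_sd, provenance)
#'   with attribute `k`
#' @export
load_kmer_table <- function(path) {
  first <- readLines(path, n = 1)
  toks <- strsplit(trimws(first), "\\s+")[[1]]
  has_header <- length(toks) >= 3 && is.na(suppressWarnings(as.numeric(toks[2])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  tab <- tab[, 1:3]
  names(tab) <- c("kmer", "level_mean", "level_sd")
  # T -> U only: case is significant (lowercase letters are modification
  # characters in the extended alphabet)
  tab$kmer <- chartr("T", "U", as.character(tab$kmer))
  kmer_table(tab$kmer, tab$level_mean, tab$level_sd)
}

#' Construct a kmer table
#'
#' @param kmer character vector of kmers (extended alphabet allowed)
#' @param level_mean,level_sd Gaussian current level parameters (pA)
#' @param provenance "default" or "trained" per entry
#' @return a `kmer_table` data.frame
#' @export
kmer_table <- function(kmer, level_mean, level_sd,
                       provenance = rep("default", length(kmer))) {
  k <- unique(nchar(kmer))
  if (length(k) != 1) stop("all kmers must have the same length")
  if (any(!is.finite(level_sd)) || any(level_sd <= 0))
    stop("level_sd must be positive")
  if (anyDuplicated(kmer)) stop("duplicate kmer entries")
  canon <- apply(expand.grid(rep(list(RNA_BASES), k),
                             stringsAsFactors = FALSE), 1, paste, collapse = "")
  miss <- setdiff(canon, kmer)
  if (length(miss))
    stop("missing canonical kmer(s), e.g. ", miss[1])
  out <- data.frame(kmer = kmer, level_mean = as.numeric(level_mean),
                    level_sd = as.numeric(level_sd),
                    provenance = provenance, stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_table", "data.frame")
  out
}

#' Write a kmer table in ONT-style layout
#'
#' @param table `kmer_table`
#' @param path output path
#' @export
write_kmer_table <- function(table, path) {
  write.table(table[, c("kmer", "level_mean", "level_sd")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Add modification-branch kmers to a kmer table
#'
#' Every variant kmer appearing in the branch map gains an entry. New
#' modified-kmer entries are initialized from their canonical counterpart's
#' Gaussian (training later separates them); canonical entries are untouched.
#'
#' @param table `kmer_table` covering all canonical kmers
#' @param branch_map a `branch_map`
#' @return enlarged `kmer_table`
#' @export
derive_branch_kmers <- function(table, branch_map) {
  k <- attr(table, "k")
  if (k != branch_map$k) stop("kmer length mismatch between table and branch map")
  variants <- unique(unlist(branch_map$slots))
  new <- setdiff(variants, table$kmer)
  if (!length(new)) return(table)
  counterpart <- canonical_counterpart(new, branch_map)
  idx <- match(counterpart, table$kmer)
  if (anyNA(idx)) stop("missing canonical kmer for ", new[which(is.na(idx))[1]])
  add <- data.frame(kmer = new, level_mean = table$level_mean[idx],
                    level_sd = table$level_sd[idx],
                    provenance = "default", stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(table), add)
  attr(out, "k") <- k
  class(out) <- c("kmer_table", "data.frame")
  out
}

# Translate modification characters back to their canonical base.
canonical_counterpart <- function(kmers, branch_map) {
  map <- setNames(branch_map$sites$canonical, branch_map$sites$mod_char)
  if (!length(map)) return(kmers)
  old <- paste(names(map), collapse = "")
  new <- paste(unname(map), collapse = "")
  chartr(old, new, kmers)
}

# kmer lookup returning (mean, sd) rows aligned with `kmers`
kmer_params <- function(table, kmers) {
  idx <- match(kmers, table$kmer)
  if (anyNA(idx)) stop("kmer not in table: ", kmers[which(is.na(idx))[1]])
  list(mu = table$level_mean[idx], sd = table$level_sd[idx])
}
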