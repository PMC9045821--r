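# Plain-text interchange formats: events TSV (per-read event sequences,
# sequencing order 3'->5'), per-read calls TSV, and the wide/long dialects
# of the modification-probability matrix.

#' Write event sequences to a TSV
#'
#' Columns: read_id, contig, start, end, strand, event_index, mean, spread,
#' duration. Events are written in sequencing (3'->5') order.
#'
#' @param reads list of `event_seq`
#' @param path output path
#' @export
write_events_tsv <- function(reads, path) {
  rows <- lapply(reads, function(r) {
    n <- length(r$means)
    data.frame(read_id = r$read_id, contig = r$contig, start = r$start,
               end = r$end, strand = "+", event_index = seq_len(n),
               mean = rev(r$means),
               spread = if (is.null(r$spread)) NA_real_ else rev(r$spread),
               duration = if (is.null(r$duration)) NA_real_ else rev(r$duration),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read event sequences from a TSV
#'
#' @param path events TSV (see [write_events_tsv()])
#' @return list of `event_seq` (events reversed into 5'->3' reference order)
#' @export
read_events_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab <- tab[order(match(tab$read_id, unique(tab$read_id)), tab$event_index), ]
  lapply(split(tab, factor(tab$read_id, levels = unique(tab$read_id))), function(d) {
    event_seq(d$read_id[1], d$contig[1], d$start[1], d$end[1], d$mean,
              spread = if (all(is.na(d$spread))) NULL else d$spread,
              duration = if (all(is.na(d$duration))) NULL else d$duration,
              orientation = "3to5")
  })
}

#' Write a modification-probability matrix
#'
#' @param matrix a `mod_profile_matrix`
#' @param path output path
#' @param dialect `"wide"` (read_id, sample, one column per contig:position)
#'   or `"long"` (read_id, sample, contig, position, prob)
#' @export
write_profile_matrix <- function(matrix, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  cols <- paste0(matrix$sites$contig, ":", matrix$sites$position)
  if (dialect == "wide") {
    d <- data.frame(read_id = matrix$reads$read_id, sample = matrix$reads$sample,
                    stringsAsFactors = FALSE, check.names = FALSE)
    probs <- as.data.frame(matrix$probs)
    names(probs) <- cols
    d <- cbind(d, probs)
  } else {
    idx <- expand.grid(r = seq_len(nrow(matrix$probs)), s = seq_len(ncol(matrix$probs)))
    d <- data.frame(read_id = matrix$reads$read_id[idx$r],
                    sample = matrix$reads$sample[idx$r],
                    contig = matrix$sites$contig[idx$s],
                    position = matrix$sites$position[idx$s],
                    prob = matrix$probs[cbind(idx$r, idx$s)],
                    stringsAsFactors = FALSE)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a modification-probability matrix
#'
#' Accepts either dialect written by [write_profile_matrix()].
#'
#' @param path TSV path
#' @return a `mod_profile_matrix`
#' @export
read_profile_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (all(c("contig", "position", "prob") %in% names(d))) {
    sites <- unique(d[, c("contig", "position")])
    sites <- sites[order(sites$contig, sites$position), ]
    reads <- unique(d[, c("read_id", "sample")])
    probs <- matrix(NA_real_, nrow(reads), nrow(sites))
    ri <- match(d$read_id, reads$read_id)
    si <- match(paste(d$contig, d$position), paste(sites$contig, sites$position))
    probs[cbind(ri, si)] <- d$prob
  } else {
    cols <- setdiff(names(d), c("read_id", "sample"))
    parts <- strsplit(cols, ":", fixed = TRUE)
    sites <- data.frame(contig = vapply(parts, `[[`, "", 1),
                        position = as.integer(vapply(parts, `[[`, "", 2)),
                        stringsAsFactors = FALSE)
    reads <- d[, c("read_id", "sample")]
    probs <- as.matrix(d[, cols, drop = FALSE])
    dimnames(probs) <- NULL
  }
  mod_profile_matrix(probs, reads, sites)
}
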