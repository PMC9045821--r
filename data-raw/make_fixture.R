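# Generates the bundled SYNTHETIC stand-in for the yeast rRNA modification
# annotation: 37 sites on an 1800-nt "18S" contig and 73 on a 3396-nt "25S"
# contig. Well-known positions discussed in the rRNA modification literature
# are placed at their real coordinates with their real modification codes
# and guides; the remaining positions and the reference sequence itself are
# synthetic (seeded). Reference bases at annotated positions are set to the
# annotation's canonical base.
# Run from the package root: Rscript data-raw/make_fixture.R

set.seed(20221804)

marquee_18s <- data.frame(
  position = c(100, 106, 436, 562, 632, 759, 766, 974, 999, 1191, 1269, 1271,
               1280, 1290, 1415, 1639, 1773, 1782),
  canonical = c("A", "U", "A", "U", "U", "U", "U", "A", "U", "U", "U", "G",
                "C", "U", "U", "C", "C", "A"),
  mod_code = c("Am", "Y", "Am", "Y", "Y", "Y", "Y", "Am", "Y", "m1acp3Y",
               "Um", "Gm", "ac4C", "Y", "Y", "Cm", "ac4C", "m62A"),
  guide = c("", "snR44", "snR87", "", "snR161", "snR80", "snR161", "snR54",
            "snR31", "snR35", "snR55", "", "snR4", "snR83", "snR83", "snR70",
            "snR45", "Dim1"),
  stringsAsFactors = FALSE)

marquee_25s <- data.frame(
  position = c(817, 908, 1437, 1449, 1450, 2619, 2724, 2921, 2922, 2923),
  canonical = c("A", "G", "C", "A", "G", "G", "U", "U", "G", "U"),
  mod_code = c("Am", "Gm", "Cm", "Am", "Gm", "Gm", "Um", "Um", "Gm", "Y"),
  guide = c("snR60", "snR60", "U24", "U24", "U24", "snR67", "snR67", "snR52",
            "Spb1", "snR10"),
  stringsAsFactors = FALSE)

fill_sites <- function(n_total, L, marquee, min_gap = 8) {
  pos <- marquee$position
  need <- n_total - length(pos)
  cand <- setdiff(seq(20, L - 10), unlist(lapply(pos, function(p) (p - min_gap):(p + min_gap))))
  extra <- integer(0)
  while (length(extra) < need) {
    p <- sample(cand, 1)
    cand <- setdiff(cand, (p - min_gap):(p + min_gap))
    extra <- c(extra, p)
  }
  sort(c(pos, extra))
}

build_contig <- function(name, L, n_total, marquee) {
  bases <- c("A", "C", "G", "U")
  seq <- sample(bases, L, replace = TRUE)
  all_pos <- fill_sites(n_total, L, marquee)
  canonical <- character(length(all_pos))
  mod_code <- character(length(all_pos))
  guide <- character(length(all_pos))
  for (i in seq_along(all_pos)) {
    j <- match(all_pos[i], marquee$position)
    if (!is.na(j)) {
      canonical[i] <- marquee$canonical[j]
      mod_code[i] <- marquee$mod_code[j]
      guide[i] <- marquee$guide[j]
    } else {
      canonical[i] <- seq[all_pos[i]]
      mod_code[i] <- if (canonical[i] == "U") "Y" else paste0(canonical[i], "m")
      guide[i] <- ""
    }
    seq[all_pos[i]] <- canonical[i]
  }
  list(seq = paste(seq, collapse = ""),
       sites = data.frame(contig = name, position = all_pos,
                          canonical = canonical, mod_code = mod_code,
                          guide = guide, stringsAsFactors = FALSE))
}

c18 <- build_contig("18S", 1800, 37, marquee_18s)
c25 <- build_contig("25S", 3396, 73, marquee_25s)

wrap <- function(s, width = 70) {
  substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
}
writeLines(c(">18S synthetic stand-in", wrap(c18$seq),
             ">25S synthetic stand-in", wrap(c25$seq)),
           "inst/extdata/yeast_rrna_synthetic.fasta")
sites <- rbind(c18$sites, c25$sites)
write.table(sites, "inst/extdata/yeast_rrna_synthetic_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(sites), "sites\n")
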