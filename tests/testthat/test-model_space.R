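ref_small <- c(sim = "AAACCCGGGUUUACGUACGUACGUACGUAC")

write_annotation <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  header <- "contig\tposition\tcanonical\tmod_code\tguide"
  writeLines(c(header, rows), path)
  path
}

test_that("bundled synthetic annotation yields 110 sites, 37 on 18S and 73 on 25S", {
  fa <- system.file("extdata", "yeast_rrna_synthetic.fasta", package = "modprofiler")
  tsv <- system.file("extdata", "yeast_rrna_synthetic_annotation.tsv", package = "modprofiler")
  sites <- load_annotation(tsv, fa)
  expect_equal(nrow(sites), 110)
  expect_equal(sum(sites$contig == "18S"), 37)
  expect_equal(sum(sites$contig == "25S"), 73)
  expect_true(all(sites$callable))  # no yeast site lies in the 5' dead zone
  # canonical bases validated against the reference by construction
  ref <- read_reference(fa)
  base_at <- substr(ref[sites$contig], sites$position, sites$position)
  expect_equal(unname(base_at), sites$canonical)
})

test_that("load_annotation handles empty input, dead zone, and bad rows", {
  empty <- load_annotation(write_annotation(character()), ref_small)
  expect_s3_class(empty, "mod_sites")
  expect_equal(nrow(empty), 0)

  dead <- load_annotation(write_annotation("sim\t10\tU\tY\t"), ref_small)
  expect_false(dead$callable)
  alive <- load_annotation(write_annotation("sim\t20\tU\tY\t"), ref_small)
  expect_true(alive$callable)

  expect_error(load_annotation(write_annotation("sim\t99\tA\tY\t"), ref_small),
               "out of bounds")
  expect_error(load_annotation(write_annotation("sim\t1\tC\tY\t"), ref_small),
               "canonical mismatch")
  expect_error(load_annotation(write_annotation(c("sim\t20\tU\tY\t", "sim\t20\tU\tY\t")),
                               ref_small), "duplicate")
  expect_error(load_annotation(write_annotation("other\t5\tA\tY\t"), ref_small),
               "not in reference")
})

test_that("assign_mod_chars gives unique characters and disjoint kmer coverage", {
  one <- assign_mod_chars(toy_sites("c", 20, "U"))
  expect_equal(one$sites$mod_char, "a")
  expect_length(one$alphabet$c, 1)

  # two pseudouridine sites 100 nt apart: distinct characters, and the kmers
  # covering each site share nothing
  seqc <- paste(rep("ACGU", 60), collapse = "")
  two <- assign_mod_chars(toy_sites("c", c(40, 140), c("U", "U")))
  sites <- two$sites
  expect_equal(anyDuplicated(sites$mod_char), 0)
  bm <- build_branch_map(c(c = seqc), sites, k = 5)
  cover <- function(pos) unique(unlist(bm$slots[(pos - 4):pos]))
  k1 <- grep(sites$mod_char[1], cover(40), fixed = TRUE, value = TRUE)
  k2 <- grep(sites$mod_char[2], cover(140), fixed = TRUE, value = TRUE)
  expect_length(intersect(k1, k2), 0)
  expect_true(length(k1) > 0 && length(k2) > 0)
})

test_that("two close sites expand to all character combinations (enumeration)", {
  seqc <- c(c = "AAAAACGUACGUAAAAAAAA")
  sites <- assign_mod_chars(toy_sites("c", c(8, 10), c("U", "C")))$sites
  bm <- build_branch_map(seqc, sites, k = 5)
  # slot 6 covers positions 6..10, including both sites
  vs <- bm$slots[[6]]
  expect_length(vs, 4)
  # brute-force enumeration of the 2^2 combinations
  base <- strsplit(substr(seqc, 6, 10), "")[[1]]
  combos <- c()
  for (a in c("U", sites$mod_char[1])) for (b in c("C", sites$mod_char[2])) {
    w <- base; w[3] <- a; w[5] <- b
    combos <- c(combos, paste(w, collapse = ""))
  }
  expect_setequal(vs, combos)
})

test_that("assign_mod_chars is deterministic, idempotent and order-stable", {
  s <- toy_sites("c", c(30, 20, 40), c("U", "U", "U"))
  a1 <- assign_mod_chars(s)$sites
  a2 <- assign_mod_chars(s[c(3, 1, 2), ])$sites
  expect_equal(a1, a2)
  expect_equal(assign_mod_chars(a1)$sites, a1)  # idempotent
  expect_error(assign_mod_chars(toy_sites("c", c(20, 25), c("U", "U")),
                                pool = "a"), "exhausted")
})

test_that("branch map slots and allowed sets follow the covering rule", {
  # toy single-slot contig with one branch position
  s <- toy_sites("c", 3, "G", mod_char = "x")
  bm <- build_branch_map(c(c = "ACGUA"), s, k = 5)
  expect_length(bm$allowed[[3]], 2)
  expect_length(bm$slots, 1)
  expect_setequal(bm$slots[[1]], c("ACGUA", "ACxUA"))

  # a lone interior site is covered by exactly k slots
  seqc <- c(c = paste(rep("ACGU", 10), collapse = ""))
  s2 <- assign_mod_chars(toy_sites("c", 20, "U"))$sites
  bm2 <- build_branch_map(seqc, s2, k = 5)
  nv <- lengths(bm2$slots)
  expect_equal(length(nv), 40 - 5 + 1)
  expect_equal(sum(nv == 2), 5)
  expect_equal(which(nv == 2), 16:20)
  expect_true(all(nv %in% c(1, 2)))

  expect_error(build_branch_map(c(c = "ACGUA"), toy_sites("c", 3, "G"), k = 5),
               "mod_char")
  expect_error(build_branch_map(c(c = "ACGUA"), s, k = 0), "k must be")
})

test_that("total variant count matches brute-force enumeration on short contigs", {
  set.seed(11)
  for (trial in 1:5) {
    L <- sample(10:30, 1)
    seqc <- setNames(paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = ""), "c")
    npos <- sample(1:3, 1)
    pos <- sort(sample(seq_len(L), npos))
    chars <- strsplit(seqc, "")[[1]]
    sites <- assign_mod_chars(toy_sites("c", pos, chars[pos]))$sites
    k <- sample(2:5, 1)
    if (L < k) next
    bm <- build_branch_map(seqc, sites, k = k)
    b_per_slot <- vapply(seq_len(L - k + 1), function(j)
      sum(pos >= j & pos <= j + k - 1), 0L)
    expect_equal(sum(lengths(bm$slots)), sum(2^b_per_slot))
    expect_equal(lengths(bm$slots), 2^b_per_slot)
  }
})

test_that("kmer tables load, validate, derive branch entries and round-trip", {
  # toy k=1 table
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kmer\tlevel_mean\tlevel_sd",
               "A\t80\t1", "C\t90\t1", "G\t100\t1", "U\t110\t1"), p)
  tab <- load_kmer_table(p)
  expect_equal(attr(tab, "k"), 1L)
  expect_equal(tab$level_mean[match("A", tab$kmer)], 80)

  # header-less whitespace layout also accepted
  p2 <- withr::local_tempfile(fileext = ".model")
  writeLines(c("A 80 1", "C 90 1", "G 100 1", "T 110 1"), p2)  # T normalized
  tab2 <- load_kmer_table(p2)
  expect_true("U" %in% tab2$kmer)

  # missing canonical kmer and bad sd rejected
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A 80 1", "C 90 1", "G 100 1"), p3)
  expect_error(load_kmer_table(p3), "missing canonical")
  expect_error(kmer_table(c("A", "C", "G", "U"), 1:4, c(1, 1, 0, 1)), "positive")

  # derivation over a lone interior site grows the table by exactly k entries,
  # initialized identical to the canonical counterpart
  seqc <- c(c = paste(rep("ACGU", 10), collapse = ""))
  sites <- assign_mod_chars(toy_sites("c", 20, "U"))$sites
  bm <- build_branch_map(seqc, sites, k = 5)
  canon <- apply(expand.grid(rep(list(c("A","C","G","U")), 5)), 1, paste, collapse = "")
  big <- kmer_table(canon, seq_along(canon), rep(1, length(canon)))
  grown <- derive_branch_kmers(big, bm)
  expect_equal(nrow(grown), nrow(big) + 5)
  new <- setdiff(grown$kmer, big$kmer)
  for (u in new) {
    counter <- chartr(sites$mod_char[1], "U", u)
    expect_equal(grown$level_mean[grown$kmer == u],
                 big$level_mean[big$kmer == counter])
  }

  # write/load round trip preserves values
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_table(grown, p4)
  back <- load_kmer_table(p4)
  expect_equal(back$kmer, grown$kmer)
  expect_equal(back$level_mean, grown$level_mean)
  expect_equal(back$level_sd, grown$level_sd)
})
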