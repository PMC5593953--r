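# Seed index, read alignment, pair classification and SAM input/output.

test_that("index position counts follow the k-mer count identity", {
  seqs <- c(chr = withr::with_seed(1, rand_dna(10000)))
  idx <- build_index(seqs, k = 21L)
  info <- index_info(idx)
  expect_equal(info$n_positions, 10000 - 21 + 1)
  expect_error(build_index(seqs, k = 9L), "k must be")
  expect_error(build_index(setNames("", "chr")), "non-empty")
})

test_that("a homopolymer contig indexes one key with many positions", {
  idx <- build_index(c(chr = strrep("A", 210)), k = 21L)
  info <- index_info(idx)
  expect_equal(info$n_kmers, 1)
  expect_equal(info$n_positions, 190)
  expect_equal(nrow(index_lookup(idx, strrep("A", 21))), 190L)
})

test_that("vector k-mers are retrievable from the composite index", {
  idx <- build_index(composite_reference(fix$ref, fix$vec), k = 21L)
  set.seed(17)
  for (start in sample.int(fix$vec$length - 21L, 20)) {
    kmer <- substring(fix$vec$sequence, start, start + 20L)
    hits <- index_lookup(idx, kmer)
    # oracle: direct substring scan over both contigs
    on_vec <- as.integer(
      gregexpr(kmer, fix$vec$sequence, fixed = TRUE)[[1]]) - 1L
    on_gen <- as.integer(
      gregexpr(kmer, fix$ref$contigs[[1]], fixed = TRUE)[[1]])
    on_gen <- on_gen[on_gen > 0] - 1L
    expect_setequal(hits$pos[hits$contig == "vector"], on_vec)
    expect_setequal(hits$pos[hits$contig == fix$ref$contig_name], on_gen)
  }
})

test_that("an exact copied read aligns uniquely with zero clips", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  p <- 54321L
  read <- substring(fix$ref$contigs[[1]], p + 1L, p + 150L)
  rec <- align_read(read, idx)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$pos, p)
  expect_true(rec$unique)
  expect_identical(rec$clip5 + rec$clip3, 0L)
  expect_identical(rec$alen, 150L)
  expect_identical(rec$strand, "+")
})

test_that("aligning the reverse complement flips the strand only", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  p <- 98765L
  read <- substring(fix$ref$contigs[[1]], p + 1L, p + 150L)
  fwd <- align_read(read, idx)
  rev <- align_read(revcomp(read), idx)
  expect_identical(rev$pos, fwd$pos)
  expect_identical(rev$contig, fwd$contig)
  expect_identical(rev$strand, "-")
})

test_that("a constructed junction read yields clipped records on both sides", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  p <- 30000L; q <- 2000L
  read <- paste0(substring(fix$ref$contigs[[1]], p + 1L, p + 75L),
                 substring(fix$vec$sequence, q + 1L, q + 75L))
  rec <- align_read(read, idx)
  gen <- rec[rec$contig == fix$ref$contig_name, ]
  vec <- rec[rec$contig == "vector", ]
  expect_identical(nrow(gen), 1L)
  expect_identical(nrow(vec), 1L)
  # string arithmetic: genome half ends where the vector half begins
  expect_identical(gen$pos, p)
  expect_identical(gen$clip3, 75L)
  expect_identical(gen$alen, 75L)
  expect_identical(vec$pos, q)
  expect_identical(vec$clip5, 75L)
  expect_true(all(rec$unique))
})

test_that("mapper placements match an exhaustive-scan oracle", {
  # <= 10 kb reference, 1% read error: best placement by brute-force
  # Hamming distance at every start position on both strands
  ref_seq <- withr::with_seed(400L, rand_dna(10000))
  sim <- simulate_reads(ref_seq, NULL, "WT",
                        read_sim_params(depth = 15, error_rate = 0.01,
                                        seed = 401L), wt_name = "oracle")
  idx <- build_index(c(oracle = ref_seq))
  aln <- align_pairs(sim, idx)
  pri <- aln[aln$rank == 1L & aln$mate == 1L, ]

  subject <- Biostrings::DNAString(ref_seq)
  n_checked <- 0L; n_agree <- 0L
  set.seed(402)
  for (i in sample(seq_along(sim$names), 400)) {
    read <- sim$r1[i]
    starts <- 1:(10000 - 150 + 1)
    d_fwd <- Biostrings::neditStartingAt(Biostrings::DNAString(read),
                                         subject, starting.at = starts)
    d_rev <- Biostrings::neditStartingAt(
      Biostrings::DNAString(revcomp(read)), subject, starting.at = starts)
    best <- min(d_fwd, d_rev)
    oracle_pos <- if (min(d_fwd) <= min(d_rev)) {
      which(d_fwd == best) - 1L
    } else {
      which(d_rev == best) - 1L
    }
    got <- pri[pri$qname == sim$names[i], ]
    n_checked <- n_checked + 1L
    # implied full-read start: the reference-orientation leading clip
    # shifts `pos` right of the full read's span start
    implied <- if (nrow(got) == 1L) got$pos - got$clip5 else NA_integer_
    if (!is.na(implied) && implied %in% oracle_pos) n_agree <- n_agree + 1L
  }
  expect_gte(n_agree / n_checked, 0.99)
})

test_that("pair classes follow their definitions on constructed records", {
  rec <- function(qname, mate, contig, pos, strand, clip5 = 0L, clip3 = 0L,
                  alen = 150L, unique = TRUE, rank = 1L) {
    data.frame(qname = qname, mate = mate, contig = contig, pos = pos,
               strand = strand, clip5 = clip5, clip3 = clip3, alen = alen,
               read_length = clip5 + alen + clip3, nm = 0L, score = alen,
               unique = unique, rank = rank, stringsAsFactors = FALSE)
  }
  aln <- rbind(
    rec("conc", 1L, "chrS", 1000L, "+"),
    rec("conc", 2L, "chrS", 1400L, "-"),        # insert 550
    rec("chim", 1L, "chrS", 5000L, "+"),
    rec("chim", 2L, "vector", 100L, "-"),
    rec("disc", 1L, "chrS", 9000L, "+"),
    rec("disc", 2L, "chrS", 20000L, "-"),
    rec("vint", 1L, "vector", 200L, "+"),
    rec("vint", 2L, "vector", 600L, "-"),
    rec("splt", 1L, "chrS", 7000L, "+", clip3 = 60L, alen = 90L),
    rec("splt", 1L, "vector", 300L, "+", clip5 = 90L, alen = 60L,
        rank = 2L),
    rec("splt", 2L, "chrS", 6600L, "+"),
    rec("unmp", 1L, "chrS", 3000L, "+", unique = FALSE))
  cls <- classify_pairs(aln)
  got <- setNames(cls$class, cls$qname)
  expect_identical(got[["conc"]], "GENOME_CONCORDANT")
  expect_identical(got[["chim"]], "CHIMERIC_GENOME_VECTOR")
  expect_identical(got[["disc"]], "DISCORDANT_GENOME")
  expect_identical(got[["vint"]], "VECTOR_INTERNAL")
  expect_identical(got[["splt"]], "SPLIT_JUNCTION")
  expect_identical(got[["unmp"]], "UNMAPPED")
})

test_that("every simulated pair receives exactly one class", {
  h <- hom_aln()
  expect_setequal(h$pairs$qname, h$sim$names)
  expect_identical(anyDuplicated(h$pairs$qname), 0L)
  expect_identical(sum(table(h$pairs$class)), length(h$sim$names))
  # a HOM simulation must show genome+vector evidence
  expect_gt(sum(h$pairs$class == "CHIMERIC_GENOME_VECTOR"), 0L)
  expect_gt(sum(h$pairs$class == "VECTOR_INTERNAL"), 0L)
})

test_that("an error-free WT simulation classifies as genome-concordant", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  aln <- align_pairs(fix$wt_sim, idx)
  cls <- classify_pairs(aln)
  expect_identical(unique(cls$class), "GENOME_CONCORDANT")
})

test_that("SAM output round-trips all alignment record fields", {
  h <- hom_aln()
  sub_names <- unique(h$aln$qname)[1:500]
  aln <- h$aln[h$aln$qname %in% sub_names, ]
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, h$idx$contig_lengths, path, reads = h$sim)
  back <- read_sam(path)
  for (col in c("qname", "mate", "contig", "pos", "strand", "clip5",
                "clip3", "alen", "read_length", "nm", "score", "unique",
                "rank")) {
    expect_identical(back[[col]], aln[[col]], label = col)
  }
})

test_that("empty input yields a header-only SAM and an empty stream", {
  empty <- list(r1 = character(0), r2 = character(0), names = character(0))
  idx <- build_index(c(chr = withr::with_seed(2, rand_dna(5000))))
  aln <- align_pairs(empty, idx)
  expect_identical(nrow(aln), 0L)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, idx$contig_lengths, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "@")))
  expect_identical(nrow(read_sam(path)), 0L)
})

test_that("mate count mismatch and gapped external CIGARs are rejected", {
  idx <- build_index(c(chr = withr::with_seed(2, rand_dna(5000))))
  expect_error(align_pairs(list(r1 = c("ACGT"), r2 = character(0),
                                names = "x"), idx), "mate")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste("r1", 0, "chr", 100, 60, "50M2D100M", "*", 0, 0, "*",
                     "*", sep = "\t")), path)
  expect_error(read_sam(path), "gapped")
})
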