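# Synthetic reference and insertion-architecture construction.

test_that("wild-type reference is seeded-deterministic with fixed annotation", {
  a <- build_wt_reference(150000L, scale = 0.05, seed = 1L)
  b <- build_wt_reference(150000L, scale = 0.05, seed = 1L)
  c <- build_wt_reference(150000L, scale = 0.05, seed = 2L)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$annotations, b$annotations)
  expect_false(identical(a$contigs, c$contigs))
  # annotations depend only on the layout, not on the sequence seed
  expect_identical(a$annotations, c$annotations)
  expect_equal(nrow(a$annotations), 3L)
  genes <- setNames(a$annotations$start, a$annotations$name)
  expect_lt(genes[["tfap2d_analog"]], genes[["tfap2b_analog"]])
  expect_lt(genes[["tfap2b_analog"]], genes[["ak_analog"]])
})

test_that("unscaled layout does not fit a 500 kb contig", {
  # 250 kb + 100 kb offsets plus genes and deletions span ~600 kb unscaled
  expect_error(build_wt_reference(500000L, scale = 1.0, seed = 1L),
               "does not fit")
  expect_silent(build_wt_reference(700000L, scale = 1.0, seed = 1L))
})

test_that("transgenic haplotype length obeys the composition identity", {
  # |tg| = |wt| - sum(deletions) + copies * |vector| + |ins1 fragment|,
  # checked by independent summation over several random architectures
  for (copies in c(1L, 3L, 5L)) {
    arch <- insertion_architecture(fix$ref, ins2_copies = copies)
    tg <- apply_architecture(fix$ref, fix$vec, arch)
    expected <- fix$ref$contig_length -
      sum(arch$deletions$end - arch$deletions$start) +
      copies * fix$vec$length + diff(fix$vec$ins1_fragment)
    expect_identical(nchar(tg$haplotype), as.integer(expected))
    expect_identical(tg$truth$tg_length, as.integer(expected))
  }
})

test_that("one concatemer copy with no deletions adds one vector length", {
  arch <- insertion_architecture(
    fix$ref, ins2_copies = 1L,
    deletions = data.frame(name = character(0), start = integer(0),
                           end = integer(0)))
  vec1 <- vector_construct(seed = 7L,
                           ins1_fragment = c(0L, 1L))  # 1 b token fragment
  tg <- apply_architecture(fix$ref, vec1, arch)
  expect_identical(nchar(tg$haplotype),
                   fix$ref$contig_length + vec1$length + 1L)
})

test_that("the largest deletion removes the ak analog sequence", {
  ak <- fix$ref$annotations[fix$ref$annotations$name == "ak_analog", ]
  ak_seq <- substring(fix$ref$contigs[[1]], ak$start + 1L, ak$end)
  expect_true(grepl(ak_seq, fix$ref$contigs[[1]], fixed = TRUE))
  expect_false(grepl(ak_seq, fix$tg$haplotype, fixed = TRUE))
})

test_that("deletions overlapping an insertion point are rejected", {
  bad <- fix$arch$deletions
  bad$start[1] <- fix$ref$layout$ins1_point - 50L
  bad$end[1] <- fix$ref$layout$ins1_point + 50L
  arch <- insertion_architecture(fix$ref, deletions = bad)
  expect_error(apply_architecture(fix$ref, fix$vec, arch),
               "insertion point")
})

test_that("largest deletion must contain the ak analog", {
  moved <- fix$arch$deletions
  big <- which.max(moved$end - moved$start)
  moved$start[big] <- moved$start[big] + 2000L
  moved$end[big] <- moved$end[big] + 2000L
  arch <- insertion_architecture(fix$ref, deletions = moved)
  expect_error(apply_architecture(fix$ref, fix$vec, arch), "ak_analog")
})

test_that("liftover round-trips outside modified segments", {
  truth <- fix$tg$truth
  set.seed(31)
  pos <- sort(sample.int(fix$ref$contig_length, 500L)) - 1L
  tg_pos <- liftover(truth, pos, from = "wt")
  in_del <- vapply(pos, function(p) {
    any(p >= truth$deletions$start & p < truth$deletions$end)
  }, logical(1))
  expect_true(all(is.na(tg_pos[in_del])))
  expect_true(all(!is.na(tg_pos[!in_del])))
  back <- liftover(truth, tg_pos[!in_del], from = "tg")
  expect_identical(back, pos[!in_del])

  # transgenic positions inside inserted sequence have no wild-type image
  j_ins2 <- liftover(truth, truth$junctions$raw_pos[3] - 1L, from = "wt")
  expect_true(is.na(liftover(truth, j_ins2 + 11L, from = "tg")))
})

test_that("truth junctions mark real discontinuities in the haplotype", {
  truth <- fix$tg$truth
  g <- fix$ref$contigs[[1]]
  at <- function(s, i0) substring(s, i0 + 1L, i0 + 1L)
  for (i in seq_len(nrow(truth$junctions))) {
    j <- truth$junctions[i, ]
    if (j$side == "left") {
      # at the insert point the haplotype switches from genome to vector
      tg_pos <- liftover(truth, j$raw_pos - 1L, from = "wt")
      expect_identical(at(fix$tg$haplotype, tg_pos + 1L),
                       at(fix$vec$sequence,
                          j$vector_pos - (j$genome_pos - j$raw_pos)))
      # canonical form is the maximal genome extension: no further match
      expect_false(at(g, j$genome_pos) == at(fix$vec$sequence, j$vector_pos))
    } else {
      expect_false(at(g, j$genome_pos - 1L) ==
                     at(fix$vec$sequence, j$vector_pos - 1L))
    }
  }
})

test_that("truth sets survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_set(fix$tg$truth, path)
  back <- read_truth_set(path)
  expect_equal(back$junctions, fix$tg$truth$junctions)
  expect_equal(back$deletions$start, fix$tg$truth$deletions$start)
  expect_identical(back$ins2_copies, fix$tg$truth$ins2_copies)
  expect_identical(back$tg_length, fix$tg$truth$tg_length)
})

test_that("reference files are written in standard formats", {
  dir <- withr::local_tempdir()
  paths <- write_reference_files(fix$ref, fix$vec, dir, fix$tg$truth)
  comp <- Biostrings::readDNAStringSet(paths[["composite"]])
  expect_identical(names(comp), c(fix$ref$contig_name, "vector"))
  expect_identical(as.character(comp[["vector"]]), fix$vec$sequence)
  gff <- rtracklayer::import(paths[["gff"]])
  expect_identical(length(gff), 3L)
  expect_identical(GenomicRanges::start(gff) - 1L, fix$ref$annotations$start)
})
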