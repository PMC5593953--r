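# Junction-evidence collection, clustering, insertion calls and the
# depth-ratio copy-number estimate.

test_that("a WT simulation yields no junction evidence", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  aln <- align_pairs(fix$wt_sim, idx)
  ev <- collect_evidence(classify_pairs(aln), aln)
  expect_identical(nrow(ev), 0L)
  calls <- call_insertions(cluster_evidence(ev))
  expect_identical(nrow(calls), 0L)
})

test_that("a single chimeric pair yields one evidence item", {
  aln <- data.frame(
    qname = c("p", "p"), mate = c(1L, 2L), contig = c("chrS", "vector"),
    pos = c(1000L, 50L), strand = c("+", "-"), clip5 = 0L, clip3 = 0L,
    alen = 150L, read_length = 150L, nm = 0L, score = 150L, unique = TRUE,
    rank = 1L, stringsAsFactors = FALSE)
  ev <- collect_evidence(classify_pairs(aln), aln)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "chimeric_pair")
  expect_identical(ev$genome_pos, 1150L)  # outer (junction-facing) end
  expect_identical(ev$side, "left")
  expect_identical(ev$orientation, "+")
})

test_that("single-linkage clustering separates distant evidence", {
  ev <- data.frame(kind = "chimeric_pair", qname = c("a", "b", "c"),
                   genome_pos = c(100L, 150L, 5000L), side = "left",
                   orientation = "+", vector_lo = 0L, vector_hi = 100L,
                   stringsAsFactors = FALSE)
  cl <- cluster_evidence(ev, window = 500)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_identical(cl$cluster[cl$genome_pos == 5000L], 2L)
  # order independence
  cl2 <- cluster_evidence(ev[c(3, 1, 2), ], window = 500)
  expect_identical(cl2, cl)
  # empty in, empty out
  expect_identical(nrow(cluster_evidence(ev[0, ])), 0L)
})

test_that("clusters below min_support produce no call", {
  ev <- data.frame(kind = "chimeric_pair", qname = c("a", "b"),
                   genome_pos = c(100L, 120L), side = c("left", "right"),
                   orientation = "+", vector_lo = 0L, vector_hi = 100L,
                   stringsAsFactors = FALSE)
  expect_identical(nrow(call_insertions(cluster_evidence(ev),
                                        min_support = 3L)), 0L)
  expect_identical(nrow(call_insertions(cluster_evidence(ev),
                                        min_support = 2L)), 1L)
})

test_that("HOM evidence recovers both sub-sites at base resolution", {
  h <- hom_aln()
  ev <- collect_evidence(h$pairs, h$aln)
  truth_pos <- h$truth$junctions$genome_pos
  # all evidence lies within a fragment length of a true junction
  expect_true(all(vapply(ev$genome_pos, function(p) {
    min(abs(p - truth_pos)) <= 760
  }, logical(1))))

  cl <- cluster_evidence(ev, window = 1100)
  calls <- call_insertions(cl, min_support = 3L)
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$resolution, c("base_pair", "base_pair"))
  for (site in c("Ins1", "Ins2")) {
    jp <- unique(truth_pos[h$truth$junctions$site == site])
    expect_true(any(vapply(calls$breakpoint_lo, function(b) {
      min(abs(b - jp)) <= 1
    }, logical(1))), label = site)
  }
  # the Ins1 call's vector interval matches the 517 b fragment
  f <- fix$vec$ins1_fragment
  ins1 <- calls[which.min(abs(calls$breakpoint_lo - truth_pos[1])), ]
  expect_lt(abs(ins1$vector_lo - f[1]), 25)
  expect_lt(abs(ins1$vector_hi - f[2]), 25)
})

test_that("raising min_support never increases the number of calls", {
  h <- hom_aln()
  cl <- cluster_evidence(collect_evidence(h$pairs, h$aln))
  n <- vapply(1:60, function(ms) nrow(call_insertions(cl, ms)), integer(1))
  expect_true(all(diff(n) <= 0))
  expect_identical(n[3], 2L)
})

test_that("copy-number estimate needs genome coverage and is 0 for WT", {
  idx <- build_index(composite_reference(fix$ref, fix$vec))
  aln <- align_pairs(fix$wt_sim, idx)
  vprof <- compute_depth(aln, "vector", idx$contig_lengths)
  gprof <- compute_depth(aln, fix$ref$contig_name, idx$contig_lengths)
  est <- estimate_transgene_copies(vprof, gprof)
  expect_identical(est$copies_per_diploid, 0)

  none <- aln[0, ]
  empty_g <- compute_depth(none, fix$ref$contig_name, idx$contig_lengths)
  expect_error(estimate_transgene_copies(vprof, empty_g), "zero")
})

test_that("HOM depth ratio estimates twice the per-haplotype copy number", {
  h <- hom_aln()
  vprof <- compute_depth(h$aln, "vector", h$idx$contig_lengths)
  ins_points <- unique(h$truth$junctions$raw_pos)
  gprof <- compute_depth(h$aln, fix$ref$contig_name, h$idx$contig_lengths,
                         mask = rbind(
                           fix$arch$deletions[, c("start", "end")],
                           data.frame(start = ins_points - 550L,
                                      end = ins_points + 550L)))
  est <- estimate_transgene_copies(vprof, gprof)
  expect_gt(est$copies_per_diploid, 9)
  expect_lt(est$copies_per_diploid, 11.2)
})

test_that("insertion calls serialize to VCF breakends", {
  h <- hom_aln()
  calls <- call_insertions(cluster_evidence(collect_evidence(h$pairs,
                                                             h$aln)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_insertions_vcf(calls, "chrS", path)
  lines <- readLines(path)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), nrow(calls))
  f <- strsplit(body[1], "\t")[[1]]
  expect_identical(f[1], "chrS")
  expect_identical(as.integer(f[2]), calls$breakpoint_lo[1])
  expect_match(f[5], "^N\\[vector:\\d+\\[$")
  expect_match(f[8], "SVTYPE=BND")
})
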