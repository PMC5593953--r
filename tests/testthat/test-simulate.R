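# Paired-end read simulator and breeding-colony simulator.

test_that("error-free wild-type reads are exact substrings of the contig", {
  sim <- fix$wt_sim
  g <- fix$ref$contigs[[1]]
  tags <- parse_truth_tags(sim$names)
  expect_true(all(tags$hap == "wt"))
  idx <- sample(seq_along(sim$names), 300)
  for (i in idx) {
    frag <- substring(g, tags$start[i] + 1L, tags$end[i])
    # FR layout: the "+" mate reads the fragment's left end forward, its
    # partner the right end reverse-complemented
    left <- if (tags$strand[i] == "+") sim$r1[i] else sim$r2[i]
    right <- if (tags$strand[i] == "+") sim$r2[i] else sim$r1[i]
    expect_identical(left, substring(frag, 1L, 150L))
    expect_identical(revcomp(right),
                     substring(frag, nchar(frag) - 149L, nchar(frag)))
  }
})

test_that("total sequenced bases match the target depth within 5%", {
  paths <- c(withr::local_tempfile(), withr::local_tempfile())
  write_fastq(fix$wt_sim, paths[1], paths[2])
  bases <- sum(nchar(read_fastq(paths[1])$seqs)) +
    sum(nchar(read_fastq(paths[2])$seqs))
  expect_lt(abs(bases - 8 * 150000) / (8 * 150000), 0.05)
})

test_that("truth-tagged HOM reads show the expected vector depth ratio", {
  # oracle on truth tags only: bases falling in the concatemer plus Ins1
  # segments of the transgenic haplotype, divided by the 7 kb vector
  # length, versus per-base depth over the unique genome remainder; with
  # 5 copies per haplotype the mapped-depth ratio must be ~5
  sim <- simulate_reads(unname(fix$ref$contigs[[1]]), fix$tg$haplotype,
                        "HOM", read_sim_params(depth = 20, error_rate = 0,
                                               seed = 21L))
  truth <- fix$tg$truth
  tags <- parse_truth_tags(sim$names)
  conc_start <- liftover(truth, truth$junctions$raw_pos[3] - 1L,
                         from = "wt") + 1L
  vec_len <- truth$ins2_copies * truth$vector_length
  ins1_start <- liftover(truth, truth$junctions$raw_pos[1] - 1L,
                         from = "wt") + 1L
  vec_iv <- rbind(c(conc_start, conc_start + vec_len),
                  c(ins1_start, ins1_start + diff(truth$ins1_fragment)))
  read_iv <- rbind(cbind(tags$start, pmin(tags$start + 150L, tags$end)),
                   cbind(pmax(tags$end - 150L, tags$start), tags$end))
  vec_bases <- sum(vapply(seq_len(nrow(vec_iv)), function(j) {
    sum(pmax(0L, pmin(read_iv[, 2], vec_iv[j, 2]) -
                 pmax(read_iv[, 1], vec_iv[j, 1])))
  }, numeric(1)))
  tot_bases <- sum(read_iv[, 2] - read_iv[, 1])
  g_len <- truth$tg_length - vec_len - diff(truth$ins1_fragment)
  ratio <- (vec_bases / truth$vector_length) /
    ((tot_bases - vec_bases) / g_len)
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 5.5)
})

test_that("substitution errors appear at the configured rate", {
  sim <- simulate_reads(unname(fix$ref$contigs[[1]]), fix$tg$haplotype,
                        "WT", read_sim_params(depth = 4, error_rate = 0.01,
                                              seed = 9L))
  g <- fix$ref$contigs[[1]]
  tags <- parse_truth_tags(sim$names)
  mism <- 0L
  for (i in seq_len(500L)) {
    frag <- substring(g, tags$start[i] + 1L, tags$end[i])
    left <- if (tags$strand[i] == "+") sim$r1[i] else sim$r2[i]
    src <- substring(frag, 1L, 150L)
    mism <- mism + sum(strsplit(left, "")[[1]] != strsplit(src, "")[[1]])
  }
  rate <- mism / (500 * 150)
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
})

test_that("identical seed and parameters give byte-identical FASTQ", {
  p <- replicate(4, tempfile(fileext = ".fastq"))
  withr::defer(unlink(p))
  args <- list(unname(fix$ref$contigs[[1]]), fix$tg$haplotype, "HET",
               read_sim_params(depth = 2, seed = 33L))
  write_fastq(do.call(simulate_reads, args), p[1], p[2])
  write_fastq(do.call(simulate_reads, args), p[3], p[4])
  expect_identical(readLines(p[1]), readLines(p[3]))
  expect_identical(readLines(p[2]), readLines(p[4]))
  args2 <- args; args2[[4]]$seed <- 34L
  other <- do.call(simulate_reads, args2)
  expect_false(identical(readLines(p[1]),
                         c(rbind(paste0("@", other$names), other$r1, "+",
                                 other$qual1))))
})

test_that("genotypes require their source haplotypes", {
  expect_error(simulate_reads(fix$ref$contigs[[1]], NULL, "HOM"),
               "transgenic")
  expect_error(simulate_reads(NULL, fix$tg$haplotype, "HET"), "wild-type")
})

test_that("simulated colonies follow 1:2:1 segregation with penetrance", {
  tab0 <- simulate_colony(500, penetrance = 0, seed = 1L)
  expect_identical(tab0$n_pos_glaucoma, 0L)
  expect_identical(tab0$total, 500L)

  n <- 20000L
  tab <- simulate_colony(n, penetrance = 0.75, seed = 2L)
  g <- attr(tab, "genotype_counts")
  expect_identical(sum(g), n)
  expect_identical(tab$n_neg + tab$n_pos_normal + tab$n_pos_glaucoma, n)
  # genotype fractions converge to (1/4, 1/2, 1/4)
  expect_lt(max(abs(g / n - c(0.25, 0.5, 0.25))), 0.02)
  # glaucoma fraction: closed form 0.25 * 0.75, within 3 binomial SDs
  p <- 0.25 * 0.75
  expect_lt(abs(tab$n_pos_glaucoma / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a colony near the real size shows ~19% glaucoma", {
  tab <- simulate_colony(433, penetrance = 0.75, seed = 5L)
  pct <- 100 * tab$n_pos_glaucoma / tab$total
  expect_gt(pct, 13)
  expect_lt(pct, 25)
})
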