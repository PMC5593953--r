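# End-to-end orchestration: simulate -> map -> call insertions -> call
# CNV/deletions -> segregation statistics, as one reproducible, seeded run
# with optional on-disk artifacts and a consolidated report.

#' Assemble a run configuration
#'
#' All module parameters with their defaults, plus the single top-level
#' seed every stochastic stage derives from. The effective configuration
#' is written verbatim into the run's output directory.
#'
#' @param seed Top-level RNG seed.
#' @param genotype Simulated individual: `"WT"`, `"HET"` or `"HOM"`.
#' @param contig_length,scale,contig_name Wild-type reference parameters.
#' @param vector_length,ins1_fragment Vector construct parameters.
#' @param ins2_copies,ins2_orientations Concatemer parameters.
#' @param depth,error_rate,read_length,insert_mean,insert_sd Read
#'   simulation parameters.
#' @param k,min_clip Mapper parameters (see [mapper_params()]).
#' @param cluster_window,min_support Insertion-caller parameters; the
#'   default cluster window is `2 * insert_mean`.
#' @param cnv_window,hom_max,het_band,min_windows Depth/CNV parameters.
#' @param colony `list(n_offspring=, penetrance=)` to simulate an F2
#'   colony, or `NULL`.
#' @param tables_tsv Path to a transmission-table TSV to analyse, `NULL`
#'   to skip, or `"packaged"` for the packaged colony tables.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, genotype = "HOM",
                       contig_length = 500000L, scale = 0.05,
                       contig_name = "chrS",
                       vector_length = 7000L, ins1_fragment = NULL,
                       ins2_copies = 5L, ins2_orientations = NULL,
                       depth = 30, error_rate = 0.002, read_length = 150L,
                       insert_mean = 550, insert_sd = 60,
                       k = 21L, min_clip = 20L,
                       cluster_window = NULL, min_support = 3L,
                       cnv_window = 200L, hom_max = 0.2,
                       het_band = c(0.3, 0.7), min_windows = 3L,
                       colony = NULL, tables_tsv = "packaged") {
  cfg <- list(seed = as.integer(seed), genotype = genotype,
              contig_length = as.integer(contig_length), scale = scale,
              contig_name = contig_name,
              vector_length = as.integer(vector_length),
              ins1_fragment = ins1_fragment,
              ins2_copies = as.integer(ins2_copies),
              ins2_orientations = ins2_orientations,
              depth = depth, error_rate = error_rate,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              k = as.integer(k), min_clip = as.integer(min_clip),
              cluster_window = cluster_window %||% (2 * insert_mean),
              min_support = as.integer(min_support),
              cnv_window = as.integer(cnv_window), hom_max = hom_max,
              het_band = het_band, min_windows = as.integer(min_windows),
              colony = colony, tables_tsv = tables_tsv)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, Filter(Negate(is.null), yaml::read_yaml(path)))
}

run_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

run_stage <- function(stage, outdir, quiet, expr) {
  if (!quiet) run_log(stage, "start")
  tryCatch(expr, error = function(e) {
    if (!is.null(outdir)) {
      writeLines(paste0("failed at stage: ", stage, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
    }
    stop_tgloc("stage '", stage, "' failed: ", conditionMessage(e))
  })
}

# re-derive masked flags and normalization for an existing profile
mask_profile <- function(profile, mask) {
  masked <- rep(FALSE, length(profile$start))
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      masked <- masked | interval_overlap(
        profile$start, profile$start + profile$width,
        mask$start[i], mask$end[i]) > 0L
    }
  }
  profile$masked <- masked
  med <- median(profile$raw[!masked])
  profile$median_raw <- if (is.finite(med) && med > 0) med else NA_real_
  profile$norm <- if (is.na(profile$median_raw)) profile$raw * NA_real_
                  else profile$raw / profile$median_raw
  profile
}

#' Run the full pipeline
#'
#' Executes reference construction, read simulation, mapping, pair
#' classification, insertion calling, depth/deletion/copy-number analysis
#' and segregation statistics in order. Identical configuration and seed
#' give an identical report (and byte-identical artifacts).
#'
#' @param config A `run_config`.
#' @param outdir Output directory for artifacts (`reads/`, `aln/`,
#'   `calls/`, `report/`); `NULL` runs in memory only.
#' @param quiet Suppress stage log messages.
#' @return Object of class `run_report`.
#' @export
run_all <- function(config = run_config(), outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(outdir)) {
    for (d in c("", "ref", "reads", "aln", "calls", "report")) {
      dir.create(file.path(outdir, d), recursive = TRUE,
                 showWarnings = FALSE)
    }
    write_run_config(config, file.path(outdir, "config.yaml"))
  }

  ref <- vec <- truth <- hap <- sim <- idx <- aln <- NULL
  run_stage("simulate", outdir, quiet, {
    ref <- build_wt_reference(config$contig_length, config$scale,
                               seed = config$seed,
                               contig_name = config$contig_name)
    vec <- vector_construct(length = config$vector_length,
                             ins1_fragment = config$ins1_fragment,
                             seed = config$seed + 7L)
    arch <- insertion_architecture(ref, config$ins2_copies,
                                   config$ins2_orientations)
    tg <- apply_architecture(ref, vec, arch)
    truth <- tg$truth
    hap <- tg$haplotype
    sim <- simulate_reads(
      unname(ref$contigs[[1]]), hap, config$genotype,
      read_sim_params(read_length = config$read_length,
                      insert_mean = config$insert_mean,
                      insert_sd = config$insert_sd,
                      error_rate = config$error_rate,
                      depth = config$depth, seed = config$seed + 77L),
      wt_name = config$contig_name,
      tg_name = paste0(config$contig_name, "_tg"))
    if (!is.null(outdir)) {
      write_reference_files(ref, vec, file.path(outdir, "ref"), truth)
      write_fastq(sim, file.path(outdir, "reads", "sim_R1.fastq"),
                  file.path(outdir, "reads", "sim_R2.fastq"))
    }
  })

  mp <- mapper_params(k = config$k, min_clip = config$min_clip,
                      insert_mean = config$insert_mean,
                      insert_sd = config$insert_sd)
  pairs <- NULL
  run_stage("map", outdir, quiet, {
    idx <- build_index(composite_reference(ref, vec), k = config$k)
    aln <- align_pairs(sim, idx, mp)
    pairs <- classify_pairs(aln, mp, vec$name)
    if (!is.null(outdir)) {
      write_sam(aln, idx$contig_lengths, file.path(outdir, "aln", "aln.sam"),
                reads = sim)
    }
  })

  ins_calls <- NULL
  run_stage("call-insertions", outdir, quiet, {
    ev <- collect_evidence(pairs, aln, mp, vec$name)
    cl <- cluster_evidence(ev, window = config$cluster_window)
    ins_calls <- call_insertions(cl, min_support = config$min_support)
    if (!is.null(outdir)) {
      write_insertions_vcf(ins_calls, config$contig_name,
                           file.path(outdir, "calls", "insertions.vcf"),
                           vec$name, mp)
      write_insertions_tsv(ins_calls, config$contig_name,
                           file.path(outdir, "calls", "insertions.tsv"))
    }
  })

  del_calls <- cn <- locus_gt <- NULL
  run_stage("call-cnv", outdir, quiet, {
    gprof <- compute_depth(aln, config$contig_name, idx$contig_lengths,
                           window = config$cnv_window)
    del_calls <- call_deletions(
      gprof, config$hom_max, config$het_band, config$min_windows,
      clip_positions = clip_boundaries(aln, config$contig_name,
                                       config$min_clip))
    del_calls <- annotate_overlaps(del_calls, ref$annotations)

    flank <- config$insert_mean
    ins_mask <- if (nrow(ins_calls)) {
      data.frame(start = ins_calls$breakpoint_lo - flank,
                 end = ins_calls$breakpoint_hi + flank)
    } else data.frame(start = integer(0), end = integer(0))
    full_mask <- rbind(ins_mask,
                       data.frame(start = del_calls$start,
                                  end = del_calls$end))
    vprof <- compute_depth(aln, vec$name, idx$contig_lengths,
                           window = config$cnv_window)
    cn <- estimate_transgene_copies(vprof,
                                     mask_profile(gprof, full_mask))

    # genotype the ak locus against a background that masks the insertion
    # flanks and the other deletions, but not the assayed locus itself
    ak <- ref$annotations[ref$annotations$name == "ak_analog", ]
    locus <- c(ak$start, ak$end)
    keep <- interval_overlap(full_mask$start, full_mask$end,
                             locus[1], locus[2]) == 0L
    locus_gt <- genotype_locus_copy_number(
      mask_profile(gprof, full_mask[keep, , drop = FALSE]),
      locus, name = "ak_analog")
    if (!is.null(outdir)) {
      write_deletions_bed(del_calls, config$contig_name,
                          file.path(outdir, "calls", "deletions.bed"))
      writeLines(sprintf("locus\tcopies\tclass\tmean_norm\n%s\t%d\t%s\t%.4f",
                         locus_gt$name, locus_gt$copies, locus_gt$class,
                         locus_gt$mean_norm),
                 file.path(outdir, "calls", "locus_genotype.tsv"))
    }
  })

  segregation <- NULL
  run_stage("segregation", outdir, quiet, {
    segregation <- list()
    tsv <- config$tables_tsv
    if (identical(tsv, "packaged")) {
      tsv <- system.file("extdata", "transmission_tables.tsv",
                         package = "tgloc")
    }
    if (!is.null(tsv) && nzchar(tsv)) {
      for (tab in read_transmission_tsv(tsv, quiet = TRUE)) {
        segregation[[tab$label]] <- segregation_report(tab)
      }
    }
    if (!is.null(config$colony)) {
      tab <- simulate_colony(config$colony$n_offspring,
                             config$colony$penetrance,
                             seed = config$seed + 777L,
                             label = "simulated_colony")
      segregation[["simulated_colony"]] <- segregation_report(tab)
    }
  })

  report <- structure(list(
    config = config,
    contig = config$contig_name,
    insertion_calls = ins_calls,
    deletion_calls = del_calls,
    copy_number = cn,
    locus_genotype = locus_gt,
    segregation = segregation,
    class_counts = table(pairs$class),
    n_pairs = length(sim$names),
    truth = truth
  ), class = "run_report")
  report$truth_metrics <- compare_to_truth(report, truth)

  if (!is.null(outdir)) {
    run_stage("report", outdir, quiet, {
      out <- report[c("contig", "n_pairs")]
      out$insertion_calls <- as.data.frame(ins_calls)
      out$deletion_calls <- as.data.frame(
        del_calls[, setdiff(names(del_calls), "genes")])
      out$copy_number = unclass(cn)
      out$locus_genotype = unclass(locus_gt)
      out$class_counts = as.list(report$class_counts)
      out$segregation <- lapply(segregation, function(s) list(
        label = s$label,
        p_mendelian = s$mendelian$p, p_mendelian_rounded = s$mendelian$p_rounded,
        p_homozygote = s$homozygote_glaucoma$p,
        p_homozygote_rounded = s$homozygote_glaucoma$p_rounded,
        penetrance = s$penetrance$penetrance, summary = s$summary))
      out$truth_metrics <- report$truth_metrics
      jsonlite::write_json(out, file.path(outdir, "report", "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", force = TRUE)
    })
  }
  report
}

#' Compare a run report with its truth set
#'
#' @param report A `run_report` (or a list with `insertion_calls`,
#'   `deletion_calls`, `copy_number`, `locus_genotype`, `contig` and
#'   `config`).
#' @param truth The `truth_set` from the same simulation.
#' @return List of class `truth_metrics`: per-site breakpoint errors in
#'   bases, per-deletion reciprocal overlaps and zygosity correctness,
#'   copy-number error and locus-genotype correctness.
#' @export
compare_to_truth <- function(report, truth) {
  if (!identical(report$contig, truth$contig)) {
    stop_tgloc("report contig does not match truth contig")
  }
  genotype <- report$config$genotype
  calls <- report$insertion_calls

  site_err <- lapply(split(truth$junctions, truth$junctions$site),
                     function(j) {
    targets <- unique(c(j$genome_pos, j$raw_pos))
    if (is.null(calls) || nrow(calls) == 0L) return(NA_real_)
    d <- vapply(seq_len(nrow(calls)), function(i) {
      lo <- calls$breakpoint_lo[i]; hi <- calls$breakpoint_hi[i]
      min(ifelse(targets >= lo & targets <= hi, 0,
                 pmin(abs(targets - lo), abs(targets - hi))))
    }, numeric(1))
    min(d)
  })

  del_metrics <- NULL
  dels <- report$deletion_calls
  expected_zyg <- switch(genotype, HOM = "hom", HET = "het", WT = NA)
  for (i in seq_len(nrow(truth$deletions))) {
    ts <- truth$deletions$start[i]; te <- truth$deletions$end[i]
    ro <- 0; zyg_ok <- NA
    if (!is.null(dels) && nrow(dels) > 0L) {
      ov <- interval_overlap(dels$start, dels$end, ts, te)
      rec <- pmin(ov / (te - ts), ov / (dels$end - dels$start))
      j <- which.max(rec)
      ro <- rec[j]
      if (!is.na(expected_zyg) && ro > 0) {
        zyg_ok <- dels$zygosity[j] == expected_zyg
      }
    }
    del_metrics <- rbind(del_metrics, data.frame(
      name = truth$deletions$name[i], reciprocal_overlap = ro,
      zygosity_correct = zyg_ok))
  }

  n_hap <- switch(genotype, WT = 0, HET = 1, HOM = 2)
  expected_copies <- n_hap * (truth$ins2_copies +
    diff(truth$ins1_fragment) / truth$vector_length)
  expected_locus <- switch(genotype, WT = 2L, HET = 1L, HOM = 0L)

  structure(list(
    n_insertion_calls = if (is.null(calls)) 0L else nrow(calls),
    breakpoint_error = unlist(site_err),
    deletion_metrics = del_metrics,
    copy_number_error = if (is.null(report$copy_number)) NA_real_ else
      report$copy_number$copies_per_diploid - expected_copies,
    expected_copies = expected_copies,
    locus_genotype_correct = if (is.null(report$locus_genotype)) NA else
      report$locus_genotype$copies == expected_locus
  ), class = "truth_metrics")
}

#' @export
print.run_report <- function(x, ...) {
  cat("tgloc run report\n")
  cat(sprintf("  genotype: %s, seed: %d, contig: %s\n",
              x$config$genotype, x$config$seed, x$contig))
  cat(sprintf("  fragments simulated: %d\n", x$n_pairs))
  cat(sprintf("  insertion calls: %d\n", nrow(x$insertion_calls)))
  for (i in seq_len(nrow(x$insertion_calls))) {
    cat(sprintf("    [%d] breakpoint %d..%d (%s; %d split, %d pairs)\n", i,
                x$insertion_calls$breakpoint_lo[i],
                x$insertion_calls$breakpoint_hi[i],
                x$insertion_calls$resolution[i],
                x$insertion_calls$n_split[i], x$insertion_calls$n_pairs[i]))
  }
  cat(sprintf("  deletion calls: %d\n", nrow(x$deletion_calls)))
  if (!is.null(x$copy_number)) {
    cat(sprintf("  transgene copies per diploid: %.2f\n",
                x$copy_number$copies_per_diploid))
  }
  if (!is.null(x$locus_genotype)) {
    cat(sprintf("  ak_analog locus copies: %d (%s)\n",
                x$locus_genotype$copies, x$locus_genotype$class))
  }
  invisible(x)
}
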