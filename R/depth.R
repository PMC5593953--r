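# Windowed read-depth profiles, depth-based deletion calling with
# changepoint boundary refinement, and the categorical 2/1/0 locus
# copy-number genotype.

#' Compute a windowed depth profile
#'
#' Depth per window is the count of uniquely-aligned bases falling in the
#' window divided by the window width (the final partial window uses its
#' true width), computed from primary, unique alignment records only.
#' Normalized depth divides by the median over unmasked windows.
#'
#' @param aln Alignment data frame.
#' @param contig Contig to profile.
#' @param contig_lengths Named integer vector of reference contig lengths
#'   (e.g. `index$contig_lengths`), or a bare length for `contig`.
#' @param window Window size in bases.
#' @param mask Optional data frame (`start`, `end`, 0-based half-open) of
#'   intervals whose windows are excluded from normalization.
#' @return Object of class `depth_profile`.
#' @export
compute_depth <- function(aln, contig, contig_lengths, window = 200L,
                          mask = NULL) {
  if (!is.null(names(contig_lengths))) {
    if (!contig %in% names(contig_lengths)) {
      stop_tgloc("contig '", contig, "' absent from the reference")
    }
    contig_length <- contig_lengths[[contig]]
  } else {
    contig_length <- contig_lengths
  }
  if (!is.null(aln$rank)) aln <- aln[aln$rank == 1L & aln$unique, ,
                                     drop = FALSE]
  rows <- aln[aln$contig == contig, , drop = FALSE]
  cov <- if (nrow(rows) == 0L) {
    S4Vectors::Rle(0L, contig_length)
  } else {
    IRanges::coverage(IRanges::IRanges(start = rows$pos + 1L,
                                       width = rows$alen),
                      width = contig_length)
  }
  starts <- seq(1L, contig_length, by = window)
  ends <- pmin(starts + window - 1L, contig_length)
  width <- ends - starts + 1L
  raw <- as.numeric(IRanges::viewSums(
    IRanges::Views(cov, start = starts, end = ends))) / width
  masked <- rep(FALSE, length(starts))
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      masked <- masked |
        interval_overlap(starts - 1L, ends, mask$start[i], mask$end[i]) > 0L
    }
  }
  med <- median(raw[!masked])
  if (!is.finite(med) || med == 0) med <- NA_real_
  structure(list(
    contig = contig, contig_length = as.integer(contig_length),
    window = as.integer(window),
    start = starts - 1L, width = width,          # 0-based half-open
    raw = raw, norm = if (is.na(med)) raw * NA_real_ else raw / med,
    masked = masked, median_raw = med,
    total_aligned_bases = sum(as.numeric(rows$alen)),
    coverage = cov
  ), class = "depth_profile")
}

# Joint two-changepoint refinement: fit a three-segment piecewise-constant
# model (background | loss | background) to per-base coverage over the run
# plus `pad` flanking bases, minimizing total SSE over both cut positions.
# Jointly fitting both cuts keeps the big coverage steps in control even
# when window-level run edges were dragged around by noisy windows.
refine_run <- function(cov, run_start, run_end, pad) {
  a <- max(0L, run_start - pad)
  b <- min(length(cov), run_end + pad)
  x <- as.numeric(cov[(a + 1L):b])
  n <- length(x)
  if (n < 4L) return(c(run_start, run_end))
  S <- c(0, cumsum(x)); Q <- c(0, cumsum(x^2))
  seg_sse <- function(i, j) {  # region-local [i, j), 0-based, vectorized
    len <- pmax(j - i, 1L)
    (Q[j + 1L] - Q[i + 1L]) - (S[j + 1L] - S[i + 1L])^2 / len
  }
  mid <- max(1L, min(n - 2L, (run_start + run_end) %/% 2L - a))
  s_cand <- seq.int(1L, min(run_start - a + pad, mid))
  e_cand <- seq.int(max(run_end - a - pad, mid + 1L), min(n - 1L, b - a))
  best <- c(NA_real_, run_start, run_end)
  left <- seg_sse(rep(0L, length(s_cand)), s_cand)
  for (k in seq_along(s_cand)) {
    s <- s_cand[k]
    if (s >= min(e_cand)) ec <- e_cand[e_cand > s] else ec <- e_cand
    if (!length(ec)) next
    tot <- left[k] + seg_sse(rep(s, length(ec)), ec) +
      seg_sse(ec, rep(n, length(ec)))
    j <- which.min(tot)
    if (is.na(best[1]) || tot[j] < best[1]) {
      best <- c(tot[j], a + s, a + ec[j])
    }
  }
  as.integer(best[2:3])
}

#' Call deletions from a normalized depth profile
#'
#' Maximal runs of at least `min_windows` consecutive depth-loss windows
#' (normalized depth below the upper edge of `het_band`) become calls;
#' treating everything below the band's ceiling as one loss state merges
#' adjacent compatible windows into a single run even when individual
#' windows fluctuate between the homozygous and heterozygous depth
#' ranges. The run's zygosity comes from its mean normalized depth: below
#' `hom_max` homozygous, otherwise heterozygous. Call boundaries are then
#' refined to base resolution by a two-segment changepoint fit on the
#' per-base coverage around each run edge.
#'
#' @param profile A `depth_profile`.
#' @param hom_max Normalized-depth ceiling for homozygous loss.
#' @param het_band Normalized-depth interval for heterozygous loss.
#' @param min_windows Minimum number of loss windows per run.
#' @param refine Refine boundaries on per-base coverage.
#' @param edge_exclude Calls lying entirely within this many bases of a
#'   contig end are dropped: fragment sampling cannot extend past the
#'   ends, so coverage ramps over roughly one fragment length there and
#'   mimics loss.
#' @param clip_positions Optional integer vector of soft-clip boundary
#'   coordinates from the alignments on this contig (see
#'   [clip_boundaries()]). Reads crossing a deletion junction are clipped
#'   exactly at the boundary, so a refined boundary is snapped to the
#'   modal clip position nearby (at least two supporting reads), giving
#'   base-precise edges.
#' @return Data frame of class `deletion_calls`: `start`, `end` (0-based
#'   half-open), `zygosity`, `mean_norm`, `n_windows`.
#' @export
call_deletions <- function(profile, hom_max = 0.2, het_band = c(0.3, 0.7),
                           min_windows = 3L, refine = TRUE,
                           edge_exclude = 700L, clip_positions = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  loss <- !is.na(profile$norm) & profile$norm < het_band[2]
  # close single-window gaps whose depth is still visibly depressed, so a
  # lone in-run window fluctuating above the band does not split a run
  n <- length(loss)
  if (n >= 3L) {
    gap <- !loss & c(FALSE, loss[-n])[seq_len(n)] &
      c(loss[-1L], FALSE) & !is.na(profile$norm) & profile$norm < 0.85
    loss <- loss | gap
  }
  # window-level noise scale for the run-depth significance test
  sigma <- stats::mad(profile$norm[!profile$masked & !loss], center = 1,
                      na.rm = TRUE)
  if (!is.finite(sigma) || sigma == 0) sigma <- 0.1
  r <- rle(loss)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = integer(0), end = integer(0),
                    zygosity = character(0), mean_norm = numeric(0),
                    n_windows = integer(0), stringsAsFactors = FALSE)
  for (j in which(keep)) {
    wi <- starts_i[j]:ends_i[j]
    # gap-closing windows do not count toward the run-length requirement
    if (sum(profile$norm[wi] < het_band[2], na.rm = TRUE) < min_windows) next
    mean_norm <- mean(profile$norm[wi])
    if (mean_norm > het_band[2]) next
    # the run mean must sit well below the diploid level relative to
    # window noise, or short stretches of marginally low windows would
    # pass as heterozygous losses
    if ((1 - mean_norm) * sqrt(length(wi)) / sigma < 5) next
    zygosity <- if (mean_norm < hom_max) "hom" else "het"
    s <- profile$start[starts_i[j]]
    e <- profile$start[ends_i[j]] + profile$width[ends_i[j]]
    if (refine) {
      se <- refine_run(profile$coverage, s, e, pad = 4L * profile$window)
      s <- snap_to_clips(se[1], clip_positions, 2L * profile$window)
      e <- snap_to_clips(se[2], clip_positions, 2L * profile$window)
      if (e <= s) next
    }
    if (s < edge_exclude ||
        e > profile$contig_length - edge_exclude) next
    out <- rbind(out, data.frame(
      start = s, end = e, zygosity = zygosity,
      mean_norm = mean_norm,
      n_windows = length(wi), stringsAsFactors = FALSE))
  }
  class(out) <- c("deletion_calls", class(out))
  out
}

# snap a refined boundary to the modal soft-clip coordinate within
# `window` bases, when at least two clipped reads agree on it
snap_to_clips <- function(pos, clip_positions, window) {
  if (is.null(clip_positions) || !length(clip_positions)) return(pos)
  near <- clip_positions[abs(clip_positions - pos) <= window]
  if (!length(near)) return(pos)
  t <- table(near)
  if (max(t) < 2L) return(pos)
  as.integer(names(t)[which.max(t)])
}

#' Soft-clip boundary coordinates on one contig
#'
#' Collects, from primary unique alignment records, the reference
#' coordinate at which each sufficiently long soft clip begins -- the
#' junction-facing edge of the aligned segment. These pile up at
#' structural-variant breakpoints and serve to sharpen depth-derived
#' deletion boundaries.
#'
#' @param aln Alignment data frame.
#' @param contig Contig name.
#' @param min_clip Minimum clip length counted.
#' @return Integer vector of 0-based boundary coordinates.
#' @export
clip_boundaries <- function(aln, contig, min_clip = 20L) {
  rows <- aln[aln$rank == 1L & aln$unique & aln$contig == contig, ,
              drop = FALSE]
  c(rows$pos[rows$clip5 >= min_clip],
    (rows$pos + rows$alen)[rows$clip3 >= min_clip])
}

#' Genotype locus copy number from depth
#'
#' The categorical 2/1/0 readout: `copies = round(2 * mean normalized
#' depth over the locus)`, clamped to `[0, 2]`, with the genotype class
#' mapped 2 to wild-type-like, 1 to heterozygote-like, 0 to
#' homozygote-like. The mean is weighted by each window's overlap with the
#' locus; masked windows are excluded.
#'
#' @param profile A `depth_profile`.
#' @param locus Integer pair, 0-based half-open locus interval.
#' @param name Locus label.
#' @return List of class `locus_genotype`: `locus`, `copies`, `class`,
#'   `mean_norm`.
#' @export
genotype_locus_copy_number <- function(profile, locus, name = "locus") {
  stopifnot(inherits(profile, "depth_profile"))
  if (locus[1] < 0L || locus[2] > profile$contig_length ||
      locus[2] <= locus[1]) {
    stop_tgloc("locus must be a non-empty interval within the contig")
  }
  ov <- interval_overlap(profile$start, profile$start + profile$width,
                         locus[1], locus[2])
  use <- ov > 0L & !profile$masked & !is.na(profile$norm)
  if (!any(use)) stop_tgloc("locus fully masked; genotype undefined")
  mean_norm <- sum(profile$norm[use] * ov[use]) / sum(ov[use])
  copies <- max(0L, min(2L, as.integer(round(2 * mean_norm))))
  structure(list(
    name = name, locus = as.integer(locus), copies = copies,
    class = c("hom_like", "het_like", "wt_like")[copies + 1L],
    mean_norm = mean_norm), class = "locus_genotype")
}

#' Annotate deletion calls with overlapping genes
#'
#' @param calls A `deletion_calls` data frame.
#' @param genes Gene data frame (`name`, `start`, `end`, 0-based
#'   half-open), e.g. `ref$annotations`.
#' @return `calls` with a `genes` list-column; each element is a data
#'   frame of overlapping genes with the fraction of the gene covered.
#' @export
annotate_overlaps <- function(calls, genes) {
  calls$genes <- lapply(seq_len(nrow(calls)), function(i) {
    ov <- interval_overlap(genes$start, genes$end,
                           calls$start[i], calls$end[i])
    hit <- ov > 0L
    data.frame(name = genes$name[hit],
               overlap_fraction = ov[hit] / (genes$end[hit] -
                                             genes$start[hit]),
               stringsAsFactors = FALSE)
  })
  calls
}

#' Write deletion calls as BED
#'
#' BED is 0-based half-open, matching the internal convention; zygosity
#' and mean normalized depth go in columns 4-5.
#'
#' @param calls A `deletion_calls` data frame.
#' @param contig Contig name.
#' @param path Output path.
#' @export
write_deletions_bed <- function(calls, contig, path) {
  df <- data.frame(chrom = rep(contig, nrow(calls)),
                   start = calls$start, end = calls$end,
                   name = paste0("del_", calls$zygosity),
                   score = round(calls$mean_norm, 4))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
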