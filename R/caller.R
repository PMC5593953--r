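# Insertion-site caller: turns chimeric-pair and split-read evidence into
# clustered breakpoint calls on the genome, and estimates transgene copy
# number from the vector/genome depth ratio.

#' Collect junction evidence from classified pairs
#'
#' One evidence item per `CHIMERIC_GENOME_VECTOR` pair (the genome mate's
#' junction-facing outer coordinate, an interval bound) and one per
#' `SPLIT_JUNCTION` read (the clip boundary, a base-pair-resolution
#' position). All other classes are ignored. `side` records which flank of
#' the insertion the genome segment lies on: `left` segments bound the
#' breakpoint from below, `right` segments from above.
#'
#' @param pairs Classification data frame from [classify_pairs()].
#' @param aln Alignment data frame the classification came from.
#' @param params A `mapper_params`.
#' @param vector_name Name of the vector contig.
#' @return Data frame of class `junction_evidence`: `kind`, `qname`,
#'   `genome_pos`, `side`, `orientation`, `vector_lo`, `vector_hi`.
#' @export
collect_evidence <- function(pairs, aln, params = mapper_params(),
                             vector_name = "vector") {
  ev <- list()
  aln$cls <- contig_class(aln$contig, vector_name)
  pri <- aln[aln$rank == 1L, , drop = FALSE]

  chim <- pairs$qname[pairs$class == "CHIMERIC_GENOME_VECTOR"]
  if (length(chim)) {
    sub <- pri[pri$qname %in% chim, , drop = FALSE]
    g <- sub[sub$cls == "genome", , drop = FALSE]
    v <- sub[sub$cls == "vector", , drop = FALSE]
    vi <- match(g$qname, v$qname)
    left <- g$strand == "+"          # junction lies beyond the aligned end
    ev[["chim"]] <- data.frame(
      kind = "chimeric_pair", qname = g$qname,
      genome_pos = ifelse(left, g$pos + g$alen, g$pos),
      side = ifelse(left, "left", "right"),
      orientation = ifelse(g$strand != v$strand[vi], "+", "-"),
      vector_lo = v$pos[vi], vector_hi = v$pos[vi] + v$alen[vi],
      stringsAsFactors = FALSE)
  }

  spl <- pairs[pairs$class == "SPLIT_JUNCTION", , drop = FALSE]
  if (nrow(spl)) {
    sec <- aln[aln$rank > 1L & aln$unique, , drop = FALSE]
    rows <- lapply(seq_len(nrow(spl)), function(i) {
      q <- spl$qname[i]; m <- spl$split_mate[i]
      p <- pri[pri$qname == q & pri$mate == m, , drop = FALSE]
      s <- sec[sec$qname == q & sec$mate == m, , drop = FALSE]
      if (nrow(p) != 1L || nrow(s) < 1L) return(NULL)
      s <- s[s$cls != p$cls, , drop = FALSE][1, , drop = FALSE]
      g <- if (p$cls == "genome") p else s
      v <- if (p$cls == "genome") s else p
      # the clipped side of the genome segment faces the junction
      left <- g$clip3 >= g$clip5
      data.frame(
        kind = "split_read", qname = q,
        genome_pos = if (left) g$pos + g$alen else g$pos,
        side = if (left) "left" else "right",
        orientation = if (g$strand == v$strand) "+" else "-",
        vector_lo = v$pos, vector_hi = v$pos + v$alen,
        stringsAsFactors = FALSE)
    })
    ev[["split"]] <- do.call(rbind, rows)
  }

  out <- do.call(rbind, ev)
  if (is.null(out)) {
    out <- data.frame(kind = character(0), qname = character(0),
                      genome_pos = integer(0), side = character(0),
                      orientation = character(0), vector_lo = integer(0),
                      vector_hi = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$genome_pos, out$qname), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("junction_evidence", class(out))
  out
}

#' Cluster junction evidence along the genome
#'
#' Single-linkage clustering after sorting by genome coordinate: an item
#' joins a cluster when it lies within `window` of the cluster's nearest
#' member. The result does not depend on input order.
#'
#' @param evidence A `junction_evidence` data frame.
#' @param window Linkage distance in bases (default twice the mean
#'   fragment length, the localization uncertainty of a chimeric pair).
#' @return `evidence` with an integer `cluster` column.
#' @export
cluster_evidence <- function(evidence, window = 1100) {
  evidence <- evidence[order(evidence$genome_pos, evidence$qname), ,
                       drop = FALSE]
  n <- nrow(evidence)
  if (n == 0L) {
    evidence$cluster <- integer(0)
    return(evidence)
  }
  gap <- c(FALSE, diff(evidence$genome_pos) > window)
  evidence$cluster <- cumsum(gap) + 1L
  rownames(evidence) <- NULL
  evidence
}

# most frequent value; ties broken toward the smallest
mode_int <- function(x) {
  t <- table(x)
  as.integer(names(t)[which.max(t)])
}

#' Call insertion sites from evidence clusters
#'
#' Clusters with at least `min_support` items become calls. With split
#' reads the breakpoint is resolved to base pair (`breakpoint_lo ==
#' breakpoint_hi`, the modal clip boundary); otherwise the call reports
#' the interval bounded by the innermost chimeric-pair coordinates of the
#' two junction sides (or the evidence span when only one side was seen).
#'
#' @param clustered Output of [cluster_evidence()].
#' @param min_support Minimum evidence items per call.
#' @return Data frame of class `insertion_calls`.
#' @export
call_insertions <- function(clustered, min_support = 3L) {
  cols <- data.frame(breakpoint_lo = integer(0), breakpoint_hi = integer(0),
                     n_split = integer(0), n_pairs = integer(0),
                     resolution = character(0), orientation = character(0),
                     vector_lo = integer(0), vector_hi = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(clustered) == 0L) {
    class(cols) <- c("insertion_calls", class(cols))
    return(cols)
  }
  for (cl in sort(unique(clustered$cluster))) {
    e <- clustered[clustered$cluster == cl, , drop = FALSE]
    n_split <- sum(e$kind == "split_read")
    n_pairs <- sum(e$kind == "chimeric_pair")
    if (n_split + n_pairs < min_support) next
    if (n_split > 0L) {
      s <- e[e$kind == "split_read", , drop = FALSE]
      bp <- mode_int(s$genome_pos)
      lo <- hi <- bp
      resolution <- "base_pair"
    } else {
      lower <- e$genome_pos[e$side == "left"]
      upper <- e$genome_pos[e$side == "right"]
      if (length(lower) && length(upper)) {
        lo <- max(lower); hi <- min(upper)
        if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
      } else {
        lo <- min(e$genome_pos); hi <- max(e$genome_pos)
      }
      resolution <- "interval"
    }
    cols <- rbind(cols, data.frame(
      breakpoint_lo = lo, breakpoint_hi = hi,
      n_split = n_split, n_pairs = n_pairs, resolution = resolution,
      orientation = names(which.max(table(e$orientation))),
      vector_lo = min(e$vector_lo), vector_hi = max(e$vector_hi),
      stringsAsFactors = FALSE))
  }
  rownames(cols) <- NULL
  class(cols) <- c("insertion_calls", class(cols))
  cols
}

#' Estimate transgene copies per diploid genome from relative depth
#'
#' `copies_per_diploid = 2 * mean vector depth / mean genome depth`, the
#' genome mean taken over unmasked windows only (deletions and insertion
#' flanks are masked upstream). A heterozygote carrying an n-copy
#' concatemer is expected near n, a homozygote near 2n; the short Ins1
#' fragment adds fractional coverage over its vector interval only.
#'
#' @param vector_profile `depth_profile` of the vector contig.
#' @param genome_profile `depth_profile` of the genome contig (masked).
#' @return List of class `copy_number_estimate`.
#' @export
estimate_transgene_copies <- function(vector_profile, genome_profile) {
  stopifnot(inherits(vector_profile, "depth_profile"),
            inherits(genome_profile, "depth_profile"))
  v_mean <- sum(vector_profile$raw * vector_profile$width) /
    sum(vector_profile$width)
  use <- !genome_profile$masked
  g_mean <- sum(genome_profile$raw[use] * genome_profile$width[use]) /
    sum(genome_profile$width[use])
  if (!is.finite(g_mean) || g_mean == 0) {
    stop_tgloc("genome mean depth is zero; copy number undefined")
  }
  structure(list(mean_vector_depth = v_mean, mean_genome_depth = g_mean,
                 copies_per_diploid = 2 * v_mean / g_mean),
            class = "copy_number_estimate")
}

#' Write insertion calls as VCF 4.2 breakend records
#'
#' One `SVTYPE=BND` record per call, with the mate locus on the vector
#' contig, support counts and resolution in INFO. POS is the 1-based last
#' genome base before the junction (left-breakpoint convention).
#'
#' @param calls An `insertion_calls` data frame.
#' @param contig Genome contig name.
#' @param path Output path.
#' @param vector_name Vector contig name.
#' @param params A `mapper_params` recorded in the header.
#' @export
write_insertions_vcf <- function(calls, contig, path,
                                 vector_name = "vector",
                                 params = mapper_params()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tgloc",
    sprintf("##tgloc_params=min_clip=%d,insert_mean=%g", params$min_clip,
            params$insert_mean),
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=NSPLIT,Number=1,Type=Integer,Description=\"Split reads\">",
    "##INFO=<ID=NPAIRS,Number=1,Type=Integer,Description=\"Chimeric pairs\">",
    "##INFO=<ID=RES,Number=1,Type=String,Description=\"Resolution\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Interval about POS\">",
    "##INFO=<ID=VSPAN,Number=2,Type=Integer,Description=\"Vector interval\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- character(0)
  for (i in seq_len(nrow(calls))) {
    pos1 <- calls$breakpoint_lo[i]      # 0-based junction = 1-based last base
    alt <- sprintf("N[%s:%d[", vector_name, calls$vector_lo[i] + 1L)
    info <- sprintf(
      "SVTYPE=BND;NSPLIT=%d;NPAIRS=%d;RES=%s;CIPOS=0,%d;VSPAN=%d,%d",
      calls$n_split[i], calls$n_pairs[i], calls$resolution[i],
      calls$breakpoint_hi[i] - calls$breakpoint_lo[i],
      calls$vector_lo[i], calls$vector_hi[i])
    rec <- c(rec, paste(contig, pos1, sprintf("bnd_%d", i), "N", alt, ".",
                        "PASS", info, sep = "\t"))
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write insertion calls as TSV
#' @param calls An `insertion_calls` data frame.
#' @param contig Genome contig name.
#' @param path Output path.
#' @export
write_insertions_tsv <- function(calls, contig, path) {
  df <- cbind(contig = rep(contig, nrow(calls)), as.data.frame(calls))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
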