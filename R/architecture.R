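# Synthetic reference architecture: a wild-type contig carrying three gene
# analogs, and a transgenic haplotype with a two-sub-site insertion (Ins1 =
# short vector fragment; Ins2 = multi-copy concatemer) plus three associated
# deletions, the largest of which removes the non-coding gene analog.

#' Transgene vector construct
#'
#' Builds the cloning-vector contig used both by the simulator (as the
#' inserted sequence) and by the mapper (as the extra `vector` contig of the
#' composite reference). The construct defaults to 7 kb; `ins1_fragment` is
#' the sub-interval of the vector that is inserted on its own at the Ins1
#' sub-site (517 b by default). Which construct region that short fragment
#' derives from is a free parameter.
#'
#' @param length Vector length in bases.
#' @param ins1_fragment Integer pair, 0-based half-open interval within the
#'   vector; defaults to a 517 b interval starting at 3000.
#' @param sequence Optional explicit DNA string; drawn uniformly at random
#'   (seeded) when `NULL`.
#' @param seed RNG seed used when `sequence` is `NULL`.
#' @param name Contig identifier, `"vector"` by convention.
#' @return An object of class `vector_construct`.
#' @export
vector_construct <- function(length = 7000L, ins1_fragment = NULL,
                             sequence = NULL, seed = 99L, name = "vector") {
  if (is.null(sequence)) {
    sequence <- withr::with_seed(seed, rand_dna(length))
  }
  length <- nchar(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop_tgloc("vector sequence must be over {A,C,G,T}")
  }
  if (is.null(ins1_fragment)) {
    start <- min(3000L, length - 517L)
    ins1_fragment <- c(start, start + 517L)
  }
  ins1_fragment <- as.integer(ins1_fragment)
  if (ins1_fragment[1] < 0L || ins1_fragment[2] > length ||
      diff(ins1_fragment) <= 0L) {
    stop_tgloc("ins1_fragment must be a non-empty interval within the vector")
  }
  structure(list(name = name, sequence = sequence,
                 length = length, ins1_fragment = ins1_fragment),
            class = "vector_construct")
}

# Unscaled genomic layout, anchored at the Ins1 insertion point (= 0).
# Distances follow the real locus: Ins1 sits `ins1_offset` upstream of the
# tfap2d analog, Ins2 `ins2_offset` downstream of the tfap2b analog, the
# largest deletion contains the ak analog. All coordinates are multiplied by
# `scale` and shifted by a centering margin before use.
design_layout <- function(contig_length, scale = 0.05,
                          ins1_offset = 100000, ins2_offset = 250000,
                          del_large_len = 100000, del_small_len = 20000,
                          min_margin = 1000) {
  tfap2d <- c(ins1_offset, ins1_offset + 60000)
  tfap2b <- c(ins1_offset + 100000, ins1_offset + 130000)
  ins2_point <- tfap2b[2] + ins2_offset
  u <- list(
    ins1_point = 0,
    del_small1 = c(0.6 * ins1_offset, 0.6 * ins1_offset + del_small_len),
    tfap2d = tfap2d,
    tfap2b = tfap2b,
    del_small2 = c(ins2_point - 40000, ins2_point - 20000),
    ins2_point = ins2_point,
    del_large = c(ins2_point + 20000, ins2_point + 20000 + del_large_len),
    ak = c(ins2_point + 50000, ins2_point + 80000)
  )
  span <- max(unlist(u))
  span_scaled <- round(span * scale)
  margin <- floor((contig_length - span_scaled) / 2)
  if (margin < min_margin) {
    stop_tgloc(sprintf(
      paste0("scaled layout span (%d b, covering the %d b unscaled gene/",
             "insertion layout at scale %g) does not fit contig_length %d ",
             "with a %d b margin"),
      span_scaled, round(span), scale, contig_length, min_margin))
  }
  sc <- function(x) as.integer(margin + round(x * scale))
  list(
    scale = scale, margin = margin, span_scaled = span_scaled,
    ins1_point = sc(u$ins1_point), ins2_point = sc(u$ins2_point),
    genes = data.frame(
      name = c("tfap2d_analog", "tfap2b_analog", "ak_analog"),
      start = c(sc(u$tfap2d[1]), sc(u$tfap2b[1]), sc(u$ak[1])),
      end = c(sc(u$tfap2d[2]), sc(u$tfap2b[2]), sc(u$ak[2])),
      strand = c("+", "+", "-"),
      stringsAsFactors = FALSE),
    deletions = data.frame(
      name = c("del_small1", "del_small2", "del_large"),
      start = c(sc(u$del_small1[1]), sc(u$del_small2[1]), sc(u$del_large[1])),
      end = c(sc(u$del_small1[2]), sc(u$del_small2[2]), sc(u$del_large[2])),
      stringsAsFactors = FALSE)
  )
}

#' Build the wild-type reference contig
#'
#' Draws a uniformly random (seeded) DNA contig and places three gene
#' analogs on it in the real locus order: `tfap2d_analog` upstream of
#' `tfap2b_analog`, with the non-coding `ak_analog` downstream inside the
#' span of the future largest deletion. All inter-feature distances are the
#' real ones multiplied by `scale`.
#'
#' @param contig_length Contig length in bases.
#' @param scale Positive factor applied to all real-genome distances.
#' @param seed RNG seed; the same seed and parameters give a byte-identical
#'   reference.
#' @param contig_name Name of the contig.
#' @param ... Further layout overrides passed to the internal layout
#'   designer (`ins1_offset`, `ins2_offset`, `del_large_len`,
#'   `del_small_len`), all in unscaled bases.
#' @return An object of class `reference_genome` with fields `contigs`
#'   (named character vector), `annotations` (gene data frame, 0-based
#'   half-open) and the resolved `layout`.
#' @export
build_wt_reference <- function(contig_length = 500000L, scale = 0.05,
                               seed = 1L, contig_name = "chrS", ...) {
  layout <- design_layout(contig_length, scale, ...)
  seq <- withr::with_seed(seed, rand_dna(contig_length))
  structure(list(
    contigs = setNames(seq, contig_name),
    contig_name = contig_name,
    contig_length = as.integer(contig_length),
    annotations = layout$genes,
    layout = layout,
    seed = seed
  ), class = "reference_genome")
}

#' Describe the transgene insertion architecture
#'
#' Collects the coordinates at which the transgenic haplotype differs from
#' the wild type: the Ins1 point (a single vector fragment), the Ins2 point
#' (a concatemer of `ins2_copies` full vector copies) and the associated
#' deletions. Positions come from the reference's scaled layout.
#'
#' @param ref A `reference_genome`.
#' @param ins2_copies Concatemer copies per haplotype (>= 1).
#' @param ins2_orientations Per-copy strand pattern, e.g. `"+++++"`;
#'   defaults to head-to-tail (all `+`).
#' @param deletions Optional data frame (`start`, `end`, 0-based half-open)
#'   overriding the layout's three default deletions.
#' @return An object of class `insertion_architecture`.
#' @export
insertion_architecture <- function(ref, ins2_copies = 5L,
                                   ins2_orientations = NULL,
                                   deletions = NULL) {
  stopifnot(inherits(ref, "reference_genome"))
  ins2_copies <- as.integer(ins2_copies)
  if (ins2_copies < 1L) stop_tgloc("ins2_copies must be >= 1")
  if (is.null(ins2_orientations)) {
    ins2_orientations <- strrep("+", ins2_copies)
  }
  ori <- strsplit(ins2_orientations, "")[[1]]
  if (length(ori) != ins2_copies || !all(ori %in% c("+", "-"))) {
    stop_tgloc("ins2_orientations must be a +/- string of length ins2_copies")
  }
  if (is.null(deletions)) deletions <- ref$layout$deletions
  structure(list(
    scale = ref$layout$scale,
    ins1_point = ref$layout$ins1_point,
    ins2_point = ref$layout$ins2_point,
    ins2_copies = ins2_copies,
    ins2_orientations = ori,
    deletions = deletions
  ), class = "insertion_architecture")
}

validate_architecture <- function(ref, arch) {
  del <- arch$deletions[order(arch$deletions$start), , drop = FALSE]
  L <- ref$contig_length
  if (any(del$start < 0L) || any(del$end > L) || any(del$end <= del$start)) {
    stop_tgloc("deletion intervals must be non-empty and within the contig")
  }
  if (nrow(del) > 1L && any(del$start[-1L] < del$end[-nrow(del)])) {
    stop_tgloc("deletion intervals must be pairwise disjoint")
  }
  for (p in c(arch$ins1_point, arch$ins2_point)) {
    if (any(p > del$start & p < del$end)) {
      stop_tgloc("insertion point falls inside a deletion interval")
    }
  }
  if (arch$ins1_point == arch$ins2_point) {
    stop_tgloc("Ins1 and Ins2 points must differ")
  }
  # the largest deletion must remove the ak analog entirely
  ak <- ref$annotations[ref$annotations$name == "ak_analog", , drop = FALSE]
  if (nrow(ak) == 1L && nrow(del) > 0L) {
    big <- del[which.max(del$end - del$start), ]
    if (!(big$start <= ak$start && big$end >= ak$end)) {
      stop_tgloc("largest deletion must contain the ak_analog gene")
    }
  }
  del
}

#' Apply an insertion architecture to the wild-type reference
#'
#' Excises each deletion, inserts the Ins1 vector fragment at the Ins1
#' point and a concatemer of full vector copies at the Ins2 point, and
#' returns the transgenic haplotype together with a machine-readable truth
#' set (junctions in wild-type coordinates, deletion intervals, copy number
#' and a wild-type/transgenic liftover map). Junction coordinates in the
#' truth set are extended across any junction microhomology to the maximal
#' genome match, the same boundary an ungapped aligner reports.
#'
#' @param ref A `reference_genome`.
#' @param vector A `vector_construct`.
#' @param arch An `insertion_architecture`.
#' @return A list with `haplotype` (DNA string) and `truth` (class
#'   `truth_set`).
#' @export
apply_architecture <- function(ref, vector, arch) {
  stopifnot(inherits(vector, "vector_construct"),
            inherits(arch, "insertion_architecture"))
  del <- validate_architecture(ref, arch)
  g <- unname(ref$contigs[[1]])
  f <- vector$ins1_fragment
  ins1_seq <- substring(vector$sequence, f[1] + 1L, f[2])
  copies <- vapply(arch$ins2_orientations, function(o) {
    if (o == "+") vector$sequence else revcomp(vector$sequence)
  }, character(1))
  ins2_seq <- paste(copies, collapse = "")

  # events in wild-type coordinates, sorted
  ev <- data.frame(type = "ins",
                   start = c(arch$ins1_point, arch$ins2_point),
                   end = c(arch$ins1_point, arch$ins2_point),
                   insert = c(ins1_seq, ins2_seq), stringsAsFactors = FALSE)
  if (nrow(del) > 0L) {
    ev <- rbind(data.frame(type = "del", start = del$start, end = del$end,
                           insert = rep("", nrow(del)),
                           stringsAsFactors = FALSE), ev)
  }
  ev <- ev[order(ev$start, ev$type), , drop = FALSE]

  pieces <- character(0)
  lift <- NULL   # kept wild-type segments and their transgenic offsets
  wt_cursor <- 0L
  tg_cursor <- 0L
  for (i in seq_len(nrow(ev))) {
    keep_len <- ev$start[i] - wt_cursor
    if (keep_len > 0L) {
      pieces <- c(pieces, substring(g, wt_cursor + 1L, ev$start[i]))
      lift <- rbind(lift, data.frame(
        wt_start = wt_cursor, wt_end = ev$start[i],
        tg_start = tg_cursor, tg_end = tg_cursor + keep_len))
      tg_cursor <- tg_cursor + keep_len
    }
    if (ev$type[i] == "del") {
      wt_cursor <- ev$end[i]
    } else {
      pieces <- c(pieces, ev$insert[i])
      tg_cursor <- tg_cursor + nchar(ev$insert[i])
      wt_cursor <- ev$start[i]
    }
  }
  if (wt_cursor < nchar(g)) {
    pieces <- c(pieces, substring(g, wt_cursor + 1L, nchar(g)))
    lift <- rbind(lift, data.frame(
      wt_start = wt_cursor, wt_end = nchar(g),
      tg_start = tg_cursor, tg_end = tg_cursor + (nchar(g) - wt_cursor)))
  }
  haplotype <- paste(pieces, collapse = "")

  junctions <- rbind(
    truth_junction(g, vector$sequence, "Ins1", "left", arch$ins1_point,
                   f[1], "+"),
    truth_junction(g, vector$sequence, "Ins1", "right", arch$ins1_point,
                   f[2], "+"),
    truth_junction(g, vector$sequence, "Ins2", "left", arch$ins2_point,
                   if (arch$ins2_orientations[1] == "+") 0L else vector$length,
                   arch$ins2_orientations[1]),
    truth_junction(g, vector$sequence, "Ins2", "right", arch$ins2_point,
                   if (arch$ins2_orientations[arch$ins2_copies] == "+")
                     vector$length else 0L,
                   arch$ins2_orientations[arch$ins2_copies]))

  truth <- structure(list(
    contig = ref$contig_name,
    junctions = junctions,
    deletions = del,
    ins2_copies = arch$ins2_copies,
    ins2_orientations = paste(arch$ins2_orientations, collapse = ""),
    ins1_fragment = f,
    vector_length = vector$length,
    scale = arch$scale,
    wt_length = nchar(g),
    tg_length = nchar(haplotype),
    liftover = lift
  ), class = "truth_set")

  list(haplotype = haplotype, truth = truth)
}

truth_junction <- function(genome_seq, vector_seq, site, side, p, v, ori) {
  raw_p <- p
  if (ori == "+") {
    can <- if (side == "left") {
      # genome | insert: aligner extends the genome match rightward
      extend_junction_right(genome_seq, vector_seq, p, v)
    } else {
      # insert | genome: aligner extends the genome match leftward
      extend_junction_left(genome_seq, vector_seq, p, v)
    }
    p <- can[["genome_pos"]]
    v <- can[["vector_pos"]]
  }
  data.frame(site = site, side = side, genome_pos = as.integer(p),
             raw_pos = as.integer(raw_p), vector_pos = as.integer(v),
             orientation = ori, stringsAsFactors = FALSE)
}

#' Lift coordinates between wild-type and transgenic haplotypes
#'
#' Positions inside deleted (wild-type to transgenic) or inserted
#' (transgenic to wild-type) segments map to `NA`. Outside modified
#' segments the two directions are inverse bijections.
#'
#' @param truth A `truth_set`.
#' @param pos Integer vector of 0-based positions.
#' @param from `"wt"` or `"tg"`.
#' @return Integer vector of lifted 0-based positions, `NA` where undefined.
#' @export
liftover <- function(truth, pos, from = c("wt", "tg")) {
  from <- match.arg(from)
  lift <- truth$liftover
  out <- rep(NA_integer_, length(pos))
  if (from == "wt") {
    s <- lift$wt_start; e <- lift$wt_end; o <- lift$tg_start
  } else {
    s <- lift$tg_start; e <- lift$tg_end; o <- lift$wt_start
  }
  for (i in seq_along(pos)) {
    j <- which(pos[i] >= s & pos[i] < e)
    if (length(j) == 1L) out[i] <- o[j] + (pos[i] - s[j])
  }
  out
}

#' Write reference/vector FASTA, gene GFF3 and truth-set files
#'
#' @param ref A `reference_genome`.
#' @param vector A `vector_construct` (appended as the `vector` contig of
#'   the composite reference).
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth_set`, written as JSON.
#' @return Invisibly, the paths written.
#' @export
write_reference_files <- function(ref, vector, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(wt = file.path(dir, "wt.fa"),
             composite = file.path(dir, "composite.fa"),
             gff = file.path(dir, "genes.gff3"))
  wt <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(wt, paths[["wt"]])
  comp <- Biostrings::DNAStringSet(c(ref$contigs,
                                     setNames(vector$sequence, vector$name)))
  Biostrings::writeXStringSet(comp, paths[["composite"]])
  gr <- GenomicRanges::GRanges(
    seqnames = ref$contig_name,
    ranges = IRanges::IRanges(start = ref$annotations$start + 1L,
                              end = ref$annotations$end),
    strand = ref$annotations$strand)
  gr$type <- "gene"
  gr$ID <- ref$annotations$name
  rtracklayer::export.gff3(gr, paths[["gff"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    write_truth_set(truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Write / read a truth set as JSON
#' @param truth A `truth_set`.
#' @param path File path.
#' @export
write_truth_set <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_set
#' @export
read_truth_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$junctions <- as.data.frame(x$junctions, stringsAsFactors = FALSE)
  x$deletions <- as.data.frame(x$deletions, stringsAsFactors = FALSE)
  x$liftover <- as.data.frame(x$liftover, stringsAsFactors = FALSE)
  x$ins1_fragment <- as.integer(x$ins1_fragment)
  structure(x, class = "truth_set")
}
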