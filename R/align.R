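# R surface of the minimal seed-and-extend mapper: index construction,
# single-read and batch alignment, mate-pair classification into evidence
# categories, and a minimal SAM dialect (header @SQ lines, 11 mandatory
# columns, NM/AS tags).

#' Mapper parameters
#'
#' @param k Seed length in bases (11..31).
#' @param seed_step Offset between successive seeds along the read; the
#'   final read-end seed is always included.
#' @param margin Uniqueness margin in score units: a placement is `unique`
#'   when no competing placement over the same part of the read scores
#'   within `margin` of it.
#' @param max_mismatch_rate Maximum mismatch fraction within the aligned
#'   segment.
#' @param min_seg Minimum aligned segment length reported.
#' @param max_hits_per_seed Seeds hitting more reference positions than
#'   this are skipped (repeat guard).
#' @param max_records Maximum placements reported per read (primary plus
#'   non-overlapping supplementary segments).
#' @param min_clip Minimum clipped length for split-read evidence.
#' @param insert_mean,insert_sd Expected fragment-length distribution;
#'   concordant insert bounds are `insert_mean +/- 4 * insert_sd`.
#' @return Object of class `mapper_params`.
#' @export
mapper_params <- function(k = 21L, seed_step = 10L, margin = 2L,
                          max_mismatch_rate = 0.08, min_seg = 20L,
                          max_hits_per_seed = 64L, max_records = 3L,
                          min_clip = 20L, insert_mean = 550, insert_sd = 60) {
  if (k < 11L || k > 31L) stop_tgloc("k must be in [11, 31]")
  structure(list(k = as.integer(k), seed_step = as.integer(seed_step),
                 margin = as.integer(margin),
                 max_mismatch_rate = max_mismatch_rate,
                 min_seg = as.integer(min_seg),
                 max_hits_per_seed = as.integer(max_hits_per_seed),
                 max_records = as.integer(max_records),
                 min_clip = as.integer(min_clip),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_bounds = c(insert_mean - 4 * insert_sd,
                                   insert_mean + 4 * insert_sd)),
            class = "mapper_params")
}

#' Build the composite reference (genome contigs plus vector contig)
#' @param ref A `reference_genome`.
#' @param vector A `vector_construct`.
#' @return Named character vector of contig sequences.
#' @export
composite_reference <- function(ref, vector) {
  c(ref$contigs, setNames(vector$sequence, vector$name))
}

#' Build a k-mer seed index over a reference
#'
#' Indexes every forward-strand k-mer of every contig (k-mers containing
#' non-ACGT are skipped); query strand is recovered at alignment time by
#' also aligning the reverse complement of the read.
#'
#' @param contigs Named character vector of contig sequences (e.g. from
#'   [composite_reference()]), or a `reference_genome`.
#' @param k Seed length (11..31).
#' @return Object of class `seed_index`.
#' @export
build_index <- function(contigs, k = 21L) {
  if (inherits(contigs, "reference_genome")) contigs <- contigs$contigs
  if (k < 11L || k > 31L) stop_tgloc("k must be in [11, 31]")
  if (length(contigs) == 0L || any(!nzchar(contigs))) {
    stop_tgloc("reference must be non-empty")
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop_tgloc("contigs must have unique names")
  }
  ptr <- .cpp_build_index(names(contigs), unname(contigs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 contig_names = names(contigs),
                 contig_lengths = setNames(nchar(contigs), names(contigs))),
            class = "seed_index")
}

#' Summary statistics of a seed index
#' @param index A `seed_index`.
#' @return List with `k`, per-contig lengths, total indexed positions and
#'   distinct k-mer count.
#' @export
index_info <- function(index) {
  .cpp_index_info(index$ptr)
}

#' Look up one k-mer in the index
#' @param index A `seed_index`.
#' @param kmer A DNA string of length `k`.
#' @return Data frame of (contig, 0-based position) hits.
#' @export
index_lookup <- function(index, kmer) {
  .cpp_index_lookup(index$ptr, kmer)
}

# shared batch-alignment core returning the standard alignment data frame
align_batch <- function(seqs, qnames, mate, index, params) {
  stopifnot(inherits(index, "seed_index"))
  df <- .cpp_align_batch(index$ptr, seqs,
                         params$seed_step, params$margin,
                         params$max_mismatch_rate, params$min_seg,
                         params$max_hits_per_seed, params$max_records)
  data.frame(
    qname = qnames[df$qid], mate = mate[df$qid],
    contig = index$contig_names[df$contig_id],
    pos = df$pos,
    strand = ifelse(df$strand > 0L, "+", "-"),
    clip5 = df$clip5, clip3 = df$clip3, alen = df$alen,
    read_length = nchar(seqs)[df$qid],
    nm = df$nm, score = df$score,
    unique = df$unique == 1L, rank = df$rank,
    stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Seeds are sampled along the read and each hit extended ungapped in both
#' directions; the best-scoring placements are returned, with clipped ends
#' where the read overhangs a junction. `clip5`/`clip3` are in reference
#' orientation; `clip5 + alen + clip3` equals the read length.
#'
#' @param sequence DNA string (length >= `k`).
#' @param index A `seed_index`.
#' @param params A `mapper_params`.
#' @return Alignment data frame (possibly empty) with one row per
#'   placement; `rank` 1 is the primary placement.
#' @export
align_read <- function(sequence, index, params = mapper_params()) {
  if (nchar(sequence) < index$k) stop_tgloc("read shorter than seed length")
  align_batch(sequence, "read", 1L, index, params)
}

#' Align mate pairs
#'
#' Both mates are aligned independently; mate identity is recorded in the
#' `mate` column. Input is either a `read_sim` object or explicit
#' `r1`/`r2`/`names` vectors (e.g. from [read_fastq()]).
#'
#' @param reads A `read_sim`, or a list with `r1`, `r2`, `names`.
#' @param index A `seed_index`.
#' @param params A `mapper_params`.
#' @return Alignment data frame for both mates.
#' @export
align_pairs <- function(reads, index, params = mapper_params()) {
  if (length(reads$r1) != length(reads$r2)) {
    stop_tgloc("mate files differ in read count")
  }
  if (length(reads$r1) == 0L) {
    return(align_batch(character(0), character(0), integer(0), index, params))
  }
  rbind(
    align_batch(reads$r1, reads$names, rep(1L, length(reads$r1)),
                index, params),
    align_batch(reads$r2, reads$names, rep(2L, length(reads$r2)),
                index, params))
}

# genome/vector contig class
contig_class <- function(contig, vector_name = "vector") {
  ifelse(contig == vector_name, "vector", "genome")
}

#' Classify mate pairs into evidence categories
#'
#' Each fragment receives exactly one class:
#' * `CHIMERIC_GENOME_VECTOR` -- one mate uniquely on the genome, the other
#'   uniquely on the vector contig;
#' * `SPLIT_JUNCTION` -- a mate whose primary placement carries a clipped
#'   segment of at least `min_clip` bases that re-aligns uniquely to the
#'   other contig class;
#' * `GENOME_CONCORDANT` -- both mates unique on the genome, opposite
#'   strands, implied insert within bounds;
#' * `VECTOR_INTERNAL` -- both mates placed on the vector contig;
#' * `DISCORDANT_GENOME` -- both genome-unique but not concordant;
#' * `UNMAPPED` -- anything else.
#' Classes are assigned in that precedence order.
#'
#' @param aln Alignment data frame from [align_pairs()].
#' @param params A `mapper_params`.
#' @param vector_name Name of the vector contig.
#' @return Data frame with one row per fragment: `qname`, `class`, and the
#'   index of the split mate (`NA` when none).
#' @export
classify_pairs <- function(aln, params = mapper_params(),
                           vector_name = "vector") {
  qnames <- unique(aln$qname)
  n <- length(qnames)
  if (n == 0L) {
    return(data.frame(qname = character(0), class = character(0),
                      split_mate = integer(0), stringsAsFactors = FALSE))
  }
  aln$cls <- contig_class(aln$contig, vector_name)
  pri <- aln[aln$rank == 1L, , drop = FALSE]
  key <- function(q, m) paste0(q, "/", m)
  pk <- key(pri$qname, pri$mate)

  get <- function(col, m, default) {
    i <- match(key(qnames, m), pk)
    out <- pri[[col]][i]
    out[is.na(i)] <- default
    out
  }
  u_g <- list(`1` = get("unique", 1L, FALSE) & get("cls", 1L, "") == "genome",
              `2` = get("unique", 2L, FALSE) & get("cls", 2L, "") == "genome")
  u_v <- list(`1` = get("unique", 1L, FALSE) & get("cls", 1L, "") == "vector",
              `2` = get("unique", 2L, FALSE) & get("cls", 2L, "") == "vector")
  on_v <- list(`1` = get("cls", 1L, "") == "vector",
               `2` = get("cls", 2L, "") == "vector")

  # split evidence: unique primary with a long clip, plus a unique
  # supplementary segment on the other contig class
  sec <- aln[aln$rank > 1L & aln$unique, , drop = FALSE]
  split_flag <- list(`1` = rep(FALSE, n), `2` = rep(FALSE, n))
  if (nrow(sec) > 0L) {
    sk <- key(sec$qname, sec$mate)
    j <- match(sk, pk)
    ok <- !is.na(j) & pri$unique[j] & sec$cls != pri$cls[j] &
      (pri$clip5[j] >= params$min_clip | pri$clip3[j] >= params$min_clip)
    for (m in c(1L, 2L)) {
      hit <- unique(sec$qname[ok & sec$mate == m])
      split_flag[[as.character(m)]][qnames %in% hit] <- TRUE
    }
  }

  # implied insert for concordance: outer span of the two primary segments
  p1 <- get("pos", 1L, NA_integer_); p2 <- get("pos", 2L, NA_integer_)
  e1 <- p1 + get("alen", 1L, 0L); e2 <- p2 + get("alen", 2L, 0L)
  s1 <- get("strand", 1L, ""); s2 <- get("strand", 2L, "")
  same_contig <- get("contig", 1L, "a") == get("contig", 2L, "b")
  ins_len <- pmax(e1, e2) - pmin(p1, p2)
  fr_ok <- ifelse(p1 <= p2, s1 == "+" & s2 == "-", s2 == "+" & s1 == "-")
  concordant <- u_g[["1"]] & u_g[["2"]] & same_contig & s1 != s2 & fr_ok &
    !is.na(ins_len) & ins_len >= params$insert_bounds[1] &
    ins_len <= params$insert_bounds[2]

  chimeric <- (u_g[["1"]] & u_v[["2"]]) | (u_v[["1"]] & u_g[["2"]])
  split <- split_flag[["1"]] | split_flag[["2"]]
  both_genome <- u_g[["1"]] & u_g[["2"]]
  both_vector <- on_v[["1"]] & on_v[["2"]]

  cls <- rep("UNMAPPED", n)
  cls[both_genome] <- "DISCORDANT_GENOME"
  cls[both_vector] <- "VECTOR_INTERNAL"
  cls[concordant] <- "GENOME_CONCORDANT"
  cls[split] <- "SPLIT_JUNCTION"
  cls[chimeric] <- "CHIMERIC_GENOME_VECTOR"

  split_mate <- ifelse(split_flag[["1"]], 1L,
                       ifelse(split_flag[["2"]], 2L, NA_integer_))
  data.frame(qname = qnames, class = cls, split_mate = split_mate,
             stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Minimal SAM dialect: `@HD`/`@SQ` header, the 11 mandatory columns, and
#' `NM`/`AS` tags. Uniqueness is encoded in MAPQ (60 unique, 0 otherwise);
#' supplementary segments carry flag 0x800. Positions are converted to the
#' SAM 1-based convention.
#'
#' @param aln Alignment data frame.
#' @param contig_lengths Named integer vector (e.g. `index$contig_lengths`).
#' @param path Output path.
#' @param reads Optional `read_sim`-like list supplying SEQ/QUAL.
#' @export
write_sam <- function(aln, contig_lengths, path, reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)),
           "@PG\tID:tgloc\tPN:tgloc")
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- 1L + ifelse(aln$mate == 1L, 64L, 128L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$rank > 1L, 2048L, 0L)
  cigar <- paste0(ifelse(aln$clip5 > 0L, paste0(aln$clip5, "S"), ""),
                  aln$alen, "M",
                  ifelse(aln$clip3 > 0L, paste0(aln$clip3, "S"), ""))
  seqs <- "*"; quals <- "*"
  if (!is.null(reads)) {
    i <- match(aln$qname, reads$names)
    seqs <- ifelse(aln$mate == 1L, reads$r1[i], reads$r2[i])
    quals <- ifelse(aln$mate == 1L, reads$qual1[i], reads$qual2[i])
    rc <- aln$strand == "-"
    seqs[rc] <- revcomp(seqs[rc])
    quals[rc] <- vapply(strsplit(quals[rc], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
  }
  rec <- paste(aln$qname, flag, aln$contig, aln$pos + 1L,
               ifelse(aln$unique, 60L, 0L), cigar, "*", 0L, 0L,
               seqs, quals,
               paste0("NM:i:", aln$nm), paste0("AS:i:", aln$score),
               paste0("XK:i:", aln$rank), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into the alignment data frame
#'
#' Inverse of [write_sam()] for the minimal dialect; also ingests external
#' SAM with clipped/matched CIGARs (M/=/X/S/H runs; gapped alignments are
#' rejected, a documented limitation of the ungapped model).
#'
#' @param path SAM file path.
#' @return Alignment data frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(qname = character(0), mate = integer(0),
                      contig = character(0), pos = integer(0),
                      strand = character(0), clip5 = integer(0),
                      clip3 = integer(0), alen = integer(0),
                      read_length = integer(0), nm = integer(0),
                      score = integer(0), unique = logical(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  if (length(f) == 0L) return(empty)
  cig <- vapply(f, `[[`, "", 6)
  m <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))
  clip5 <- integer(length(f)); clip3 <- integer(length(f))
  alen <- integer(length(f))
  for (i in seq_along(m)) {
    lens <- as.integer(sub("[MIDNSHP=X]$", "", m[[i]]))
    op <- sub("^\\d+", "", m[[i]])
    if (any(op %in% c("I", "D", "N", "P"))) {
      stop_tgloc("gapped CIGAR not supported by the ungapped model: ",
                 cig[i])
    }
    is_clip <- op %in% c("S", "H")
    j <- which(!is_clip)
    clip5[i] <- if (length(j) && j[1] > 1L) sum(lens[seq_len(j[1] - 1L)])
                else 0L
    clip3[i] <- if (length(j) && j[length(j)] < length(op))
      sum(lens[(j[length(j)] + 1L):length(op)]) else 0L
    alen[i] <- sum(lens[j])
  }
  tag <- function(prefix, default) {
    vapply(seq_along(f), function(i) {
      x <- f[[i]]
      hit <- x[startsWith(x, prefix)]
      if (length(hit)) as.integer(sub(prefix, "", hit[1])) else default
    }, integer(1))
  }
  data.frame(
    qname = vapply(f, `[[`, "", 1),
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    contig = vapply(f, `[[`, "", 3),
    pos = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    clip5 = clip5, clip3 = clip3, alen = alen,
    read_length = clip5 + alen + clip3,
    nm = tag("NM:i:", 0L),
    score = tag("AS:i:", NA_integer_),
    unique = vapply(f, function(x) as.integer(x[5]), integer(1)) >= 1L,
    rank = {
      r <- tag("XK:i:", NA_integer_)
      ifelse(is.na(r), ifelse(bitwAnd(flag, 2048L) > 0L, 2L, 1L), r)
    },
    stringsAsFactors = FALSE)
}
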