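# Paired-end read simulation from the wild-type / transgenic haplotype pair,
# with truth tags in the read names, and the het-cross breeding-colony
# simulator.

#' Read-simulation parameters
#'
#' Defaults mirror the sequencing library the pipeline is designed around:
#' paired-end 150 b reads from ~550 b fragments (sd 60 b), fragment lengths
#' truncated below at the read length.
#'
#' @param read_length Read length in bases.
#' @param insert_mean,insert_sd Fragment-length normal distribution (bases).
#' @param error_rate Per-base substitution probability in `[0, 0.5)`.
#' @param depth Target diploid (haplotype-pair) coverage.
#' @param seed RNG seed; identical seed and parameters give byte-identical
#'   output.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 150L, insert_mean = 550,
                            insert_sd = 60, error_rate = 0.002,
                            depth = 30, seed = 1L) {
  if (read_length > insert_mean) {
    stop_tgloc("read_length must not exceed insert_mean")
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    stop_tgloc("error_rate must be in [0, 0.5)")
  }
  if (depth <= 0) stop_tgloc("depth must be positive")
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, depth = depth,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a diploid individual
#'
#' Draws fragments with seeded RNG from the two haplotypes implied by
#' `genotype` (`WT` = two wild-type, `HET` = one of each drawn with
#' probability 1/2 per fragment, `HOM` = two transgenic), with lengths
#' Normal(`insert_mean`, `insert_sd`) truncated at the read length, applies
#' per-base substitution errors, and emits mate pairs in FR orientation
#' with Phred+33 qualities. Read names carry truth tags with the grammar
#' `name:hap:contig:start:end:strand` (0-based half-open fragment
#' coordinates on the source haplotype); downstream callers must never
#' parse them -- they exist for tests and truth comparison only.
#'
#' @param wt_seq Wild-type haplotype DNA string.
#' @param tg_seq Transgenic haplotype DNA string (may be `NULL` for `WT`).
#' @param genotype One of `"WT"`, `"HET"`, `"HOM"`.
#' @param params A `read_sim_params`.
#' @param wt_name,tg_name Contig names used in the truth tags.
#' @return An object of class `read_sim`: `names`, `r1`, `r2`, `qual1`,
#'   `qual2` and a `truth` data frame.
#' @export
simulate_reads <- function(wt_seq, tg_seq, genotype = c("WT", "HET", "HOM"),
                           params = read_sim_params(),
                           wt_name = "chrS", tg_name = "chrS_tg") {
  genotype <- match.arg(genotype)
  if (genotype != "WT" && (is.null(tg_seq) || !nzchar(tg_seq))) {
    stop_tgloc("genotype ", genotype, " requires a transgenic haplotype")
  }
  if (genotype != "HOM" && (is.null(wt_seq) || !nzchar(wt_seq))) {
    stop_tgloc("genotype ", genotype, " requires a wild-type haplotype")
  }
  rl <- params$read_length
  haps <- switch(genotype,
    WT = list(c(name = "wt"), c(name = "wt")),
    HET = list(c(name = "wt"), c(name = "tg")),
    HOM = list(c(name = "tg"), c(name = "tg")))
  seqs <- c(wt = if (genotype != "HOM") wt_seq else "",
            tg = if (genotype != "WT") tg_seq else "")
  lens <- nchar(seqs)
  hap_names <- vapply(haps, `[[`, "", "name")
  mean_len <- mean(lens[hap_names])
  n_frag <- as.integer(ceiling(params$depth * mean_len / (2 * rl)))

  # fragments are sampled from the two haplotype molecules in proportion
  # to their lengths (equal-length haplotypes reduce to probability 1/2
  # each), so per-base coverage is uniform across haplotypes even when an
  # insertion makes one haplotype longer
  p2 <- lens[hap_names[2]] / sum(lens[hap_names])
  withr::with_seed(params$seed, {
    hap <- hap_names[rbinom(n_frag, 1L, p2) + 1L]
    flen <- as.integer(round(rnorm(n_frag, params$insert_mean,
                                   params$insert_sd)))
    flen <- pmax(flen, rl)
    flen <- pmin(flen, lens[hap])
    start <- as.integer(floor(runif(n_frag) * (lens[hap] - flen + 1)))
    fstrand <- ifelse(runif(n_frag) < 0.5, "+", "-")

    frag_left <- substring(seqs[hap], start + 1L, start + rl)
    frag_right_rc <- revcomp(substring(seqs[hap], start + flen - rl + 1L,
                                       start + flen))
    r1 <- ifelse(fstrand == "+", frag_left, frag_right_rc)
    r2 <- ifelse(fstrand == "+", frag_right_rc, frag_left)

    if (params$error_rate > 0) {
      n_bases <- 2 * n_frag * rl
      n_err <- rbinom(1L, n_bases, params$error_rate)
      if (n_err > 0L) {
        at <- sample.int(n_bases, n_err)
        mate <- ifelse(at > n_frag * rl, 2L, 1L)
        within <- ifelse(mate == 2L, at - n_frag * rl, at) - 1L
        ri <- within %/% rl + 1L
        off <- within %% rl + 1L
        subst <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
        for (e in seq_len(n_err)) {
          v <- if (mate[e] == 1L) substr(r1[ri[e]], off[e], off[e])
               else substr(r2[ri[e]], off[e], off[e])
          new <- subst[e]
          if (new == v) new <- c(A = "C", C = "G", G = "T", T = "A")[[v]]
          if (mate[e] == 1L) substr(r1[ri[e]], off[e], off[e]) <- new
          else substr(r2[ri[e]], off[e], off[e]) <- new
        }
      }
    }

    contig <- ifelse(hap == "wt", wt_name, tg_name)
    nm <- sprintf("sim%07d:%s:%s:%d:%d:%s", seq_len(n_frag), hap, contig,
                  start, start + flen, fstrand)
    q <- if (params$error_rate > 0) {
      min(40L, as.integer(round(-10 * log10(params$error_rate))))
    } else 40L
    qual <- strrep(rawToChar(as.raw(q + 33L)), rl)
    structure(list(
      names = nm, r1 = unname(r1), r2 = unname(r2),
      qual1 = rep(qual, n_frag), qual2 = rep(qual, n_frag),
      genotype = genotype, params = params,
      truth = data.frame(name = nm, hap = unname(hap),
                         contig = unname(contig), start = unname(start),
                         end = unname(start + flen),
                         strand = unname(fstrand),
                         stringsAsFactors = FALSE)
    ), class = "read_sim")
  })
}

#' Parse truth tags from simulated read names
#' @param names Character vector of `name:hap:contig:start:end:strand` tags.
#' @return Data frame with the tag fields; coordinates 0-based half-open.
#' @export
parse_truth_tags <- function(names) {
  parts <- strsplit(names, ":", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stop_tgloc("malformed truth tag in read name")
  m <- do.call(rbind, parts)
  data.frame(name = names, hap = m[, 2], contig = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             strand = m[, 6], stringsAsFactors = FALSE)
}

#' Write / read paired FASTQ (Phred+33)
#' @param sim A `read_sim` object.
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @export
write_fastq <- function(sim, path1, path2) {
  enc <- function(names, seqs, quals) {
    as.vector(rbind(paste0("@", names), seqs, "+", quals))
  }
  writeLines(enc(sim$names, sim$r1, sim$qual1), path1)
  writeLines(enc(sim$names, sim$r2, sim$qual2), path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq
#' @param path A FASTQ file path.
#' @return `read_fastq`: list with `names`, `seqs`, `quals`.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4L != 0L) stop_tgloc("truncated FASTQ: ", path)
  i <- seq(1L, length(x), by = 4L)
  list(names = sub("^@", "", sub("\\s.*$", "", x[i])),
       seqs = x[i + 1L], quals = x[i + 3L])
}

#' Simulate an F2 breeding colony from a het x het cross
#'
#' Offspring genotypes are drawn Multinomial(1/4 WT, 1/2 HET, 1/4 HOM); the
#' glaucoma phenotype occurs with probability `penetrance` in homozygotes
#' only. Transgene-positive animals without glaucoma (heterozygotes plus
#' non-penetrant homozygotes) are pooled, as a presence/absence genotyping
#' assay cannot distinguish them.
#'
#' @param n_offspring Number of F2 animals.
#' @param penetrance Probability a homozygote is glaucomatous.
#' @param seed RNG seed.
#' @param label Table label.
#' @return A `transmission_table` with attribute `genotype_counts`.
#' @export
simulate_colony <- function(n_offspring, penetrance = 0.75, seed = 1L,
                            label = "simulated") {
  if (penetrance < 0 || penetrance > 1) {
    stop_tgloc("penetrance must be in [0, 1]")
  }
  if (n_offspring <= 0) stop_tgloc("n_offspring must be positive")
  withr::with_seed(seed, {
    g <- as.integer(rmultinom(1L, n_offspring, c(0.25, 0.5, 0.25)))
    n_glau <- rbinom(1L, g[3L], penetrance)
    tab <- transmission_table(
      n_neg = g[1L],
      n_pos_normal = g[2L] + g[3L] - n_glau,
      n_pos_glaucoma = n_glau,
      label = label)
    attr(tab, "genotype_counts") <- setNames(g, c("WT", "HET", "HOM"))
    tab
  })
}
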