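# Transmission-genetics statistics for breeding-colony count tables:
# Pearson chi-square goodness of fit against the two genetic hypotheses
# (simple Mendelian transmission of the transgene; glaucoma in all
# homozygotes), and the plug-in penetrance estimator.

#' Breeding-colony transmission table
#'
#' Counts of F2 animals by transgene presence and phenotype: transgene
#' negative (A), transgene positive without glaucoma (B), transgene
#' positive with glaucoma (C).
#'
#' @param n_neg,n_pos_normal,n_pos_glaucoma Non-negative counts.
#' @param label Table label.
#' @return An object of class `transmission_table`.
#' @export
transmission_table <- function(n_neg, n_pos_normal, n_pos_glaucoma,
                               label = "") {
  counts <- c(n_neg = n_neg, n_pos_normal = n_pos_normal,
              n_pos_glaucoma = n_pos_glaucoma)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_tgloc("transmission counts must be non-negative")
  }
  total <- sum(counts)
  if (total <= 0) stop_tgloc("transmission table must contain animals")
  structure(list(n_neg = as.integer(n_neg),
                 n_pos_normal = as.integer(n_pos_normal),
                 n_pos_glaucoma = as.integer(n_pos_glaucoma),
                 total = as.integer(total), label = label),
            class = "transmission_table")
}

#' @export
print.transmission_table <- function(x, ...) {
  cat(sprintf(
    "transmission_table '%s': A(neg)=%d B(pos,normal)=%d C(pos,glaucoma)=%d total=%d\n",
    x$label, x$n_neg, x$n_pos_normal, x$n_pos_glaucoma, x$total))
  invisible(x)
}

#' Goodness-of-fit hypothesis
#' @param proportions Expected category proportions (positive, sum 1).
#' @param label Hypothesis label.
#' @export
gof_hypothesis <- function(proportions, label = "") {
  if (any(proportions <= 0)) stop_tgloc("expected proportions must be > 0")
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop_tgloc("expected proportions must sum to 1")
  }
  structure(list(proportions = proportions, label = label),
            class = "gof_hypothesis")
}

#' Pearson chi-square goodness of fit
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with `E = total *
#' proportion`, `df = k - 1`, and upper-tail p-value from the chi-square
#' distribution (the regularized upper incomplete gamma function
#' `Q(df/2, chi2/2)`). No continuity correction is applied.
#'
#' @param observed Integer vector of category counts.
#' @param hypothesis A `gof_hypothesis` (or bare proportions vector).
#' @return An object of class `gof_result`: `chi2`, `df`, `p`, `p_rounded`
#'   (2 decimals), `observed`, `expected`.
#' @export
chisq_gof <- function(observed, hypothesis) {
  if (!inherits(hypothesis, "gof_hypothesis")) {
    hypothesis <- gof_hypothesis(hypothesis)
  }
  if (length(observed) < 2L) stop_tgloc("need at least 2 categories")
  if (length(observed) != length(hypothesis$proportions)) {
    stop_tgloc("observed categories do not match the hypothesis")
  }
  if (any(is.na(observed)) || any(observed < 0)) {
    stop_tgloc("observed counts must be non-negative")
  }
  expected <- sum(observed) * hypothesis$proportions
  if (any(expected == 0)) stop_tgloc("hypothesis gives a zero expected count")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p,
                 p_rounded = round(p, 2L),
                 observed = observed, expected = expected,
                 label = hypothesis$label),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square GoF%s: chi2 = %.4f, df = %d, p = %.4g (%.2f)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$chi2, x$df, x$p, x$p_rounded))
  invisible(x)
}

#' Test Mendelian transmission of the transgene
#'
#' Pools transgene-positive animals (B + C) and tests the observed
#' negative/positive split against the 25%/75% expectation of a het x het
#' cross.
#'
#' @param table A `transmission_table`.
#' @return A `gof_result`.
#' @export
test_mendelian_positive <- function(table) {
  stopifnot(inherits(table, "transmission_table"))
  chisq_gof(c(table$n_neg, table$n_pos_normal + table$n_pos_glaucoma),
            gof_hypothesis(c(0.25, 0.75),
                           "mendelian transmission, A : (B + C)"))
}

#' Test that all transgene homozygotes are glaucomatous
#'
#' Tests (A, B, C) against the 25%/50%/25% expectation that holds if the
#' glaucoma phenotype marks exactly the homozygotes.
#'
#' @param table A `transmission_table`.
#' @return A `gof_result`.
#' @export
test_homozygote_glaucoma <- function(table) {
  stopifnot(inherits(table, "transmission_table"))
  chisq_gof(c(table$n_neg, table$n_pos_normal, table$n_pos_glaucoma),
            gof_hypothesis(c(0.25, 0.5, 0.25),
                           "all homozygotes glaucomatous, A : B : C"))
}

#' Estimate glaucoma penetrance in transgene homozygotes
#'
#' Plug-in estimator: the observed glaucoma fraction divided by the 25%
#' homozygote expectation under 1:2:1 segregation, clamped to `[0, 1]`
#' with a flag when the raw ratio exceeds 1. A Wilson score interval on
#' the glaucoma fraction (scaled by 4) is attached as an auxiliary,
#' non-primary output.
#'
#' @param table A `transmission_table`.
#' @param conf_level Confidence level for the auxiliary Wilson interval.
#' @return List with `penetrance`, `raw`, `clamped`, `conf_int`.
#' @export
estimate_penetrance <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "transmission_table"))
  if (table$total <= 0) stop_tgloc("empty transmission table")
  frac <- table$n_pos_glaucoma / table$total
  raw <- frac / 0.25
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- table$total
  centre <- (frac + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(frac * (1 - frac) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(penetrance = min(raw, 1), raw = raw, clamped = raw > 1,
       conf_int = pmin(pmax(c(centre - half, centre + half) * 4, 0), 1))
}

#' Colony summary fractions
#'
#' Percent transgene-positive animals, percent glaucomatous animals and the
#' rounded penetrance estimate, as whole percentages.
#'
#' @param table A `transmission_table`.
#' @return List with `pct_positive`, `pct_glaucoma`, `pct_penetrance`.
#' @export
colony_summary <- function(table) {
  stopifnot(inherits(table, "transmission_table"))
  pos <- table$n_pos_normal + table$n_pos_glaucoma
  list(pct_positive = round(100 * pos / table$total),
       pct_glaucoma = round(100 * table$n_pos_glaucoma / table$total),
       pct_penetrance = round(100 * estimate_penetrance(table)$penetrance))
}

#' Read transmission tables from TSV
#'
#' Expected columns: `label`, `total`, `n_neg`, `n_pos_normal`,
#' `n_pos_glaucoma`. Published tables sometimes omit one count column;
#' exactly one missing count per row is reconstructed from the printed
#' total (an explicit, logged loader step).
#'
#' @param path TSV file path.
#' @param quiet Suppress reconstruction messages.
#' @return List of `transmission_table` objects, one per row.
#' @export
read_transmission_tsv <- function(path, quiet = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "total", "n_neg", "n_pos_normal", "n_pos_glaucoma")
  if (!all(need %in% names(df))) {
    stop_tgloc("transmission TSV must have columns: ",
               paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    counts <- c(df$n_neg[i], df$n_pos_normal[i], df$n_pos_glaucoma[i])
    miss <- which(is.na(counts))
    if (length(miss) > 1L) {
      stop_tgloc("row ", i, ": more than one missing count")
    }
    if (length(miss) == 1L) {
      counts[miss] <- df$total[i] - sum(counts[-miss])
      if (!quiet) {
        message(sprintf(
          "reconstructed %s = %d for '%s' from printed total %d",
          c("n_neg", "n_pos_normal", "n_pos_glaucoma")[miss], counts[miss],
          df$label[i], df$total[i]))
      }
    }
    if (sum(counts) != df$total[i]) {
      stop_tgloc("row ", i, ": counts do not sum to the printed total")
    }
    transmission_table(counts[1], counts[2], counts[3], label = df$label[i])
  })
}

#' Write transmission tables to TSV
#' @param tables List of `transmission_table` objects.
#' @param path Output path.
#' @export
write_transmission_tsv <- function(tables, path) {
  df <- do.call(rbind, lapply(tables, function(t) {
    data.frame(label = t$label, total = t$total, n_neg = t$n_neg,
               n_pos_normal = t$n_pos_normal,
               n_pos_glaucoma = t$n_pos_glaucoma)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full segregation report for one transmission table
#'
#' Runs both goodness-of-fit tests, the penetrance estimator and the
#' summary fractions.
#'
#' @param table A `transmission_table`.
#' @return List with `label`, `mendelian`, `homozygote_glaucoma`,
#'   `penetrance`, `summary`.
#' @export
segregation_report <- function(table) {
  list(label = table$label,
       mendelian = test_mendelian_positive(table),
       homozygote_glaucoma = test_homozygote_glaucoma(table),
       penetrance = estimate_penetrance(table),
       summary = colony_summary(table))
}
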