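# Recombination-frequency statistics for the extrachromosomal episome assay:
# recombined episomes confer chloramphenicol resistance, so the readout is
# CA (chloramphenicol + ampicillin) resistant colonies over total ampicillin
# resistant colonies, as a percentage.

#' Recombination frequency from colony counts
#'
#' `f = CA / A * 100` (percent), with an exact binomial (Clopper-Pearson)
#' 95% confidence interval. The exact interval is used because CA counts in
#' this assay are routinely tiny (0-5 colonies), where Wald intervals are
#' invalid.
#'
#' @param CA Chloramphenicol+ampicillin resistant colony count(s).
#' @param A Ampicillin resistant colony count(s); must be positive.
#' @param conf_level Confidence level, default 0.95.
#' @param condition Optional condition label(s).
#' @return `data.frame` with columns `condition`, `CA`, `A`, `frequency`
#'   (percent), `ci_low`, `ci_high` (percent).
#' @examples
#' recombination_frequency(CA = 504, A = 3937500)
#' @export
recombination_frequency <- function(CA, A, conf_level = 0.95,
                                    condition = NULL) {
  CA <- as.numeric(CA); A <- as.numeric(A)
  n <- max(length(CA), length(A))
  CA <- rep_len(CA, n); A <- rep_len(A, n)
  if (any(is.na(CA)) || any(CA < 0)) stop("CA counts must be >= 0", call. = FALSE)
  if (any(is.na(A)) || any(A <= 0)) {
    stop("frequency undefined: A must be > 0", call. = FALSE)
  }
  if (any(CA > A)) {
    warning("CA exceeds A for ", sum(CA > A), " record(s); frequency > 100%",
            call. = FALSE)
  }
  ci <- t(vapply(seq_len(n), function(i) {
    if (CA[i] > A[i]) return(c(NA_real_, NA_real_))
    stats::binom.test(round(CA[i]), round(A[i]),
                      conf.level = conf_level)$conf.int * 100
  }, numeric(2L)))
  data.frame(condition = if (is.null(condition)) rep(NA_character_, n)
             else rep_len(condition, n),
             CA = CA, A = A, frequency = CA / A * 100,
             ci_low = ci[, 1L], ci_high = ci[, 2L])
}

#' Fold change between two frequencies
#'
#' @param f_num,f_den Frequencies (percent, or any common unit).
#' @return `f_num / f_den`. A zero denominator (an assay with no
#'   recombinants) yields `Inf` with attribute `zero_denominator = TRUE` and
#'   a warning rather than an error.
#' @examples
#' fold_change(0.0128, 0.0032)
#' @export
fold_change <- function(f_num, f_den) {
  if (any(f_num < 0) || any(f_den < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  if (any(f_den == 0)) {
    warning("zero denominator frequency: fold change reported as Inf",
            call. = FALSE)
    out <- ifelse(f_den == 0, Inf, f_num / f_den)
    attr(out, "zero_denominator") <- TRUE
    return(out)
  }
  f_num / f_den
}

#' Significance stars for a p value
#'
#' The convention used throughout: `*` p < 0.05, `**` p < 0.005,
#' `***` p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric p value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 5e-3, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare replicate frequencies by Student's t test
#'
#' Unpaired two-sample Student's t (pooled variance) by default, matching the
#' assay's stated analysis; Welch's unequal-variance form is available via
#' `welch = TRUE`. Degenerate input with zero pooled variance and equal means
#' returns `t = 0`, `p = 1` by convention.
#'
#' @param group1,group2 Numeric replicate frequencies, each of length >= 2.
#' @param welch Use Welch's t instead of pooled variance.
#' @return List with `t`, `df`, `p_value`, `stars`.
#' @examples
#' compare_replicates(c(0.001, 0.002, 0.003), c(0.004, 0.005, 0.006))
#' @export
compare_replicates <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0 &&
      mean(group1) == mean(group2)) {
    return(list(t = 0, df = length(group1) + length(group2) - 2L,
                p_value = 1, stars = "ns"))
  }
  tt <- stats::t.test(group1, group2, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, stars = significance_stars(tt$p.value))
}

#' Summarise a colony-count table
#'
#' @param counts `data.frame` with columns `condition`, `replicate`, `CA`,
#'   `A` (the TSV layout written by the assay).
#' @param conf_level Confidence level for per-replicate intervals.
#' @return Per-replicate [recombination_frequency()] rows with the replicate
#'   index attached.
#' @export
frequency_table <- function(counts, conf_level = 0.95) {
  req <- c("condition", "replicate", "CA", "A")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- recombination_frequency(counts$CA, counts$A, conf_level,
                                 condition = counts$condition)
  out$replicate <- counts$replicate
  out[, c("condition", "replicate", "CA", "A", "frequency",
          "ci_low", "ci_high")]
}
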