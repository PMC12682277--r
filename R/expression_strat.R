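# Two-gene percentile stratification of a cohort expression matrix
# (FPKM/RPKM scale). Each gene's distribution is split at its 25th and 75th
# percentiles: Low < q25, Medium in [q25, q75], High > q75 (boundary ties go
# to Medium, per the strict inequalities defining Low and High). The two
# per-gene classes combine into one of nine subgroups.

#' 25th/75th percentile thresholds of an expression vector
#'
#' Quantiles use linear interpolation between order statistics (the common
#' type-7 convention); the stratification it feeds is invariant to any
#' strictly increasing transform of the values.
#'
#' @param values Numeric expression values (transformed scale), length >= 1.
#' @return Named numeric vector `c(q25 = ..., q75 = ...)`.
#' @examples
#' percentile_thresholds(0:4)
#' @export
percentile_thresholds <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values))) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  c(q25 = q[1L], q75 = q[2L])
}

classify_one <- function(values, thresholds) {
  ifelse(values < thresholds["q25"], "L",
         ifelse(values > thresholds["q75"], "H", "M"))
}

#' Stratify a cohort on two genes' expression
#'
#' Expression is analysed on the `log2(x + 1)` scale; supply `transformed =
#' FALSE` (the default) for raw FPKM/RPKM values and the transform is
#' applied, or `TRUE` if the matrix is already transformed. Per gene, each
#' sample is classed Low / Medium / High against that gene's own 25th/75th
#' percentiles, and the two classes combine into labels such as `"R1M/R2H"`.
#'
#' @param mat Numeric genes x samples matrix (rownames = genes, colnames =
#'   sample ids) of non-negative expression values.
#' @param genes Character vector of the two gene names to stratify on.
#' @param transformed Whether `mat` is already on the log2(x+1) scale.
#' @param prefixes Two short labels used in the combined label, default
#'   `c("R1", "R2")` for the first and second gene.
#' @return `data.frame` with columns `sample_id`, `gene1_class`,
#'   `gene2_class`, `label`, plus the per-gene thresholds as attribute
#'   `thresholds`.
#' @export
stratify_cohort <- function(mat, genes = c("RAG1", "RAG2"),
                            transformed = FALSE, prefixes = c("R1", "R2")) {
  stopifnot(length(genes) == 2L, length(prefixes) == 2L)
  if (is.null(rownames(mat))) stop("matrix must have gene rownames", call. = FALSE)
  absent <- setdiff(genes, rownames(mat))
  if (length(absent)) {
    stop("gene(s) absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("sample", seq_len(ncol(mat)))
  }
  if (anyDuplicated(colnames(mat))) stop("sample ids must be unique", call. = FALSE)
  x <- mat[genes, , drop = FALSE]
  if (!transformed) {
    if (any(x < 0)) stop("raw expression values must be non-negative", call. = FALSE)
    x <- log2(x + 1)
  }
  th1 <- percentile_thresholds(x[1L, ])
  th2 <- percentile_thresholds(x[2L, ])
  c1 <- classify_one(x[1L, ], th1)
  c2 <- classify_one(x[2L, ], th2)
  out <- data.frame(sample_id = colnames(mat),
                    gene1_class = unname(c1), gene2_class = unname(c2),
                    label = paste0(prefixes[1L], c1, "/", prefixes[2L], c2))
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(th1, th2)
  names(attr(out, "thresholds")) <- genes
  out
}

#' All nine combined stratum labels
#' @param prefixes Two short gene labels, default `c("R1", "R2")`.
#' @return Character vector of the nine labels in L/M/H order.
#' @export
stratum_levels <- function(prefixes = c("R1", "R2")) {
  cls <- c("L", "M", "H")
  as.vector(t(outer(cls, cls, function(a, b)
    paste0(prefixes[1L], a, "/", prefixes[2L], b))))
}

#' Counts per combined expression subgroup
#'
#' @param labels `data.frame` from [stratify_cohort()] (or a character
#'   vector of labels).
#' @param prefixes Passed to [stratum_levels()].
#' @return `data.frame` with columns `label`, `count` covering all nine
#'   subgroups (absent ones as 0); counts sum to the cohort size.
#' @export
group_counts <- function(labels, prefixes = c("R1", "R2")) {
  lab <- if (is.data.frame(labels)) labels$label else as.character(labels)
  lev <- stratum_levels(prefixes)
  bad <- setdiff(unique(lab), lev)
  if (length(bad)) {
    stop("invalid stratum label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(lab, levels = lev))
  data.frame(label = lev, count = as.integer(tab))
}

#' Read a genes x samples expression TSV
#'
#' First column holds gene names; the header row holds sample ids.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- genes
  m
}
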