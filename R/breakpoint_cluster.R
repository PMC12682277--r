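# Fragile-region detection: structural-variant breakpoints from a cohort are
# grouped per chromosome into clusters where adjacent breakpoints lie within
# max_gap (default 100 bp) of each other; clusters with enough members are
# candidate fragile regions, annotated with nearby cryptic RSS.

SV_TYPES <- c("deletion", "insertion", "inversion",
              "inter_translocation", "intra_translocation", "unknown")

#' Clustering parameters for fragile-region calling
#'
#' @param max_gap Maximum distance in nt between two breakpoints considered
#'   linked, default 100.
#' @param min_breakpoints Minimum members for a cluster to be retained,
#'   default 2.
#' @param flank Sequence context in nt to extract on each side when
#'   annotating, default 0.
#' @param mode `"gap"` (default): single-linkage chaining on the adjacent-pair
#'   gap. `"diameter"`: additionally split so the max pairwise distance within
#'   a cluster never exceeds `max_gap` (greedy left-to-right), for sensitivity
#'   analyses.
#' @return Object of class `cluster_params`.
#' @export
cluster_params <- function(max_gap = 100L, min_breakpoints = 2L, flank = 0L,
                           mode = c("gap", "diameter")) {
  mode <- match.arg(mode)
  max_gap <- as.integer(max_gap); min_breakpoints <- as.integer(min_breakpoints)
  flank <- as.integer(flank)
  if (any(is.na(c(max_gap, min_breakpoints, flank))) ||
      max_gap < 0L || min_breakpoints < 1L || flank < 0L) {
    stop("cluster parameters must be non-negative (min_breakpoints >= 1)",
         call. = FALSE)
  }
  structure(list(max_gap = max_gap, min_breakpoints = min_breakpoints,
                 flank = flank, mode = mode),
            class = "cluster_params")
}

#' Parse a breakpoint table
#'
#' Reads a tab-delimited table of structural-variant breakpoints in the style
#' of a COSMIC export (`sample_id`, `chrom`, `pos`, `sv_type`, optionally
#' `mate_chrom`, `mate_pos`), or a BEDPE file. Tabular `pos` is 1-based
#' inclusive (the printed-genomic-coordinate convention) and is stored
#' 0-based; BEDPE is 0-based half-open per its standard and each of the two
#' sides contributes one breakpoint record (mates are clustered independently
#' on their own chromosomes).
#'
#' @param path Path to the file (or a connection).
#' @param format `"tsv"` (default) or `"bedpe"`.
#' @return `data.frame` with columns `sample_id`, `chrom`, `pos0`,
#'   `mate_chrom`, `mate_pos0`, `sv_type`, rows in input order. Unknown
#'   `sv_type` values map to `"unknown"` with a warning.
#' @export
parse_breakpoint_table <- function(path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  if (format == "bedpe") return(parse_bedpe(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "chrom", "pos", "sv_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("breakpoint table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos0 = integer(), mate_chrom = character(),
                      mate_pos0 = integer(), sv_type = character()))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("non-integer or non-positive pos at data line(s) ",
         paste(bad, collapse = ", "), " (value(s): ",
         paste(df$pos[bad], collapse = ", "), ")", call. = FALSE)
  }
  sv <- df$sv_type
  unk <- !(sv %in% SV_TYPES)
  if (any(unk)) {
    warning("unknown sv_type value(s) mapped to 'unknown': ",
            paste(unique(sv[unk]), collapse = ", "), call. = FALSE)
    sv[unk] <- "unknown"
  }
  mate_chrom <- if ("mate_chrom" %in% names(df)) df$mate_chrom else rep(NA_character_, n)
  mate_pos0 <- if ("mate_pos" %in% names(df)) {
    suppressWarnings(as.integer(df$mate_pos)) - 1L
  } else rep(NA_integer_, n)
  data.frame(sample_id = df$sample_id, chrom = df$chrom, pos0 = pos - 1L,
             mate_chrom = mate_chrom, mate_pos0 = mate_pos0, sv_type = sv)
}

parse_bedpe <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L) stop("BEDPE requires at least 6 columns", call. = FALSE)
  name <- if (ncol(df) >= 7L) as.character(df[[7L]]) else
    paste0("bedpe", seq_len(nrow(df)))
  one <- function(chrom, start, mate_chrom, mate_start) {
    data.frame(sample_id = name, chrom = as.character(chrom),
               pos0 = as.integer(start),
               mate_chrom = as.character(mate_chrom),
               mate_pos0 = as.integer(mate_start),
               sv_type = "unknown")
  }
  out <- rbind(one(df[[1L]], df[[2L]], df[[4L]], df[[5L]]),
               one(df[[4L]], df[[5L]], df[[1L]], df[[2L]]))
  rownames(out) <- NULL
  out
}

#' Cluster breakpoints into fragile regions
#'
#' Per chromosome, breakpoints are sorted by position and chained by single
#' linkage: a new cluster starts whenever the gap to the previous breakpoint
#' exceeds `max_gap` (the "distance between 2 breakpoints <= 100 bp" rule at
#' the default). Clusters with fewer than `min_breakpoints` members are
#' dropped; every retained record belongs to exactly one cluster, and the
#' result is invariant to input record order.
#'
#' @param records Breakpoint `data.frame` from [parse_breakpoint_table()]
#'   (columns `chrom`, `pos0`; other columns carried through).
#' @param params [cluster_params()].
#' @return `data.frame` with one row per cluster: `cluster_id`, `chrom`,
#'   `start0`, `end0` (half-open), `n_breakpoints`, `span` (max - min
#'   position, nt), plus a `members` list-column of the member record rows
#'   (sorted by position).
#' @examples
#' rec <- data.frame(sample_id = "S1", chrom = "chr1",
#'                   pos0 = c(100, 150, 260), sv_type = "deletion")
#' cluster_breakpoints(rec, cluster_params(min_breakpoints = 1))
#' @export
cluster_breakpoints <- function(records, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.null(records) || nrow(records) == 0L) return(empty_clusters())
  stopifnot(all(c("chrom", "pos0") %in% names(records)))
  out <- list()
  for (chrom in sort(unique(records$chrom))) {
    sub <- records[records$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$pos0), , drop = FALSE]
    pos <- sub$pos0
    gap_break <- c(TRUE, diff(pos) > params$max_gap)
    grp <- cumsum(gap_break)
    if (params$mode == "diameter") {
      # greedy left-to-right split so max - min <= max_gap within each group
      new_grp <- integer(length(pos)); g <- 0L; anchor <- pos[1L]
      for (i in seq_along(pos)) {
        if (i == 1L || grp[i] != grp[i - 1L] ||
            pos[i] - anchor > params$max_gap) {
          g <- g + 1L; anchor <- pos[i]
        }
        new_grp[i] <- g
      }
      grp <- new_grp
    }
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      if (nrow(m) < params$min_breakpoints) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start0 = min(m$pos0), end0 = max(m$pos0) + 1L,
        n_breakpoints = nrow(m), span = max(m$pos0) - min(m$pos0))
      attr(out[[length(out)]], "members") <- m
    }
  }
  if (!length(out)) return(empty_clusters())
  members <- lapply(out, attr, "members")
  clusters <- do.call(rbind, out)
  clusters <- cbind(cluster_id = seq_len(nrow(clusters)), clusters)
  clusters$members <- members
  rownames(clusters) <- NULL
  clusters
}

empty_clusters <- function() {
  cl <- data.frame(cluster_id = integer(), chrom = character(),
                   start0 = integer(), end0 = integer(),
                   n_breakpoints = integer(), span = integer())
  cl$members <- list()
  cl
}

#' Annotate a cluster with nearby RSS hits
#'
#' Scans a sequence window covering the cluster for cryptic RSS and reports,
#' for each hit, the minimum unsigned distance between any member breakpoint
#' and the nearest base of the hit's heptamer footprint (0 when a breakpoint
#' falls inside the heptamer).
#'
#' @param cluster One row of the [cluster_breakpoints()] result (a
#'   `data.frame` with its `members` list-column), or a list with `chrom`,
#'   `start0`, `end0` and `members`.
#' @param window_sequence DNA sequence of the genomic window scanned.
#' @param window_start 0-based genomic offset of the window's first base.
#' @param consensus,params Passed to [scan_rss()].
#' @param ... Further arguments to [scan_rss()] (e.g. `model`).
#' @return The [scan_rss()] hit table in genomic top-strand coordinates with
#'   an extra `distance_to_breakpoint` column, sorted by that distance then
#'   `mismatch_score`.
#' @export
annotate_cluster_rss <- function(cluster, window_sequence, window_start,
                                 consensus = rss_consensus(),
                                 params = scan_params(), ...) {
  if (is.data.frame(cluster)) {
    stopifnot(nrow(cluster) == 1L)
    members <- cluster$members[[1L]]
    start0 <- cluster$start0; end0 <- cluster$end0
  } else {
    members <- cluster$members; start0 <- cluster$start0; end0 <- cluster$end0
  }
  window_sequence <- dna(window_sequence)
  window_start <- as.integer(window_start)
  win_end <- window_start + nchar(window_sequence)
  if (window_start > start0 || win_end < end0) {
    stop("window [", window_start, ", ", win_end,
         ") does not cover the cluster [", start0, ", ", end0, ")",
         call. = FALSE)
  }
  hits <- scan_rss(window_sequence, consensus, params, ...)
  if (nrow(hits) == 0L) {
    hits$distance_to_breakpoint <- integer()
    return(hits)
  }
  # heptamer footprint on the top strand, genomic coordinates (half-open)
  hept_lo <- window_start + hits$hept_start0_top
  hept_hi <- hept_lo + 7L
  bp <- members$pos0
  hits$distance_to_breakpoint <- vapply(seq_len(nrow(hits)), function(i) {
    d <- pmax(0L, pmax(hept_lo[i] - bp, bp - (hept_hi[i] - 1L)))
    as.integer(min(d))
  }, integer(1L))
  hits <- hits[order(hits$distance_to_breakpoint, hits$mismatch_score), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a clusters table as TSV (without the members list-column)
#'
#' @param clusters Result of [cluster_breakpoints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  utils::write.table(
    clusters[, c("cluster_id", "chrom", "start0", "end0",
                 "n_breakpoints", "span")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
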