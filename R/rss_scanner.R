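# 12/23-RSS detection. An RSS is a conserved heptamer (consensus CACAGTG)
# and nonamer (consensus ACAAAAACC) separated by a nonconserved spacer of
# 12 or 23 nt; RAGs nick immediately 5' of the heptamer. Cryptic RSS differ
# from the consensus at a few positions, so the scanner admits bounded
# mismatch counts, optionally requiring the CAC core exactly.

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER  <- "ACAAAAACC"

#' RSS consensus definition
#'
#' @param heptamer 7-mer consensus, default `CACAGTG`.
#' @param nonamer 9-mer consensus, default `ACAAAAACC`.
#' @param spacer_lengths Admissible spacer lengths in nt, default `c(12, 23)`
#'   (the 12RSS / 23RSS arrangements).
#' @return Object of class `rss_consensus`.
#' @export
rss_consensus <- function(heptamer = RSS_HEPTAMER, nonamer = RSS_NONAMER,
                          spacer_lengths = c(12L, 23L)) {
  heptamer <- dna(heptamer, "heptamer")
  nonamer <- dna(nonamer, "nonamer")
  if (nchar(heptamer) != 7L) stop("heptamer must be exactly 7 nt", call. = FALSE)
  if (nchar(nonamer) != 9L) stop("nonamer must be exactly 9 nt", call. = FALSE)
  spacer_lengths <- sort(unique(as.integer(spacer_lengths)))
  if (length(spacer_lengths) == 0L || any(spacer_lengths <= 0L)) {
    stop("spacer_lengths must be positive", call. = FALSE)
  }
  structure(list(heptamer = heptamer, nonamer = nonamer,
                 spacer_lengths = spacer_lengths),
            class = "rss_consensus")
}

#' Scan parameters for cryptic RSS detection
#'
#' Defaults take the loosest mismatch bounds described for the study's five
#' fragile regions (3 heptamer, 4 nonamer mismatches) and require the CAC
#' core of the heptamer exactly, reflecting its functional necessity for
#' RAG recognition.
#'
#' @param max_heptamer_mismatch Maximum heptamer mismatches (0..7), default 3.
#' @param max_nonamer_mismatch Maximum nonamer mismatches (0..9), default 4.
#' @param spacer_tolerance Admit spacers within +/- this many nt of an
#'   admissible spacer length, default 0.
#' @param anchor_cac If `TRUE` (default) the first three heptamer bases must
#'   match the consensus exactly; set `FALSE` for unanchored sensitivity
#'   analyses.
#' @param strands Which strands to scan: `"both"` (default), `"top"`, or
#'   `"bottom"`.
#' @return Object of class `scan_params`.
#' @export
scan_params <- function(max_heptamer_mismatch = 3L, max_nonamer_mismatch = 4L,
                        spacer_tolerance = 0L, anchor_cac = TRUE,
                        strands = c("both", "top", "bottom")) {
  strands <- match.arg(strands)
  m_h <- as.integer(max_heptamer_mismatch)
  m_n <- as.integer(max_nonamer_mismatch)
  tol <- as.integer(spacer_tolerance)
  if (is.na(m_h) || m_h < 0L || m_h > 7L) stop("max_heptamer_mismatch must be in 0..7", call. = FALSE)
  if (is.na(m_n) || m_n < 0L || m_n > 9L) stop("max_nonamer_mismatch must be in 0..9", call. = FALSE)
  if (is.na(tol) || tol < 0L) stop("spacer_tolerance must be >= 0", call. = FALSE)
  stopifnot(is.logical(anchor_cac), length(anchor_cac) == 1L)
  structure(list(max_heptamer_mismatch = m_h, max_nonamer_mismatch = m_n,
                 spacer_tolerance = tol, anchor_cac = anchor_cac,
                 strands = strands),
            class = "scan_params")
}

# admissible spacer lengths after tolerance expansion
admissible_spacers <- function(consensus, params) {
  sort(unique(unlist(lapply(consensus$spacer_lengths, function(s) {
    seq.int(max(1L, s - params$spacer_tolerance), s + params$spacer_tolerance)
  }))))
}

# distance of spacer s to the nearest nominal spacer length
spacer_deviation <- function(s, spacer_lengths) {
  min(abs(s - spacer_lengths))
}

# scan one strand's sequence string; returns hits in that strand's own
# 0-based coordinates
scan_one_strand <- function(chars, consensus, params) {
  L <- length(chars)
  hept <- strsplit(consensus$heptamer, "", fixed = TRUE)[[1L]]
  nona <- strsplit(consensus$nonamer, "", fixed = TRUE)[[1L]]
  spacers <- admissible_spacers(consensus, params)
  out <- vector("list", length(spacers))
  for (k in seq_along(spacers)) {
    s <- spacers[k]
    n_win <- L - (16L + s) + 1L
    if (n_win < 1L) next
    starts <- seq_len(n_win) - 1L                       # 0-based heptamer starts
    # mismatch counts via position-wise comparison over all windows at once
    hm <- integer(n_win); anchored <- rep(TRUE, n_win)
    for (j in 1:7) {
      neq <- chars[starts + j] != hept[j]
      hm <- hm + neq
      if (params$anchor_cac && j <= 3L) anchored <- anchored & !neq
    }
    nm <- integer(n_win)
    for (j in 1:9) nm <- nm + (chars[starts + 7L + s + j] != nona[j])
    keep <- anchored & hm <= params$max_heptamer_mismatch &
      nm <= params$max_nonamer_mismatch
    if (!any(keep)) next
    idx <- which(keep)
    out[[k]] <- data.frame(
      hept_start0 = starts[idx], spacer_len = s,
      nona_start0 = starts[idx] + 7L + s,
      hept_mm = hm[idx], nona_mm = nm[idx])
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

#' Scan a sequence for cryptic and canonical 12/23-RSS
#'
#' Enumerates every (heptamer position, spacer length, strand) arrangement
#' satisfying the scan parameters. Bottom-strand hits are found by scanning
#' the reverse complement; their rows carry both bottom-strand offsets
#' (`hept_start0`, on which the `nona_start0 = hept_start0 + 7 + spacer`
#' invariant holds) and the corresponding top-strand start of the heptamer
#' footprint (`hept_start0_top`). All qualifying hits are reported, including
#' overlapping arrangements (a region can qualify as both a cryptic 12RSS and
#' a cryptic 23RSS); downstream consumers filter by score.
#'
#' @param seq DNA sequence to scan.
#' @param consensus [rss_consensus()] definition.
#' @param params [scan_params()] thresholds.
#' @param seq_id Label carried into the hit table.
#' @param weights Mismatch-score weights passed to [mismatch_score()].
#' @param model Optional [rss_model()]; when supplied a `model_score` column
#'   is added.
#' @return A `data.frame` with one row per hit, columns `seq_id`, `strand`
#'   (`"top"`/`"bottom"`), `hept_start0`, `hept_seq`, `hept_mm`, `spacer_len`,
#'   `nona_start0`, `nona_seq`, `nona_mm`, `hept_start0_top`,
#'   `mismatch_score`, `nick_site0` and optionally `model_score`, sorted by
#'   (`mismatch_score`, `hept_start0_top`, strand top-before-bottom). A
#'   sequence shorter than the minimal RSS footprint yields zero rows.
#' @examples
#' akn1 <- fixture_oligo("AKN1")
#' scan_rss(akn1, params = scan_params(0, 0), seq_id = "AKN1")
#' @export
scan_rss <- function(seq, consensus = rss_consensus(), params = scan_params(),
                     seq_id = "seq", weights = c(2, 1, 1), model = NULL) {
  stopifnot(inherits(consensus, "rss_consensus"), inherits(params, "scan_params"))
  seq <- dna(seq)
  L <- nchar(seq)
  strands <- switch(params$strands, both = c("top", "bottom"),
                    top = "top", bottom = "bottom")
  rows <- list()
  for (st in strands) {
    s_seq <- if (st == "top") seq else revcomp(seq)
    chars <- strsplit(s_seq, "", fixed = TRUE)[[1L]]
    h <- scan_one_strand(chars, consensus, params)
    if (is.null(h) || nrow(h) == 0L) next
    h$seq_id <- seq_id
    h$strand <- st
    h$hept_seq <- substr(rep(s_seq, nrow(h)), h$hept_start0 + 1L, h$hept_start0 + 7L)
    h$nona_seq <- substr(rep(s_seq, nrow(h)), h$nona_start0 + 1L, h$nona_start0 + 9L)
    # top-strand start of the heptamer footprint
    h$hept_start0_top <- if (st == "top") h$hept_start0 else L - h$hept_start0 - 7L
    rows[[st]] <- h
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  rownames(hits) <- NULL
  if (nrow(hits)) {
    hits$mismatch_score <- mismatch_score(hits, weights = weights,
                                          spacer_lengths = consensus$spacer_lengths)
    hits$nick_site0 <- nick_site(hits)
    if (!is.null(model)) hits$model_score <- model_score(hits, seq, model)
    ord <- order(hits$mismatch_score, hits$hept_start0_top,
                 match(hits$strand, c("top", "bottom")))
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
  }
  cols <- c("seq_id", "strand", "hept_start0", "hept_seq", "hept_mm",
            "spacer_len", "nona_start0", "nona_seq", "nona_mm",
            "hept_start0_top", "mismatch_score", "nick_site0")
  if (!is.null(model)) cols <- c(cols, "model_score")
  hits[, cols, drop = FALSE]
}

empty_hits <- function() {
  data.frame(seq_id = character(), strand = character(),
             hept_start0 = integer(), hept_seq = character(),
             hept_mm = integer(), spacer_len = integer(),
             nona_start0 = integer(), nona_seq = character(),
             nona_mm = integer(), hept_start0_top = integer(),
             mismatch_score = numeric(), nick_site0 = integer(),
             model_score = numeric())
}

#' Weighted mismatch score of RSS hits
#'
#' `w_h * heptamer_mm + w_n * nonamer_mm + w_s * |spacer - nearest admissible
#' spacer|`; zero iff the hit is a perfect consensus at a nominal spacer.
#' Lower is better. A ranking heuristic, not a trained model.
#'
#' @param hits Hit table from [scan_rss()] (or any data.frame with
#'   `hept_mm`, `nona_mm`, `spacer_len`).
#' @param weights Numeric `c(w_h, w_n, w_s)`, all non-negative.
#' @param spacer_lengths Nominal spacer lengths, default `c(12, 23)`.
#' @return Numeric vector of scores.
#' @export
mismatch_score <- function(hits, weights = c(2, 1, 1),
                           spacer_lengths = c(12L, 23L)) {
  if (length(weights) != 3L || any(weights < 0) || any(is.na(weights))) {
    stop("weights must be three non-negative numbers", call. = FALSE)
  }
  dev <- vapply(hits$spacer_len, spacer_deviation, numeric(1L),
                spacer_lengths = spacer_lengths)
  weights[1L] * hits$hept_mm + weights[2L] * hits$nona_mm + weights[3L] * dev
}

#' Predicted RAG nick site of a hit
#'
#' RAGs nick immediately 5' of the heptamer, so the 0-based cut coordinate on
#' the hit's strand equals the heptamer start; for a top-strand hit it is also
#' the length of the labelled 5' fragment released by nicking.
#'
#' @param hits Hit table from [scan_rss()].
#' @return Integer vector of 0-based nick coordinates (one per hit), on each
#'   hit's own strand.
#' @export
nick_site <- function(hits) {
  as.integer(hits$hept_start0)
}

#' Position-frequency log-odds model for RSS quality
#'
#' A pluggable stand-in for externally trained recombination-information
#' models: per-position base frequencies for the heptamer and nonamer, a
#' background composition, and a linear penalty per nt of spacer deviation.
#' The defaults are artifact choices (not fitted to any published model):
#' frequency 0.91 on the consensus base at the three CAC heptamer positions
#' and the first nonamer position, 0.70 at all other positions, with the
#' remaining mass uniform over the other three bases; uniform background.
#'
#' @param heptamer_freq 7x4 matrix of per-position base frequencies
#'   (columns A,C,G,T), rows summing to 1.
#' @param nonamer_freq 9x4 matrix, same layout.
#' @param background Length-4 base frequencies, default uniform.
#' @param pseudocount Added to frequencies before taking logs; must be > 0.
#' @param spacer_penalty Score penalty per nt of deviation from the nearest
#'   admissible spacer length, default 1.
#' @return Object of class `rss_model`.
#' @export
rss_model <- function(heptamer_freq = NULL, nonamer_freq = NULL,
                      background = rep(0.25, 4), pseudocount = 1e-3,
                      spacer_penalty = 1) {
  if (is.null(heptamer_freq)) {
    heptamer_freq <- default_freq(RSS_HEPTAMER, strong = 1:3)
  }
  if (is.null(nonamer_freq)) {
    nonamer_freq <- default_freq(RSS_NONAMER, strong = 1L)
  }
  heptamer_freq <- check_freq(heptamer_freq, 7L, "heptamer_freq")
  nonamer_freq <- check_freq(nonamer_freq, 9L, "nonamer_freq")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 frequencies summing to 1", call. = FALSE)
  }
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  if (spacer_penalty < 0) stop("spacer_penalty must be >= 0", call. = FALSE)
  structure(list(heptamer_freq = heptamer_freq, nonamer_freq = nonamer_freq,
                 background = background, pseudocount = pseudocount,
                 spacer_penalty = spacer_penalty),
            class = "rss_model")
}

default_freq <- function(consensus, strong, p_strong = 0.91, p_weak = 0.70) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  n <- length(b)
  m <- matrix(0, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) {
    p <- if (i %in% strong) p_strong else p_weak
    m[i, ] <- (1 - p) / 3
    m[i, b[i]] <- p
  }
  m
}

check_freq <- function(m, n, what) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(n, 4L))) stop(what, " must be ", n, "x4", call. = FALSE)
  colnames(m) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop(what, " rows must each sum to 1", call. = FALSE)
  }
  m
}

#' A uniform (background-equal) model scoring every window 0
#' @return An [rss_model] whose position frequencies equal the background.
#' @export
uniform_rss_model <- function() {
  u <- matrix(0.25, 7L, 4L)
  rss_model(heptamer_freq = u, nonamer_freq = matrix(0.25, 9L, 4L),
            spacer_penalty = 0)
}

#' Log-odds model score of RSS hits
#'
#' Sum over the 7 heptamer and 9 nonamer positions of
#' `log((freq + pseudocount) / (background + pseudocount))`, minus
#' `spacer_penalty` per nt of spacer deviation from the nearest admissible
#' length. Higher is better; a model identical to the background scores every
#' window 0.
#'
#' @param hits Hit table from [scan_rss()].
#' @param seq The scanned sequence the hits refer to.
#' @param model [rss_model()].
#' @param spacer_lengths Nominal spacer lengths for the deviation penalty.
#' @return Numeric vector of scores, one per hit.
#' @export
model_score <- function(hits, seq, model = rss_model(),
                        spacer_lengths = c(12L, 23L)) {
  stopifnot(inherits(model, "rss_model"))
  seq <- dna(seq)
  lo <- function(freq, window) {
    b <- strsplit(window, "", fixed = TRUE)[[1L]]
    if ("N" %in% b) return(NA_real_)
    col <- match(b, colnames(freq))
    sum(log((freq[cbind(seq_along(b), col)] + model$pseudocount) /
              (model$background[b] + model$pseudocount)))
  }
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    lo(model$heptamer_freq, h$hept_seq) + lo(model$nonamer_freq, h$nona_seq) -
      model$spacer_penalty * spacer_deviation(h$spacer_len, spacer_lengths)
  }, numeric(1L))
}

#' Serialize / deserialize an RSS model as JSON
#'
#' @param model [rss_model()].
#' @param path Output (or input) JSON path.
#' @return `write_rss_model` returns `path` invisibly; `read_rss_model`
#'   returns the [rss_model].
#' @export
write_rss_model <- function(model, path) {
  stopifnot(inherits(model, "rss_model"))
  jsonlite::write_json(
    list(heptamer_freq = unname(model$heptamer_freq),
         nonamer_freq = unname(model$nonamer_freq),
         background = unname(model$background),
         pseudocount = model$pseudocount,
         spacer_penalty = model$spacer_penalty),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rss_model
#' @export
read_rss_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rss_model(heptamer_freq = x$heptamer_freq, nonamer_freq = x$nonamer_freq,
            background = x$background, pseudocount = x$pseudocount,
            spacer_penalty = x$spacer_penalty)
}
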