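# Recombinant-junction analysis. A sequenced junction is anchored so its
# first base aligns to position 0 of the left parent and its last base to
# the end of the right parent. The longest common prefix with the left
# parent (p) and longest common suffix with the right parent (q) determine
# the breakpoint: overlap (p + q > junction length) is microhomology — an
# ambiguous transition zone, the hallmark of MMEJ repair — while a shortfall
# is untemplated inserted sequence.

lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1L]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]][seq_len(n)]
  neq <- which(av != bv)
  if (length(neq)) neq[1L] - 1L else n
}

#' Map a recombinant junction onto its two parental sequences
#'
#' Computes `p` (longest common prefix of junction and left parent), `q`
#' (longest common suffix of junction and right parent), the microhomology
#' length `mu = max(0, p + q - junction_length)` and any inserted bases
#' (`junction_length - p - q` when positive). Exactly one of the three
#' outcomes holds: microhomology, insertion, or a blunt join. The breakpoint
#' is reported as an interval of length `mu` on each parent (the ambiguous
#' transition zone) together with a canonical leftmost point breakpoint.
#'
#' Matching is exact by default. With `tolerate_mismatches = TRUE`, isolated
#' single-base mismatches inside the matched prefix/suffix are skipped when
#' flanked by at least `flank` exact matches on both sides (accommodating
#' point mutations seen in sequenced recombinants); off by default for
#' determinism.
#'
#' Parents must be supplied in junction orientation: for inverted-orientation
#' rearrangements the caller passes the reverse complement.
#'
#' @param junction,left_parent,right_parent DNA sequences.
#' @param junction_id Label carried into the result.
#' @param tolerate_mismatches Allow isolated mismatches inside matches.
#' @param flank Exact-match run required on both sides of a tolerated
#'   mismatch.
#' @return Object of class `junction_call`: a one-row `data.frame` with
#'   columns `junction_id`, `p`, `q`, `mu`, `insert_seq`, `left_bp0`,
#'   `right_bp0`, `left_interval_start0`, `left_interval_end0`,
#'   `right_interval_start0`, `right_interval_end0`, `outcome`
#'   (`"microhomology"`, `"insertion"` or `"blunt"`).
#' @examples
#' map_junction("TTTACGTGGG", "TTTACGT", "ACGTGGG")
#' @export
map_junction <- function(junction, left_parent, right_parent,
                         junction_id = "junction",
                         tolerate_mismatches = FALSE, flank = 5L) {
  j <- dna(junction, "junction")
  l <- dna(left_parent, "left_parent")
  r <- dna(right_parent, "right_parent")
  nj <- nchar(j); nr <- nchar(r)
  p <- if (tolerate_mismatches) fuzzy_prefix(j, l, flank) else lcp_len(j, l)
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  q <- if (tolerate_mismatches) fuzzy_prefix(rev1(j), rev1(r), flank)
       else lcp_len(rev1(j), rev1(r))
  if (p == 0L && q == 0L) {
    stop("junction '", junction_id,
         "' shares no anchored prefix/suffix with either parent", call. = FALSE)
  }
  mu <- max(0L, p + q - nj)
  insert_seq <- if (p + q < nj) substr(j, p + 1L, nj - q) else ""
  outcome <- if (mu > 0L) "microhomology" else if (nzchar(insert_seq)) "insertion" else "blunt"
  # transition may lie anywhere in the mu-long ambiguous zone; canonical
  # point breakpoint is the leftmost transition
  left_int <- c(p - mu, p)            # 0-based half-open on left parent
  right_start <- nr - q               # first right-parent base used, leftmost
  right_int <- c(right_start, right_start + mu)
  structure(data.frame(
    junction_id = junction_id, p = p, q = q, mu = mu,
    insert_seq = insert_seq,
    left_bp0 = left_int[1L], right_bp0 = right_int[1L],
    left_interval_start0 = left_int[1L], left_interval_end0 = left_int[2L],
    right_interval_start0 = right_int[1L], right_interval_end0 = right_int[2L],
    outcome = outcome, stringsAsFactors = FALSE),
    class = c("junction_call", "data.frame"))
}

# longest prefix match allowing isolated single-base mismatches flanked by
# >= flank exact matches on both sides
fuzzy_prefix <- function(a, b, flank) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1L]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]][seq_len(n)]
  eq <- av == bv
  i <- 1L
  while (i <= n) {
    if (eq[i]) { i <- i + 1L; next }
    # exact runs immediately before and after the candidate mismatch
    before <- if (i == 1L) 0L else {
      r <- rle(rev(eq[seq_len(i - 1L)])); if (r$values[1L]) r$lengths[1L] else 0L
    }
    after <- if (i == n) 0L else {
      r <- rle(eq[seq.int(i + 1L, n)]); if (r$values[1L]) r$lengths[1L] else 0L
    }
    if (before >= flank && after >= flank) i <- i + 1L else break
  }
  i - 1L
}

#' Map many junctions against shared parents
#'
#' @param junctions Named character vector of junction sequences (e.g. from
#'   [read_fasta()]).
#' @param left_parent,right_parent Parental sequences.
#' @param ... Passed to [map_junction()].
#' @return `data.frame` of one [map_junction()] row per junction.
#' @export
map_junctions <- function(junctions, left_parent, right_parent, ...) {
  stopifnot(length(junctions) > 0L)
  ids <- names(junctions)
  if (is.null(ids)) ids <- paste0("junction", seq_along(junctions))
  out <- do.call(rbind, lapply(seq_along(junctions), function(i) {
    map_junction(junctions[[i]], left_parent, right_parent,
                 junction_id = ids[i], ...)
  }))
  rownames(out) <- NULL
  out
}

#' Breakpoint offset relative to a heptamer
#'
#' Signed distance from an RSS heptamer to the junction transition on the
#' same parent: `breakpoint interval start - heptamer start`. Zero means the
#' junction transitions exactly at the heptamer's 5' edge (canonical RAG
#' geometry: nick 5' of the heptamer); negative values lie 5' of the
#' heptamer.
#'
#' @param calls Result rows of [map_junction()]/[map_junctions()].
#' @param hit One row of a [scan_rss()] hit table on the corresponding
#'   parent.
#' @param side Which parent the hit lies on: `"left"` or `"right"`.
#' @param parent_id Optional id of the parent the caller scanned; when the
#'   hit's `seq_id` is present and differs, a reference error is raised.
#' @return Integer vector of signed offsets, one per call.
#' @export
breakpoint_offset_from_heptamer <- function(calls, hit, side = c("left", "right"),
                                            parent_id = NULL) {
  side <- match.arg(side)
  stopifnot(nrow(hit) == 1L)
  if (!is.null(parent_id) && !is.null(hit$seq_id) && hit$seq_id != parent_id) {
    stop("hit is on sequence '", hit$seq_id, "', not on parent '",
         parent_id, "'", call. = FALSE)
  }
  bp <- if (side == "left") calls$left_interval_start0 else calls$right_interval_start0
  as.integer(bp - hit$hept_start0_top)
}

#' Histogram of breakpoint offsets
#'
#' @param offsets Integer offsets (e.g. from
#'   [breakpoint_offset_from_heptamer()]).
#' @return `data.frame` with columns `offset`, `count`, sorted by offset;
#'   counts sum to `length(offsets)`.
#' @export
junction_histogram <- function(offsets) {
  if (length(offsets) == 0L) {
    return(data.frame(offset = integer(), count = integer()))
  }
  tab <- table(as.integer(offsets))
  data.frame(offset = as.integer(names(tab)), count = as.integer(tab))
}
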