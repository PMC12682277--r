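# Coordinate convention used throughout the package: 0-based, half-open.
# A feature starting at 0-based offset k has k bases 5' of it, so the offset
# doubles as the "nt away from the 5' end" count used in substrate design.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and normalise a DNA sequence
#'
#' Uppercases the input and checks that every base is one of A, C, G, T, N.
#' IUPAC ambiguity codes other than N are rejected rather than expanded:
#' the oligonucleotide substrates this package works with are unambiguous.
#'
#' @param bases Character scalar (or an object coercible via
#'   `as.character()`, e.g. a `Biostrings::DNAString`).
#' @param what Label used in error messages.
#' @return The validated uppercase sequence as a character scalar.
#' @examples
#' dna("acgtn")
#' @export
dna <- function(bases, what = "sequence") {
  bases <- toupper(as.character(bases))
  if (length(bases) != 1L || is.na(bases) || !nzchar(bases)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(bases, "", fixed = TRUE)[[1L]]), DNA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-ACGTN characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bases
}

#' Reverse complement
#'
#' Complement mapping A<->T, C<->G, N<->N with the base order reversed.
#' `revcomp()` is an involution: applying it twice returns the input.
#'
#' @param seq DNA sequence (character scalar over A/C/G/T/N; lowercase
#'   accepted and uppercased).
#' @return Character scalar of the same length.
#' @examples
#' revcomp("CACAGTG")
#' @export
revcomp <- function(seq) {
  seq <- dna(seq)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Hamming distance between equal-length sequences
#'
#' Number of mismatched positions; the mismatch-count unit in which cryptic
#' RSS quality is described (e.g. a "3 nt mismatch heptamer").
#'
#' @param a,b DNA sequences of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming("CACAGCA", "CACAGTG")
#' @export
hamming <- function(a, b) {
  a <- dna(a, "a"); b <- dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop("hamming requires equal-length sequences (", nchar(a), " vs ",
         nchar(b), ")", call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; record descriptions
#' are truncated to the first whitespace-delimited word so ids match the
#' oligo names.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped lines.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  seqs <- vapply(seqs, dna, character(1L))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Annealed duplex substrate
#'
#' Pairs a top and bottom oligonucleotide strand and records the overhangs
#' left after annealing. Overhangs are computed, not asserted: the maximal
#' exact reverse-complement overlap between the strands is located, and
#' whatever falls outside it on either end of either strand is an overhang.
#' After trimming all recorded overhangs the bottom strand is the exact
#' reverse complement of the top strand.
#'
#' @param top,bottom Strand sequences (character scalars).
#' @param top_id,bottom_id Optional labels.
#' @param min_overlap Minimum duplex overlap accepted as an annealed pair.
#' @return Object of class `duplex_substrate`: a list with `top`, `bottom`,
#'   their ids, the four overhang lengths (`five_prime_overhang_top`,
#'   `three_prime_overhang_top`, and bottom-strand counterparts) and the
#'   duplex `overlap` length.
#' @examples
#' d <- duplex_substrate("TCGACAAATTT", "TCGAAAATTTG")
#' d$five_prime_overhang_top
#' @export
duplex_substrate <- function(top, bottom, top_id = "top", bottom_id = "bottom",
                             min_overlap = 10L) {
  top <- dna(top, top_id); bottom <- dna(bottom, bottom_id)
  ov <- find_duplex_overhangs(top, bottom, min_overlap)
  if (is.null(ov)) {
    stop("strands ", top_id, "/", bottom_id,
         " share no exact reverse-complement overlap of >= ", min_overlap,
         " nt; not an annealed duplex", call. = FALSE)
  }
  structure(c(list(top = top, bottom = bottom,
                   top_id = top_id, bottom_id = bottom_id), ov),
            class = "duplex_substrate")
}

# Locate the maximal exact reverse-complement overlap between top and bottom.
# Returns overhang lengths on both ends of both strands, or NULL if no
# placement reaches min_overlap.
find_duplex_overhangs <- function(top, bottom, min_overlap = 10L) {
  rb <- revcomp(bottom)
  nt <- nchar(top); nb <- nchar(rb)
  best <- NULL
  for (shift in seq.int(-nb + 1L, nt - 1L)) {
    s <- max(0L, shift); e <- min(nt, shift + nb)  # overlap on top, 0-based
    if (e - s < min_overlap) next
    if (substr(top, s + 1L, e) == substr(rb, s - shift + 1L, e - shift)) {
      cand <- list(overlap = e - s,
                   five_prime_overhang_top = s,
                   three_prime_overhang_top = nt - e,
                   five_prime_overhang_bottom = nb - (e - shift),
                   three_prime_overhang_bottom = s - shift)
      if (is.null(best) || cand$overlap > best$overlap) best <- cand
    }
  }
  best
}

#' @export
print.duplex_substrate <- function(x, ...) {
  cat(sprintf("Duplex %s/%s: %d nt overlap; 5' overhangs %d/%d, 3' overhangs %d/%d\n",
              x$top_id, x$bottom_id, x$overlap,
              x$five_prime_overhang_top, x$five_prime_overhang_bottom,
              x$three_prime_overhang_top, x$three_prime_overhang_bottom))
  invisible(x)
}

# Strand pairing of the shipped substrate oligos (top, bottom).
FIXTURE_PAIRS <- list(
  `AKN1/AKN2`   = c("AKN1", "AKN2"),
  `AP92/AP93`   = c("AP92", "AP93"),
  `AP94/AP95`   = c("AP94", "AP95"),
  `AP96/AP97`   = c("AP96", "AP97"),
  `AP98/AP99`   = c("AP98", "AP99"),
  `AP100/AP101` = c("AP100", "AP101"),
  `DG13/DG14`   = c("DG13", "DG14"),
  `DG27/DG28`   = c("DG27", "DG28"),
  `MS20/MS21`   = c("MS20", "MS21")
)

#' Path to the shipped oligonucleotide FASTA
#' @return File path of `extdata/oligos.fasta`.
#' @export
oligos_fasta_path <- function() {
  system.file("extdata", "oligos.fasta", package = "fragilerss",
              mustWork = TRUE)
}

#' Load the study's oligonucleotide substrates
#'
#' Returns the annealed duplex substrates used in the RAG binding/cleavage
#' assays: the canonical 12RSS control AKN1/AKN2, the five fragile-region
#' substrates (AP92/93 CAMK2D, AP94/95 RNF38-MELK, AP96/97 AMY1B, AP98/99
#' DIPK1A, AP100/101 RN7SKP123-MTF2), the RSS-free controls DG13/14 and
#' DG27/28, and the pull-down control MS20/21. Overhangs are computed from
#' the sequences at load time.
#'
#' @param name Optional single pair name such as `"AKN1/AKN2"`; by default
#'   all pairs are returned.
#' @return A named list of [duplex_substrate] objects (or a single one when
#'   `name` is given).
#' @examples
#' subs <- load_fixture_oligos()
#' subs[["AKN1/AKN2"]]
#' @export
load_fixture_oligos <- function(name = NULL) {
  seqs <- read_fasta(oligos_fasta_path())
  build <- function(pr) {
    duplex_substrate(seqs[[pr[1L]]], seqs[[pr[2L]]],
                     top_id = pr[1L], bottom_id = pr[2L])
  }
  if (!is.null(name)) {
    if (!name %in% names(FIXTURE_PAIRS)) {
      stop("unknown substrate pair '", name, "'; available: ",
           paste(names(FIXTURE_PAIRS), collapse = ", "), call. = FALSE)
    }
    return(build(FIXTURE_PAIRS[[name]]))
  }
  lapply(FIXTURE_PAIRS, build)
}

#' Fetch one shipped oligo sequence by name
#'
#' @param name Oligo id as printed in the FASTA (e.g. `"AKN1"`, `"AP96"`).
#' @return Character scalar sequence.
#' @export
fixture_oligo <- function(name) {
  seqs <- read_fasta(oligos_fasta_path())
  if (!name %in% names(seqs)) {
    stop("unknown oligo '", name, "'; available: ",
         paste(names(seqs), collapse = ", "), call. = FALSE)
  }
  seqs[[name]]
}
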