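# Independent oracles, deliberately naive: written as direct transcriptions
# of the definitions so they share no code path with the package internals.

# reverse complement by explicit lookup
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# triple-loop RSS scan: every (strand, spacer, heptamer position)
oracle_scan <- function(seq, m_h = 3, m_n = 4, spacers = c(12, 23),
                        tol = 0, anchor = TRUE, strands = c("top", "bottom"),
                        heptamer = "CACAGTG", nonamer = "ACAAAAACC") {
  sp_all <- unique(unlist(lapply(spacers, function(s)
    max(1, s - tol):(s + tol))))
  rows <- list()
  for (st in strands) {
    s_seq <- if (st == "top") seq else oracle_revcomp(seq)
    L <- nchar(s_seq)
    for (sp in sp_all) {
      if (L < 16 + sp) next
      for (i in 0:(L - 16 - sp)) {
        hs <- substr(s_seq, i + 1, i + 7)
        ns <- substr(s_seq, i + 8 + sp, i + 16 + sp)
        if (anchor && substr(hs, 1, 3) != substr(heptamer, 1, 3)) next
        mh <- hamming(hs, heptamer); mn <- hamming(ns, nonamer)
        if (mh <= m_h && mn <= m_n) {
          rows[[length(rows) + 1]] <- data.frame(
            strand = st, hept_start0 = i, spacer_len = sp,
            hept_mm = mh, nona_mm = mn)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(strand = character(), hept_start0 = integer(),
               spacer_len = integer(), hept_mm = integer(),
               nona_mm = integer())
}

# canonical sorted key for comparing hit sets
hit_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$strand, df$hept_start0, df$spacer_len, df$hept_mm, df$nona_mm))
}

# exhaustive junction decomposition: try every transition point and insert
# span, keep the decomposition with maximal matched prefix + suffix
oracle_junction <- function(j, l, r) {
  nj <- nchar(j); nl <- nchar(l); nr <- nchar(r)
  best <- NULL
  for (p in 0:min(nj, nl)) {
    if (p > 0 && substr(j, 1, p) != substr(l, 1, p)) next
    for (q in 0:min(nj - p, nr)) {
      if (q > 0 && substr(j, nj - q + 1, nj) != substr(r, nr - q + 1, nr)) next
      cand <- list(p = p, q = q, insert = substr(j, p + 1, nj - q))
      if (is.null(best) || p + q > best$p + best$q) best <- cand
    }
  }
  # maximal p and q independently (the mapper's definition)
  pmax_ <- 0
  for (p in 0:min(nj, nl)) if (substr(j, 1, p) == substr(l, 1, p)) pmax_ <- p
  qmax_ <- 0
  for (q in 0:min(nj, nr)) {
    if (substr(j, nj - q + 1, nj) == substr(r, nr - q + 1, nr)) qmax_ <- q
  }
  list(p = pmax_, q = qmax_, mu = max(0, pmax_ + qmax_ - nj),
       insert = if (pmax_ + qmax_ < nj) substr(j, pmax_ + 1, nj - qmax_) else "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
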