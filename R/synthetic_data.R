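# Seeded generators emulating the statistical structure of each pipeline
# input (cryptic-RSS-bearing substrates, clustered cohort breakpoints,
# sequenced recombinant junctions, colony-count assays, a two-gene cohort
# expression matrix), so every stage is testable with no external download.
# Every generator is a pure function of its parameters and an explicit
# integer seed: randomness runs under withr::with_seed, leaving no global
# RNG state behind, and identical calls are byte-identical.

BASES <- c("A", "C", "G", "T")

random_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# mutate exactly m positions of word (character vector), choosing positions
# uniformly from `allowed`, each to a uniformly chosen different base
mutate_positions <- function(word, m, allowed) {
  if (m == 0L) return(word)
  pos <- if (length(allowed) == 1L) allowed else sample(allowed, m)
  for (i in pos) word[i] <- sample(setdiff(BASES, word[i]), 1L)
  word
}

#' Generate a substrate sequence with a planted cryptic RSS
#'
#' Background bases are i.i.d. with the stated GC content; a heptamer with
#' exactly `m_h` mismatches from consensus and a nonamer with exactly `m_n`
#' mismatches are planted at `heptamer_offset` with the requested spacer,
#' mirroring the design of the assay substrates (cryptic heptamer a fixed
#' distance from the 5' end). When `anchor_cac` is `TRUE`, heptamer
#' mismatches avoid the first three (CAC) positions so anchored scans can
#' recover the plant. An optional first-order Markov background is available
#' because motif false-positive rates depend on dinucleotide structure.
#'
#' @param length Total sequence length, nt.
#' @param heptamer_offset 0-based offset of the planted heptamer.
#' @param m_h,m_n Exact mismatch counts for heptamer and nonamer.
#' @param spacer Planted spacer length, nt.
#' @param background_gc GC fraction of the background, default 0.5.
#' @param seed Integer seed.
#' @param anchor_cac Keep the CAC core intact (default `TRUE`).
#' @param consensus [rss_consensus()] supplying the planted motifs.
#' @param markov1 Optional 4x4 row-stochastic matrix (A,C,G,T order) for a
#'   first-order Markov background; default `NULL` for i.i.d.
#' @return List with `seq` (character scalar) and `truth` (planted
#'   parameters incl. the planted heptamer/nonamer strings and the seed).
#' @examples
#' g <- gen_rss_sequence(60, 17, 0, 12, 0, seed = 1)
#' scan_rss(g$seq, params = scan_params(0, 0))
#' @export
gen_rss_sequence <- function(length, heptamer_offset, m_h, spacer, m_n,
                             background_gc = 0.5, seed,
                             anchor_cac = TRUE, consensus = rss_consensus(),
                             markov1 = NULL) {
  length <- as.integer(length); heptamer_offset <- as.integer(heptamer_offset)
  m_h <- as.integer(m_h); m_n <- as.integer(m_n); spacer <- as.integer(spacer)
  if (heptamer_offset < 0L || heptamer_offset + 16L + spacer > length) {
    stop("RSS footprint does not fit: need heptamer_offset + 16 + spacer <= length",
         call. = FALSE)
  }
  allowed_h <- if (anchor_cac) 4:7 else 1:7
  if (m_h > length(allowed_h) || m_n > 9L || m_h < 0L || m_n < 0L) {
    stop("infeasible mismatch counts", call. = FALSE)
  }
  withr::with_seed(seed, {
    bg <- if (is.null(markov1)) random_bases(length, background_gc)
          else markov_bases(length, markov1)
    hept <- mutate_positions(strsplit(consensus$heptamer, "")[[1L]], m_h, allowed_h)
    nona <- mutate_positions(strsplit(consensus$nonamer, "")[[1L]], m_n, 1:9)
    bg[heptamer_offset + 1:7] <- hept
    bg[heptamer_offset + 7L + spacer + 1:9] <- nona
    list(seq = paste(bg, collapse = ""),
         truth = list(heptamer_offset = heptamer_offset, m_h = m_h,
                      spacer = spacer, m_n = m_n,
                      heptamer = paste(hept, collapse = ""),
                      nonamer = paste(nona, collapse = ""),
                      background_gc = background_gc, seed = seed))
  })
}

markov_bases <- function(n, P) {
  P <- as.matrix(P)
  stopifnot(all(dim(P) == c(4L, 4L)), all(abs(rowSums(P) - 1) < 1e-9))
  out <- character(n)
  out[1L] <- sample(BASES, 1L)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- sample(BASES, 1L, prob = P[match(out[i], BASES), ])
  }
  out
}

#' Generate clustered breakpoint records
#'
#' Plants `n_clusters` breakpoint clusters on one chromosome, each spanning
#' at most `cluster_span` nt (first and last member pinned to the cluster
#' ends so the realised span equals `cluster_span` when members >= 2), with
#' consecutive cluster starts separated by `intercluster_gap`. With
#' `cluster_span <= 100` and `intercluster_gap > max(cluster_span, 100)`,
#' clustering at the default 100 bp gap rule recovers exactly the planted
#' memberships.
#'
#' @param n_clusters Number of clusters.
#' @param breakpoints_per_cluster Members per cluster.
#' @param cluster_span Maximum span of each cluster, nt.
#' @param intercluster_gap Distance between consecutive cluster starts; must
#'   exceed both `cluster_span` and 100.
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @param start 1-based position of the first cluster, default 1,000,000.
#' @return List with `records` (a breakpoint `data.frame` with `sample_id`,
#'   `chrom`, `pos0`, `sv_type`) and `truth` (planted cluster positions and
#'   memberships).
#' @export
gen_breakpoint_records <- function(n_clusters, breakpoints_per_cluster,
                                   cluster_span, intercluster_gap, chrom = "chr1",
                                   seed, start = 1e6) {
  n_clusters <- as.integer(n_clusters)
  k <- as.integer(breakpoints_per_cluster)
  cluster_span <- as.integer(cluster_span)
  if (intercluster_gap <= max(cluster_span, 100L)) {
    stop("intercluster_gap must exceed max(cluster_span, 100)", call. = FALSE)
  }
  if (n_clusters < 1L || k < 1L || cluster_span < 0L) {
    stop("inconsistent generator geometry", call. = FALSE)
  }
  withr::with_seed(seed, {
    recs <- list(); truth_pos <- list()
    for (ci in seq_len(n_clusters)) {
      base <- as.integer(start + (ci - 1L) * intercluster_gap)  # 1-based
      pos <- if (k == 1L) base else if (k == 2L) c(base, base + cluster_span)
        else sort(c(base, base + cluster_span,
                    base + sample.int(cluster_span + 1L, k - 2L,
                                      replace = TRUE) - 1L))
      sv <- sample(setdiff(SV_TYPES, "unknown"), k, replace = TRUE)
      recs[[ci]] <- data.frame(
        sample_id = sprintf("S%02d_%02d", ci, seq_len(k)),
        chrom = chrom, pos0 = pos - 1L, sv_type = sv)
      truth_pos[[ci]] <- pos - 1L
    }
    records <- do.call(rbind, recs)
    # shuffle row order: clustering must not depend on it
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
    list(records = records,
         truth = list(n_clusters = n_clusters,
                      breakpoints_per_cluster = k,
                      cluster_span = cluster_span,
                      member_pos0 = truth_pos, chrom = chrom, seed = seed))
  })
}

#' Generate recombinant junction reads with known truth
#'
#' Constructs `junction = left_parent[0..cut_left) + insert +
#' right_parent[cut_right..end)`. Planting a microhomology of `mu` nt
#' requires the `mu` bases of the left parent ending at `cut_left` to equal
#' the `mu` bases of the right parent ending at `cut_right` (a shared word
#' across the transition); the generator verifies this. Microhomology and
#' insertion are mutually exclusive, mirroring the junction-call invariant.
#' Sequencing errors are i.i.d. substitutions at `error_rate` per base. The
#' recorded truth holds the `(p, q, mu, insert)` values [map_junction()]
#' recovers at zero error rate (computed from the constructed junction, so
#' flanking homology in the parents is accounted for).
#'
#' @param left_parent,right_parent Parental sequences.
#' @param cut_left Bases of the left parent retained (0-based cut position).
#' @param cut_right 0-based position on the right parent where retention
#'   starts.
#' @param microhomology Planted microhomology length, nt.
#' @param insert Inserted bases (character, possibly `""`).
#' @param n Number of reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector, FASTA-ready) and
#'   `truth`.
#' @export
gen_junction_reads <- function(left_parent, right_parent, cut_left, cut_right,
                               microhomology = 0L, insert = "", n = 1L,
                               error_rate = 0, seed) {
  l <- dna(left_parent, "left_parent"); r <- dna(right_parent, "right_parent")
  cut_left <- as.integer(cut_left); cut_right <- as.integer(cut_right)
  mu <- as.integer(microhomology)
  if (nzchar(insert)) insert <- dna(insert, "insert")
  if (mu > 0L && nzchar(insert)) {
    stop("microhomology and insert cannot both be positive", call. = FALSE)
  }
  if (cut_left < 1L || cut_left > nchar(l) || cut_right < 0L ||
      cut_right >= nchar(r)) {
    stop("cut sites must lie within the parents", call. = FALSE)
  }
  if (mu > 0L) {
    if (cut_left - mu < 0L || cut_right - mu < 0L) {
      stop("microhomology extends past a parent end", call. = FALSE)
    }
    left_word <- substr(l, cut_left - mu + 1L, cut_left)
    right_word <- substr(r, cut_right - mu + 1L, cut_right)
    if (left_word != right_word) {
      stop("parents do not share the requested ", mu,
           "-nt word at the cut sites (", left_word, " vs ", right_word, ")",
           call. = FALSE)
    }
  }
  junction <- paste0(substr(l, 1L, cut_left), insert,
                     substr(r, cut_right + 1L, nchar(r)))
  clean_call <- map_junction(junction, l, r)
  withr::with_seed(seed, {
    reads <- vapply(seq_len(n), function(i) {
      if (error_rate <= 0) return(junction)
      b <- strsplit(junction, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(b)) < error_rate)
      for (j in hit) b[j] <- sample(setdiff(BASES, b[j]), 1L)
      paste(b, collapse = "")
    }, character(1L))
    names(reads) <- sprintf("read%03d", seq_len(n))
    list(reads = reads,
         truth = list(cut_left = cut_left, cut_right = cut_right,
                      microhomology = mu, insert = insert,
                      p = clean_call$p, q = clean_call$q, mu = clean_call$mu,
                      insert_recovered = clean_call$insert_seq,
                      error_rate = error_rate, seed = seed))
  })
}

#' Generate binomial colony counts
#'
#' Per replicate, `CA ~ Binomial(A, p)` out of `A` ampicillin-resistant
#' colonies, emulating the episomal recombination assay readout.
#'
#' @param A Ampicillin-resistant colony total per replicate.
#' @param p True per-colony recombination probability (0..1; note percent
#'   frequency = 100 p).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @param condition Condition label written into the counts table.
#' @return List with `counts` (`data.frame`: `condition`, `replicate`, `CA`,
#'   `A`) and `truth`.
#' @export
gen_colony_counts <- function(A, p, n_replicates, seed,
                              condition = "synthetic") {
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (A <= 0) stop("A must be positive", call. = FALSE)
  withr::with_seed(seed, {
    ca <- stats::rbinom(n_replicates, size = round(A), prob = p)
    list(counts = data.frame(condition = condition,
                             replicate = seq_len(n_replicates),
                             CA = ca, A = round(A)),
         truth = list(A = A, p = p, n_replicates = n_replicates, seed = seed))
  })
}

#' Generate a two-gene cohort expression matrix with planted classes
#'
#' Per gene, each sample's class (L/M/H) is drawn from `class_proportions`
#' and its log2-scale expression from the class's normal component, with
#' component means `centre - separation`, `centre`, `centre + separation`.
#' Values are returned on the raw FPKM-like scale `2^x - 1`, so the standard
#' `log2(x + 1)` transform recovers the simulated scale exactly.
#'
#' @param n_samples Cohort size.
#' @param class_proportions Length-3 proportions (L, M, H) summing to 1,
#'   shared by both genes; default `c(0.25, 0.5, 0.25)` so percentile
#'   thresholds fall between the components.
#' @param separation Distance between adjacent component means (log2 units).
#' @param seed Integer seed.
#' @param genes Two gene names, default `c("RAG1", "RAG2")`.
#' @param sd Within-component standard deviation (log2 units), default 0.3.
#' @param centre Medium-component mean (log2 units), default 4.
#' @return List with `mat` (genes x samples numeric matrix, FPKM scale) and
#'   `truth` (per-gene planted class per sample).
#' @export
gen_expression_matrix <- function(n_samples, class_proportions = c(0.25, 0.5, 0.25),
                                  separation = 3, seed,
                                  genes = c("RAG1", "RAG2"), sd = 0.3,
                                  centre = 4) {
  if (length(class_proportions) != 3L ||
      abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("class_proportions must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  if (separation <= 0) {
    warning("separation <= 0: planted classes will not be recoverable",
            call. = FALSE)
  }
  withr::with_seed(seed, {
    cls <- c("L", "M", "H")
    means <- stats::setNames(centre + c(-1, 0, 1) * separation, cls)
    truth <- list(); rows <- list()
    for (g in genes) {
      k <- sample(cls, n_samples, replace = TRUE, prob = class_proportions)
      x <- stats::rnorm(n_samples, mean = means[k], sd = sd)
      rows[[g]] <- pmax(0, 2^x - 1)
      truth[[g]] <- k
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- genes
    colnames(mat) <- sprintf("P%04d", seq_len(n_samples))
    list(mat = mat,
         truth = list(classes = truth, class_proportions = class_proportions,
                      separation = separation, centre = centre, sd = sd,
                      seed = seed))
  })
}

#' Serialize / deserialize a planted-truth record as JSON
#'
#' @param truth The `truth` element returned by any generator.
#' @param path JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
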