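# Assembly of longer degenerate motifs from the positional k-mer weights
# of one module, plus enrichment scoring and clustering of motif sets.
# The assembly is a greedy overlap extension: seed with the heaviest
# k-mer, then repeatedly merge the heaviest remaining k-mer whose window
# offset places it consistently on the growing consensus (letters must
# agree on the overlap; N matches anything) or within `max_gap` of it,
# filling unoccupied interior positions with N.

#' Extract a module's positional k-mer weights
#'
#' Splits the module's k-mer basis column back into `(k-mer, offset,
#' weight)` triples.
#'
#' @param model A fitted [ionmf] model containing a k-mer source.
#' @param module Module index.
#' @param source Name of the k-mer source (default `"KMER"`).
#' @return Data frame with columns `kmer` (RNA alphabet), `offset`,
#'   `weight`, in decreasing weight order.
#' @export
kmer_weights <- function(model, module, source = "KMER") {
  if (is.null(model$H[[source]]))
    stop_input("model has no source '%s'", source)
  prof <- module_profile(model, module)$profiles[[source]]
  out <- data.frame(kmer = prof$feature, offset = prof$offset,
                    weight = prof$weight, stringsAsFactors = FALSE)
  out[order(-out$weight, out$kmer, out$offset), , drop = FALSE]
}

.motif_new <- function(kmer, offset, weight) {
  list(letters = strsplit(kmer, "")[[1L]], start = offset,
       seed_kmer = kmer, seed_offset = offset,
       support = data.frame(kmer = kmer, offset = offset, weight = weight,
                            stringsAsFactors = FALSE),
       score = weight)
}

# Try to place (kmer, offset) on the motif; returns updated motif or NULL.
.motif_merge <- function(motif, kmer, offset, weight, min_overlap, max_gap) {
  letters <- strsplit(kmer, "")[[1L]]
  k <- length(letters)
  m_start <- motif$start
  m_end <- m_start + length(motif$letters) - 1L
  k_end <- offset + k - 1L
  ov <- max(m_start, offset):min(m_end, k_end)
  overlapping <- offset <= m_end && k_end >= m_start
  if (overlapping) {
    if (length(ov) < min_overlap) return(NULL)
    mo <- motif$letters[ov - m_start + 1L]
    ko <- letters[ov - offset + 1L]
    agree <- mo == ko | mo == "N" | ko == "N"
    if (!all(agree)) return(NULL)
  } else {
    gap <- if (offset > m_end) offset - m_end - 1L else m_start - k_end - 1L
    if (gap > max_gap) return(NULL)
  }
  new_start <- min(m_start, offset)
  new_end <- max(m_end, k_end)
  new_letters <- rep("N", new_end - new_start + 1L)
  new_letters[(m_start:m_end) - new_start + 1L] <- motif$letters
  idx <- (offset:k_end) - new_start + 1L
  put <- new_letters[idx] == "N"  # never overwrite agreed letters
  new_letters[idx[put]] <- letters[put]
  motif$letters <- new_letters
  motif$start <- new_start
  motif$support <- rbind(motif$support,
                         data.frame(kmer = kmer, offset = offset,
                                    weight = weight,
                                    stringsAsFactors = FALSE))
  motif$score <- motif$score + weight
  motif
}

.motif_finalize <- function(motif) {
  structure(list(consensus = paste(motif$letters, collapse = ""),
                 start_offset = motif$start,
                 seed_kmer = motif$seed_kmer,
                 seed_offset = motif$seed_offset,
                 support = motif$support, score = motif$score),
            class = "rna_motif")
}

#' @export
print.rna_motif <- function(x, ...) {
  cat(sprintf("<rna_motif> %s @ %+d  score %.4g  (%d k-mers)\n",
              x$consensus, x$start_offset, x$score, nrow(x$support)))
  invisible(x)
}

#' Assemble degenerate motifs from weighted positional k-mers
#'
#' Greedy seeded assembly over `(k-mer, offset, weight)` triples: k-mers
#' are sorted by decreasing weight (ties broken lexicographically by k-mer,
#' then offset); the heaviest unused k-mer seeds a motif, and the heaviest
#' remaining k-mer that is placement-consistent with the consensus (letters
#' agree on the overlap, N wildcards allowed, gaps up to `max_gap` filled
#' with N) is merged until nothing fits.  Up to `top_n` motifs are
#' returned, each scored by the sum of its merged weights.  Doubling all
#' weights changes no consensus (assembly depends on weight order only).
#'
#' @param weighted_kmers Data frame with columns `kmer`, `offset`,
#'   `weight` (e.g. from [kmer_weights()]); zero-weight k-mers are
#'   ignored.
#' @param top_n Maximum number of motifs to assemble.
#' @param min_overlap Minimum number of overlapping positions for an
#'   overlap merge.
#' @param max_gap Maximum interior gap (in nt) bridged with N.
#' @return List of `"rna_motif"` objects, ordered as assembled (seeds in
#'   decreasing weight order); empty when all weights are zero.
#' @examples
#' wk <- data.frame(kmer = c("ACGU", "CGUA"), offset = c(0, 1),
#'                  weight = c(2, 1))
#' assemble_motifs(wk)[[1]]$consensus  # "ACGUA"
#' @export
assemble_motifs <- function(weighted_kmers, top_n = 10, min_overlap = 1,
                            max_gap = 2) {
  wk <- as.data.frame(weighted_kmers)
  if (!all(c("kmer", "offset", "weight") %in% names(wk)))
    stop_input("weighted_kmers needs columns kmer, offset, weight")
  if (any(wk$weight < 0)) stop_input("k-mer weights must be non-negative")
  wk <- wk[wk$weight > 0, , drop = FALSE]
  if (nrow(wk) == 0L) return(list())
  wk$kmer <- toupper(chartr("T", "U", as.character(wk$kmer)))
  wk <- wk[order(-wk$weight, wk$kmer, wk$offset), , drop = FALSE]
  used <- logical(nrow(wk))
  motifs <- list()
  while (any(!used) && length(motifs) < top_n) {
    seed <- which(!used)[1L]
    used[seed] <- TRUE
    motif <- .motif_new(wk$kmer[seed], wk$offset[seed], wk$weight[seed])
    repeat {
      merged <- FALSE
      for (i in which(!used)) {
        upd <- .motif_merge(motif, wk$kmer[i], wk$offset[i], wk$weight[i],
                            min_overlap, max_gap)
        if (!is.null(upd)) {
          motif <- upd
          used[i] <- TRUE
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    motifs[[length(motifs) + 1L]] <- .motif_finalize(motif)
  }
  motifs
}

.consensus_regex <- function(consensus) {
  gsub("N", ".", toupper(chartr("T", "U", consensus)), fixed = TRUE)
}

#' Log-odds enrichment of a motif near crosslink sites
#'
#' Compares how often the consensus (N = wildcard) occurs anywhere in the
#' windows around crosslinked sites versus background windows:
#' `log2( ((hits_pos + c) / (n_pos + 2c)) / ((hits_bg + c) / (n_bg + 2c)) )`
#' with Laplace pseudocount `c`.  Positive values mean the motif is
#' enriched near crosslink sites; swapping the two window sets flips the
#' sign.
#'
#' @param motif An `"rna_motif"` or a consensus string over
#'   `{A,C,G,U,N}`.
#' @param positive_windows,background_windows Character vectors of window
#'   sequences (RNA or DNA; case-insensitive), both non-empty.
#' @param pseudocount Laplace pseudocount (default 1).
#' @return Log2 odds ratio.
#' @export
motif_logodds <- function(motif, positive_windows, background_windows,
                          pseudocount = 1) {
  consensus <- if (inherits(motif, "rna_motif")) motif$consensus else motif
  if (length(positive_windows) == 0L || length(background_windows) == 0L)
    stop_input("both window sets must be non-empty")
  rx <- .consensus_regex(consensus)
  norm <- function(x) toupper(chartr("Tt", "Uu", x))
  h_pos <- sum(grepl(rx, norm(positive_windows)))
  h_bg <- sum(grepl(rx, norm(background_windows)))
  n_pos <- length(positive_windows)
  n_bg <- length(background_windows)
  log2(((h_pos + pseudocount) / (n_pos + 2 * pseudocount)) /
         ((h_bg + pseudocount) / (n_bg + 2 * pseudocount)))
}

# Flattened position x nucleotide indicator profile on a common offset
# frame; N (and positions outside the motif) count as uniform 1/4.
.motif_embedding <- function(motifs) {
  starts <- vapply(motifs, `[[`, 0, "start_offset")
  ends <- starts + vapply(motifs, function(m) nchar(m$consensus), 0L) - 1L
  frame <- min(starts):max(ends)
  nts <- c("A", "C", "G", "U")
  emb <- matrix(0.25, length(motifs), length(frame) * 4L)
  for (i in seq_along(motifs)) {
    letters <- strsplit(motifs[[i]]$consensus, "")[[1L]]
    for (j in seq_along(letters)) {
      col0 <- (which(frame == starts[i] + j - 1L) - 1L) * 4L
      hit <- match(letters[j], nts)
      if (!is.na(hit)) {
        emb[i, col0 + 1:4] <- 0
        emb[i, col0 + hit] <- 1
      }
    }
  }
  emb
}

#' Cluster assembled motifs into representative groups
#'
#' Embeds each motif as a flattened position-by-nucleotide indicator
#' profile (N and uncovered frame positions = uniform 1/4) and clusters
#' the profiles with k-means.  The representative of each cluster is its
#' highest-scoring member.
#'
#' @param motifs List of `"rna_motif"` objects, at least `k` of them.
#' @param k Number of clusters (default 20).
#' @param seed Integer seed for the k-means initialization.
#' @return A list with `labels` (cluster id per motif), `representatives`
#'   (index of the top-scoring member per cluster) and `centers_frame`
#'   (the offset frame used for the embedding).
#' @export
cluster_motifs <- function(motifs, k = 20, seed = 1) {
  if (length(motifs) < k)
    stop_input("need at least k = %d motifs, got %d", k, length(motifs))
  emb <- .motif_embedding(motifs)
  uniq <- !duplicated(emb)
  if (sum(uniq) <= k) {
    # at most k distinct profiles: each distinct profile is its own cluster
    labels <- match(apply(emb, 1L, paste, collapse = ","),
                    apply(emb[uniq, , drop = FALSE], 1L, paste,
                          collapse = ","))
  } else {
    set.seed(seed)
    labels <- kmeans(emb, centers = k, nstart = 10, iter.max = 50)$cluster
  }
  scores <- vapply(motifs, `[[`, 0, "score")
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    members[which.max(scores[members])]
  }, 0L)
  list(labels = labels, representatives = reps)
}

#' Position-frequency matrix of a motif
#'
#' @param motif An `"rna_motif"`.
#' @return A 4 x L matrix (rows A, C, G, U) of per-position base
#'   probabilities; N positions are uniform.
#' @export
motif_pfm <- function(motif) {
  letters <- strsplit(motif$consensus, "")[[1L]]
  nts <- c("A", "C", "G", "U")
  pfm <- matrix(0.25, 4L, length(letters),
                dimnames = list(nts, NULL))
  for (j in seq_along(letters)) {
    hit <- match(letters[j], nts)
    if (!is.na(hit)) {
      pfm[, j] <- 0
      pfm[hit, j] <- 1
    }
  }
  pfm
}

#' Export motifs in MEME minimal format
#'
#' @param motifs List of `"rna_motif"` objects.
#' @param path Output file.
#' @param alphabet Alphabet line to declare (default RNA).
#' @export
export_meme <- function(motifs, path, alphabet = "ACGU") {
  lines <- c("MEME version 4", "", sprintf("ALPHABET= %s", alphabet), "",
             "strands: +", "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    pfm <- motif_pfm(m)
    lines <- c(lines,
               sprintf("MOTIF %s m%d", m$consensus, i),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(pfm)),
               apply(pfm, 2L, function(p)
                 paste(sprintf("%.6f", p), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
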