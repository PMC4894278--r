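# Featurization of crosslink sites: sampling of positive/negative
# positions and the five aligned encoders (co-binding, region type,
# structure, positional k-mers, annotation terms).  All encoders emit one
# row per site, in site order, over a window of positions relative to the
# crosslink nucleotide, read 5'->3' on the site's strand.
#
# Coordinates are 0-based internally; BED input is 0-based half-open and
# GTF 1-based inclusive, converted on read.  Within each positional block,
# offset o maps to column o + upstream (0-based); blocks are ordered by
# feature label (C-locale lexicographic), then offset.

#' Relative-position window around a crosslink site
#'
#' @param upstream,downstream Number of positions considered on either side
#'   of the crosslink nucleotide (defaults give the `[-50..50]` window).
#' @return A list of class `"window_spec"` with `upstream`, `downstream`,
#'   `width` and the offset vector.
#' @export
window_spec <- function(upstream = 50, downstream = 50) {
  if (upstream < 0 || downstream < 0)
    stop_input("window extents must be non-negative")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 width = as.integer(upstream + downstream + 1L),
                 offsets = as.integer(-upstream:downstream)),
            class = "window_spec")
}

check_sites <- function(sites) {
  need <- c("chrom", "position", "strand")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop_input("site table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(sites$position < 0)) stop_input("site positions must be >= 0")
  if (!all(sites$strand %in% c("+", "-")))
    stop_input("site strand must be '+' or '-'")
  invisible(sites)
}

# m x width matrix of genomic positions; offset o lies at pos + o on the
# plus strand and pos - o on the minus strand (5'->3' on the transcript).
.site_positions <- function(sites, window) {
  sgn <- ifelse(sites$strand == "+", 1L, -1L)
  outer(seq_len(nrow(sites)), window$offsets,
        function(s, o) sites$position[s] + sgn[s] * o)
}

# -- plain-text readers/writers ------------------------------------------

#' Read crosslink sites from a BED file
#'
#' Expects BED6 (`chrom start end name score strand`) with the cDNA count
#' in the score column and the experiment identifier in the name column.
#' Intervals wider than one base (e.g. reported interaction clusters) are
#' expanded so that every covered position becomes one site.
#'
#' @param path BED file path.
#' @return Site data frame with columns `chrom`, `position` (0-based),
#'   `strand`, `cdna_count`, `experiment_id`.
#' @export
read_crosslink_bed <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6L)
    stop_input("%s: need BED6 (chrom start end name score strand)", path)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  widths <- bed$end - bed$start
  if (any(widths < 1L)) stop_input("%s: empty intervals", path)
  idx <- rep(seq_len(nrow(bed)), widths)
  offs <- sequence(widths) - 1L
  data.frame(chrom = bed$chrom[idx], position = bed$start[idx] + offs,
             strand = bed$strand[idx], cdna_count = bed$score[idx],
             experiment_id = as.character(bed$name[idx]),
             stringsAsFactors = FALSE)
}

#' Write crosslink sites as BED6
#'
#' @param sites Site data frame (see [read_crosslink_bed()]).
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  check_sites(sites)
  bed <- data.frame(sites$chrom, sites$position, sites$position + 1L,
                    sites$experiment_id %||% ".", sites$cdna_count %||% 0L,
                    sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a per-base double-strandedness probability track
#'
#' Accepts either a three-column table `chrom position probability`
#' (0-based positions, probability that the base is paired) or a
#' two-column per-base table `position unpaired_probability` as printed by
#' RNA folding tools for a single sequence, in which case `chrom` must be
#' given and the pairing probability is taken as `1 - unpaired`.
#'
#' @param path Input path.
#' @param chrom Chromosome name for the two-column format.
#' @return Data frame with columns `chrom`, `position`, `probability`.
#' @export
read_structure_track <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) >= 3L) {
    out <- data.frame(chrom = tab[[1L]], position = as.integer(tab[[2L]]),
                      probability = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
  } else if (ncol(tab) == 2L) {
    if (is.null(chrom))
      stop_input("%s: two-column track needs an explicit 'chrom'", path)
    out <- data.frame(chrom = chrom, position = as.integer(tab[[1L]]) - 1L,
                      probability = 1 - as.numeric(tab[[2L]]),
                      stringsAsFactors = FALSE)
  } else stop_input("%s: unrecognized track format", path)
  if (any(out$probability < 0 | out$probability > 1, na.rm = TRUE))
    stop_input("%s: probabilities outside [0, 1]", path)
  out
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path Tab-separated file with columns `gene_id` and `term`.
#' @return Data frame with columns `gene_id`, `term`.
#' @export
read_gene_terms <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab[[1L]]), term = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}

read_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop_input("no such file: %s", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome
}

read_annotation <- function(annotation) {
  if (is.character(annotation)) {
    if (!file.exists(annotation)) stop_input("no such file: %s", annotation)
    annotation <- rtracklayer::import(annotation)
  }
  annotation
}

# -- site sampling -------------------------------------------------------

#' Select peak crosslink positions of one experiment
#'
#' Keeps up to `pool_cap` sites with the highest cDNA counts, then accepts
#' sites greedily in descending count order, rejecting every candidate
#' closer than `min_distance` nucleotides to an already accepted site on
#' the same chromosome and strand; neighboring positions with equal counts
#' are resolved by a seeded random pick.  The accepted set is finally
#' subsampled uniformly to at most `cap` sites.
#'
#' @param sites Site data frame of a single experiment.
#' @param min_distance Minimum spacing between accepted sites (nt).
#' @param cap Maximum number of returned positions.
#' @param pool_cap Size of the initial highest-count pool.
#' @param seed Integer seed for tie-breaking and subsampling.
#' @return The accepted subset of `sites`, ordered by chromosome and
#'   position.
#' @export
select_peak_sites <- function(sites, min_distance = 15, cap = 10000,
                              pool_cap = 100000, seed = 1) {
  if (is.null(sites) || nrow(sites) == 0L) return(sites)
  check_sites(sites)
  set.seed(seed)
  ord <- order(-sites$cdna_count, runif(nrow(sites)))
  pool <- sites[ord[seq_len(min(length(ord), pool_cap))], , drop = FALSE]
  blocked <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(pool))
  for (s in seq_len(nrow(pool))) {
    key <- paste0(pool$chrom[s], ":", pool$strand[s], ":", pool$position[s])
    if (is.null(blocked[[key]])) {
      keep[s] <- TRUE
      for (p in (pool$position[s] - min_distance + 1L):
                (pool$position[s] + min_distance - 1L))
        blocked[[paste0(pool$chrom[s], ":", pool$strand[s], ":", p)]] <- TRUE
    }
  }
  out <- pool[keep, , drop = FALSE]
  if (nrow(out) > cap)
    out <- out[sample.int(nrow(out), cap), , drop = FALSE]
  out[order(out$chrom, out$position), , drop = FALSE]
}

genes_to_granges <- function(gene_regions) {
  if (inherits(gene_regions, "GRanges")) return(gene_regions)
  GenomicRanges::GRanges(
    seqnames = gene_regions$chrom,
    ranges = IRanges::IRanges(start = gene_regions$start + 1L,
                              end = gene_regions$end),
    strand = gene_regions$strand,
    gene_id = gene_regions$gene_id)
}

#' Sample non-interacting positions within genes
#'
#' Draws `n` distinct positions uniformly from the annotated gene space,
#' excluding every position reported as interacting in any experiment.
#'
#' @param gene_regions Gene intervals: a data frame with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `gene_id`, or a
#'   `GRanges` with a `gene_id` column.
#' @param interacting Site data frame of interacting positions (any
#'   experiment); positions are excluded on both strands.
#' @param n Number of negatives to draw (default 40000).
#' @param seed Integer seed.
#' @return Site data frame with `cdna_count = 0` and the covering gene's
#'   id; errors when fewer than `n` eligible positions exist, stating the
#'   deficit.
#' @export
sample_negatives <- function(gene_regions, interacting, n = 40000, seed = 1) {
  gr_genes <- genes_to_granges(gene_regions)
  if (length(gr_genes) == 0L) stop_input("no gene regions supplied")
  gr <- GenomicRanges::reduce(gr_genes)  # strand-aware union
  L <- sum(IRanges::width(gr))
  excl_keys <- character(0)
  k_excluded <- 0L
  if (!is.null(interacting) && nrow(interacting) > 0L) {
    excl_keys <- unique(paste0(interacting$chrom, ":", interacting$position))
    uniq <- interacting[!duplicated(paste0(interacting$chrom, ":",
                                           interacting$position)), ,
                        drop = FALSE]
    gri <- GenomicRanges::GRanges(uniq$chrom,
                                  IRanges::IRanges(uniq$position + 1L,
                                                   width = 1L))
    k_excluded <- sum(GenomicRanges::countOverlaps(gri, gr,
                                                   ignore.strand = TRUE))
  }
  eligible <- L - k_excluded
  if (n == 0L) {
    out <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), cdna_count = integer(0),
                      experiment_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (eligible < n)
    stop_input("only %d eligible gene positions for %d negatives (deficit %d)",
               eligible, n, n - eligible)
  set.seed(seed)
  cum <- c(0L, cumsum(IRanges::width(gr)))
  starts0 <- GenomicRanges::start(gr) - 1L
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  picked_idx <- integer(0)
  while (TRUE) {
    need <- n - length(picked_idx)
    if (need <= 0L) break
    cand <- setdiff(sample.int(L, min(L, max(2L * need, 100L))), picked_idx)
    j <- findInterval(cand - 0.5, cum)
    pos <- starts0[j] + (cand - cum[j] - 1L)
    ok <- !(paste0(chroms[j], ":", pos) %in% excl_keys)
    picked_idx <- c(picked_idx, cand[ok])
  }
  picked_idx <- picked_idx[seq_len(n)]
  j <- findInterval(picked_idx - 0.5, cum)
  pos <- starts0[j] + (picked_idx - cum[j] - 1L)
  out <- data.frame(chrom = chroms[j], position = pos, strand = strands[j],
                    cdna_count = 0L, experiment_id = NA_character_,
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$position + 1L,
                                                       width = 1L),
                           strand = out$strand),
    gr_genes, select = "first")
  out$gene_id <- gr_genes$gene_id[hit]
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Attach covering gene identifiers to sites
#'
#' @param sites Site data frame.
#' @param gene_regions Gene intervals (see [sample_negatives()]).
#' @return `sites` with a `gene_id` column (`NA` outside genes).
#' @export
assign_gene_ids <- function(sites, gene_regions) {
  check_sites(sites)
  gr_genes <- genes_to_granges(gene_regions)
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$position + 1L,
                                               width = 1L),
                              strand = sites$strand)
  hit <- GenomicRanges::findOverlaps(q, gr_genes, select = "first")
  sites$gene_id <- gr_genes$gene_id[hit]
  sites
}

#' Combine positive and negative sites into one labelled table
#'
#' @param positives,negatives Site data frames.
#' @return Row-bound site table with a binary `label` column.
#' @export
make_site_table <- function(positives, negatives) {
  cols <- c("chrom", "position", "strand", "cdna_count", "experiment_id",
            "gene_id")
  fill <- function(df) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df[cols]
  }
  out <- rbind(fill(positives), fill(negatives))
  out$label <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))
  rownames(out) <- NULL
  out
}

#' Split sites into train and test by gene
#'
#' Genes -- not individual sites -- are partitioned, so that no gene
#' contributes to both splits; every site inherits its gene's split and
#' sites without a gene go to the training split.
#'
#' @param sites Site table with a `gene_id` column.
#' @param test_fraction Fraction of genes assigned to the test split.
#' @param seed Integer seed.
#' @return `sites` with a `split` column (`"train"`/`"test"`).
#' @export
split_by_gene <- function(sites, test_fraction = 1 / 3, seed = 1) {
  if (is.null(sites$gene_id)) stop_input("sites need a 'gene_id' column")
  genes <- sort(unique(stats::na.omit(sites$gene_id)))
  set.seed(seed)
  n_test <- round(test_fraction * length(genes))
  test_genes <- sample(genes, n_test)
  sites$split <- ifelse(!is.na(sites$gene_id) &
                          sites$gene_id %in% test_genes, "test", "train")
  sites
}

# -- encoders ------------------------------------------------------------

#' Encode co-binding of other experiments (binary, positional)
#'
#' One 0/1 block of `width` columns per retained experiment: entry 1 when
#' that experiment reports a non-zero cDNA count at the relative offset
#' (read 5'->3' on the site's strand).  Experiments in the same replicate
#' group as the target experiment are excluded entirely, so replicate
#' information never leaks into the features.
#'
#' @param sites Site table being encoded.
#' @param other_sites Site data frame pooling the other experiments'
#'   crosslink positions (`experiment_id` distinguishes them).
#' @param replicate_groups Optional experiment-to-group mapping: a named
#'   character vector or a data frame with columns `experiment_id`,
#'   `group`.
#' @param window A [window_spec()].
#' @param target_experiment Identifier of the experiment being modelled;
#'   defaults to the (single) non-missing id in `sites`.
#' @return A `"CLIP"` [data_source] with `n_experiments x width` columns,
#'   blocks ordered by experiment id.
#' @export
encode_clip <- function(sites, other_sites, replicate_groups = NULL,
                        window = window_spec(), target_experiment = NULL) {
  check_sites(sites)
  if (is.null(target_experiment)) {
    ids <- unique(stats::na.omit(sites$experiment_id))
    target_experiment <- if (length(ids)) ids[[1L]] else NA_character_
  }
  if (!is.null(replicate_groups) && is.data.frame(replicate_groups))
    replicate_groups <- setNames(as.character(replicate_groups$group),
                                 replicate_groups$experiment_id)
  grp <- function(id) {
    if (!is.null(replicate_groups) && id %in% names(replicate_groups))
      replicate_groups[[id]] else paste0(".self.", id)
  }
  exps <- sort(unique(other_sites$experiment_id), method = "radix")
  if (!is.na(target_experiment)) {
    tgt_grp <- grp(target_experiment)
    exps <- exps[exps != target_experiment &
                   vapply(exps, grp, "") != tgt_grp]
  }
  m <- nrow(sites)
  w <- window$width
  gpos <- .site_positions(sites, window)
  qkeys <- paste0(rep(sites$chrom, each = w), ":",
                  rep(sites$strand, each = w), ":", as.vector(t(gpos)))
  mat <- matrix(0, m, length(exps) * w)
  for (e in seq_along(exps)) {
    es <- other_sites[other_sites$experiment_id == exps[e] &
                        other_sites$cdna_count > 0, , drop = FALSE]
    ekeys <- paste0(es$chrom, ":", es$strand, ":", es$position)
    hit <- matrix(qkeys %in% ekeys, m, w, byrow = TRUE)
    mat[, (e - 1L) * w + seq_len(w)] <- hit * 1
  }
  data_source(mat, "CLIP", make_positional_labels(exps, window$offsets))
}

#' Encode gene-region types (binary, positional)
#'
#' Five region channels -- exon, intron, 5'UTR, 3'UTR, CDS -- over the
#' relative window, 1 when the position (on the site's strand) falls in a
#' region of that type.  Channels are not exclusive: a coding exonic base
#' activates both `exon` and `CDS`.  Introns are derived as gene bodies
#' minus exons.  Positions outside any annotated gene activate nothing.
#'
#' @param sites Site table.
#' @param annotation GTF/GFF3 path or a `GRanges` with `type` and
#'   `gene_id` metadata columns.
#' @param window A [window_spec()].
#' @return An `"RG"` [data_source] with `5 x width` columns, channel blocks
#'   in label order `3UTR, 5UTR, CDS, exon, intron`.
#' @export
encode_regions <- function(sites, annotation, window = window_spec()) {
  check_sites(sites)
  ann <- read_annotation(annotation)
  type <- as.character(ann$type)
  exon <- GenomicRanges::reduce(ann[type == "exon"])
  cds <- GenomicRanges::reduce(ann[type == "CDS"])
  utr5 <- GenomicRanges::reduce(
    ann[type %in% c("five_prime_utr", "five_prime_UTR", "5UTR")])
  utr3 <- GenomicRanges::reduce(
    ann[type %in% c("three_prime_utr", "three_prime_UTR", "3UTR")])
  gene <- if (any(type == "gene")) ann[type == "gene"] else
    ann[type %in% c("exon", "CDS")]
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(gene), exon)
  channels <- list(`3UTR` = utr3, `5UTR` = utr5, CDS = cds, exon = exon,
                   intron = intron)  # label-lexicographic order

  m <- nrow(sites)
  w <- window$width
  gpos <- .site_positions(sites, window)
  q <- GenomicRanges::GRanges(
    rep(sites$chrom, each = w),
    IRanges::IRanges(as.vector(t(gpos)) + 1L, width = 1L),
    strand = rep(sites$strand, each = w))
  mat <- matrix(0, m, 5L * w)
  for (ch in seq_along(channels)) {
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(q, channels[[ch]],
                                   ignore.strand = FALSE)) > 0
    mat[, (ch - 1L) * w + seq_len(w)] <- matrix(hits, m, w, byrow = TRUE) * 1
  }
  data_source(mat, "RG",
              make_positional_labels(names(channels), window$offsets))
}

#' Encode RNA secondary structure probabilities (real-valued, positional)
#'
#' Per-site window of the probability that each base is in a
#' double-stranded conformation, taken from a precomputed per-base track
#' (see [read_structure_track()]).  Offsets run 5'->3' on the site's
#' strand, so minus-strand windows read the track in reverse.  Bases
#' missing from the track contribute 0 and trigger one summary warning.
#'
#' @param sites Site table.
#' @param track Structure track data frame (`chrom`, `position`,
#'   `probability`) or path.
#' @param window A [window_spec()].
#' @return An `"RNA"` [data_source] with `width` columns labelled
#'   `pairprob@offset`.
#' @export
encode_structure <- function(sites, track, window = window_spec()) {
  check_sites(sites)
  if (is.character(track)) track <- read_structure_track(track)
  vals <- setNames(track$probability, paste0(track$chrom, ":",
                                             track$position))
  m <- nrow(sites)
  w <- window$width
  gpos <- .site_positions(sites, window)
  keys <- paste0(rep(sites$chrom, each = w), ":", as.vector(t(gpos)))
  v <- unname(vals[keys])
  n_missing <- sum(is.na(v))
  if (n_missing > 0L)
    warning(sprintf("structure track: %d of %d window bases missing, set to 0",
                    n_missing, length(v)))
  v[is.na(v)] <- 0
  data_source(matrix(v, m, w, byrow = TRUE), "RNA",
              make_positional_labels("pairprob", window$offsets))
}

# Transcript-strand window sequence per site: width + extra bases starting
# at offset -upstream, 5'->3' on the site strand, N-padded at chromosome
# ends.  Returns uppercase DNA characters.
.site_window_seq <- function(sites, genome, window, extra = 0L) {
  genome <- read_genome(genome)
  chrseq <- lapply(unique(sites$chrom), function(ch) {
    if (!ch %in% names(genome))
      stop_input("chromosome '%s' not in genome", ch)
    toupper(as.character(genome[[ch]]))
  })
  names(chrseq) <- unique(sites$chrom)
  up <- window$upstream
  down <- window$downstream
  out <- character(nrow(sites))
  for (s in seq_len(nrow(sites))) {
    sq <- chrseq[[sites$chrom[s]]]
    len <- nchar(sq)
    pos <- sites$position[s]
    if (sites$strand[s] == "+") {
      g0 <- pos - up
      g1 <- pos + down + extra
    } else {
      g0 <- pos - down - extra
      g1 <- pos + up
    }
    left <- max(0L, -g0)
    right <- max(0L, g1 - (len - 1L))
    raw <- substr(sq, max(g0, 0L) + 1L, min(g1, len - 1L) + 1L)
    raw <- paste0(strrep("N", left), raw, strrep("N", right))
    if (sites$strand[s] == "-") {
      raw <- chartr("ACGTN", "TGCAN", raw)
      raw <- paste(rev(strsplit(raw, "", fixed = TRUE)[[1L]]),
                   collapse = "")
    }
    out[s] <- raw
  }
  out
}

#' Fetch transcript-strand window sequences
#'
#' Returns the sequence of each site's window, read 5'->3' on the site's
#' strand (minus-strand windows are reverse-complemented), N-padded at
#' chromosome boundaries.
#'
#' @param sites Site table.
#' @param genome FASTA path or `DNAStringSet`.
#' @param window A [window_spec()].
#' @param alphabet `"RNA"` (default) or `"DNA"` letters.
#' @return Character vector of window sequences.
#' @export
fetch_site_windows <- function(sites, genome, window = window_spec(),
                               alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  check_sites(sites)
  seqs <- .site_window_seq(sites, genome, window)
  if (alphabet == "RNA") chartr("T", "U", seqs) else seqs
}

#' Encode positional k-mers (binary)
#'
#' For every k-mer over `{A,C,G,U}` and every window offset, 1 when the
#' k-mer starts at that offset of the site's transcript-strand sequence.
#' The fetched sequence spans `[-upstream, downstream + k - 1]` so every
#' offset hosts a full k-mer; k-mers touching non-ACGT letters (chromosome
#' ends, ambiguity codes) are marked absent.
#'
#' @param sites Site table.
#' @param genome FASTA path or `DNAStringSet`.
#' @param k k-mer length (default 4).
#' @param window A [window_spec()].
#' @return A `"KMER"` [data_source] with `4^k x width` columns; blocks
#'   ordered by k-mer (RNA alphabet), then offset.
#' @export
encode_kmers <- function(sites, genome, k = 4, window = window_spec()) {
  check_sites(sites)
  k <- as.integer(k)
  if (k < 1L) stop_input("k must be >= 1")
  kmers_dna <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  seqs <- .site_window_seq(sites, genome, window, extra = k - 1L)
  m <- nrow(sites)
  w <- window$width
  mat <- matrix(0, m, length(kmers_dna) * w)
  for (s in seq_len(m)) {
    kms <- substring(seqs[s], seq_len(w), seq_len(w) + k - 1L)
    j <- match(kms, kmers_dna)
    ok <- !is.na(j)
    mat[s, (j[ok] - 1L) * w + which(ok)] <- 1
  }
  data_source(mat, "KMER",
              make_positional_labels(chartr("T", "U", kmers_dna),
                                     window$offsets))
}

#' Encode gene annotation terms (binary)
#'
#' One column per annotation term; a site's row carries 1 for every term
#' mapped to its gene.  Sites without a gene, or with an unannotated gene,
#' get an all-zero row.
#'
#' @param sites Site table with a `gene_id` column.
#' @param gene_terms Two-column data frame (`gene_id`, `term`) or path.
#' @return A `"GO"` [data_source] with one column per distinct term, in
#'   label order.
#' @export
encode_go <- function(sites, gene_terms) {
  if (is.character(gene_terms)) gene_terms <- read_gene_terms(gene_terms)
  terms <- sort(unique(gene_terms$term), method = "radix")
  mat <- matrix(0, nrow(sites), length(terms))
  if (!is.null(sites$gene_id)) {
    key <- paste0(gene_terms$gene_id, "\r", gene_terms$term)
    qk <- outer(sites$gene_id, terms, paste, sep = "\r")
    mat[] <- (qk %in% key) * 1
  }
  data_source(mat, "GO", terms)
}

#' Build all feature matrices for a site table
#'
#' Runs every encoder whose inputs are supplied and returns the aligned
#' blocks.
#'
#' @param sites Site table.
#' @param genome FASTA path or `DNAStringSet` (enables `KMER`).
#' @param annotation GTF path or `GRanges` (enables `RG`).
#' @param other_sites Other experiments' site data frame (enables `CLIP`).
#' @param replicate_groups Optional replicate grouping for `CLIP`.
#' @param structure_track Structure track path or data frame (enables
#'   `RNA`).
#' @param gene_terms Gene-to-term table path or data frame (enables `GO`).
#' @param k k-mer length.
#' @param window A [window_spec()].
#' @param target_experiment Passed to [encode_clip()].
#' @return Named list of [data_source] blocks (subset of `CLIP`, `RG`,
#'   `RNA`, `KMER`, `GO`).
#' @export
build_feature_matrices <- function(sites, genome = NULL, annotation = NULL,
                                   other_sites = NULL,
                                   replicate_groups = NULL,
                                   structure_track = NULL,
                                   gene_terms = NULL, k = 4,
                                   window = window_spec(),
                                   target_experiment = NULL) {
  check_sites(sites)
  out <- list()
  if (!is.null(other_sites))
    out$CLIP <- encode_clip(sites, other_sites, replicate_groups, window,
                            target_experiment)
  if (!is.null(annotation))
    out$RG <- encode_regions(sites, annotation, window)
  if (!is.null(structure_track))
    out$RNA <- encode_structure(sites, structure_track, window)
  if (!is.null(genome))
    out$KMER <- encode_kmers(sites, genome, k = k, window = window)
  if (!is.null(gene_terms))
    out$GO <- encode_go(sites, gene_terms)
  if (length(out) == 0L)
    stop_input("no encoder inputs supplied")
  out
}
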