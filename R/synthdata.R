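# Planted-module simulator.  Emulates the structure the factor model
# assumes: a shared membership matrix over r modules, per-source feature
# blocks that are exactly orthogonal (disjoint supports), predominantly
# binary observations, and a binary target driven by a subset of modules.

#' Simulate a planted-module multi-source dataset
#'
#' Draws a ground-truth coefficient matrix `W_true` in which every sample
#' belongs to one planted module and, with probability `p_multi`, to a
#' second one (module weights uniform on `[0.5, 1]`).  Each source gets a
#' basis `H_true` whose columns occupy contiguous, disjoint feature blocks
#' (weights uniform on `[0.5, 1]`), so the planted bases are exactly
#' orthogonal.  Binary sources are `X_i = 1(W_true H_true' > 0.25)` with a
#' fraction `noise_rate` of entries flipped; continuous sources (mimicking
#' a probability track) are `W_true H_true'` plus truncated Gaussian noise,
#' clipped to be non-negative.  The target is 1 for samples belonging to
#' any module in `target_modules`.
#'
#' @param m Number of samples (must be at least `10 * rank`).
#' @param rank Number of planted modules.
#' @param source_sizes Integer vector of per-source feature counts (each at
#'   least `rank`).
#' @param target_modules Module indices that generate the positive class.
#' @param noise_rate Fraction of binary entries flipped (and Gaussian SD
#'   for continuous sources), in `[0, 1)`.
#' @param p_multi Probability that a sample belongs to a second module.
#'   The default 0.5 reflects that module memberships of crosslink sites
#'   overlap heavily in practice.
#' @param continuous Indices of sources generated as continuous values
#'   instead of binary (default: none).
#' @param seed Integer seed; the output is reproducible per seed.
#' @return A list of class `"multiview_sim"` with `sources` (named list of
#'   [data_source]), `target` (0/1 vector) and `truth` (list with `W`,
#'   `H`, logical `membership`, `target_modules`, `noise_rate`).
#' @examples
#' sim <- simulate_multiview(m = 100, rank = 5, source_sizes = c(20, 30))
#' sapply(sim$sources, dim)
#' @export
simulate_multiview <- function(m = 1000, rank = 10,
                               source_sizes = c(200, 300, 400),
                               target_modules = 1:3, noise_rate = 0.05,
                               p_multi = 0.5, continuous = integer(0),
                               seed = 1) {
  if (m < 10 * rank)
    stop_input("m = %d too small for rank %d (need m >= 10 * rank)", m, rank)
  if (any(source_sizes < rank))
    stop_input("infeasible block partition: every source needs >= %d features",
               rank)
  if (noise_rate < 0 || noise_rate >= 1)
    stop_input("noise_rate must be in [0, 1)")
  if (length(target_modules) < 1L || any(target_modules < 1) ||
      any(target_modules > rank))
    stop_input("target_modules must be a subset of 1..%d", rank)
  set.seed(seed)

  primary <- sample.int(rank, m, replace = TRUE)
  has_second <- runif(m) < p_multi
  second <- ifelse(has_second,
                   ((primary - 1L + sample.int(rank - 1L, m,
                                               replace = TRUE)) %% rank) + 1L,
                   NA_integer_)
  membership <- matrix(FALSE, m, rank)
  membership[cbind(seq_len(m), primary)] <- TRUE
  membership[cbind(which(has_second), second[has_second])] <- TRUE
  W <- matrix(0, m, rank)
  W[membership] <- runif(sum(membership), 0.5, 1)

  H <- lapply(source_sizes, function(n) {
    Hi <- matrix(0, n, rank)
    bounds <- floor(seq(0, n, length.out = rank + 1))
    for (p in seq_len(rank)) {
      block <- (bounds[p] + 1L):bounds[p + 1L]
      Hi[block, p] <- runif(length(block), 0.5, 1)
    }
    Hi
  })

  sources <- vector("list", length(source_sizes))
  for (i in seq_along(source_sizes)) {
    lam <- W %*% t(H[[i]])
    if (i %in% continuous) {
      Xi <- pmax(lam + stats::rnorm(length(lam), 0, noise_rate), 0)
    } else {
      Xi <- (lam > 0.25) * 1
      n_flip <- round(noise_rate * length(Xi))
      if (n_flip > 0) {
        flip <- sample.int(length(Xi), n_flip)
        Xi[flip] <- 1 - Xi[flip]
      }
    }
    sources[[i]] <- data_source(
      Xi, paste0("S", i),
      paste0("s", i, "_f", seq_len(source_sizes[i])))
  }
  names(sources) <- vapply(sources, `[[`, "", "name")
  target <- as.numeric(rowSums(membership[, target_modules,
                                          drop = FALSE]) > 0)
  structure(list(sources = sources, target = target,
                 truth = list(W = W, H = H, membership = membership,
                              target_modules = target_modules,
                              noise_rate = noise_rate)),
            class = "multiview_sim")
}

#' @export
print.multiview_sim <- function(x, ...) {
  cat(sprintf("<multiview_sim> %d samples, %d modules, %d sources (%s), %d positives\n",
              nrow(x$truth$W), ncol(x$truth$W), length(x$sources),
              paste(vapply(x$sources, function(s) ncol(s$values), 0L),
                    collapse = "/"),
              sum(x$target)))
  invisible(x)
}

# -- toy genome ----------------------------------------------------------

#' Write a toy genome with planted crosslink sites
#'
#' Generates a single-chromosome genome of `n_genes` genes (alternating
#' strands, fixed exon/intron/UTR layout), plants a recognition motif next
#' to each crosslink site, and writes the five plain-text inputs the
#' feature encoders consume: a FASTA genome, a GTF annotation, BED site
#' lists for the target and co-binding experiments, a per-base
#' double-strandedness probability track, and a gene-to-term table.  All
#' coordinates are consistent across the files.  The default motif is a
#' Pumilio-like element.
#'
#' Gene layout (plus-strand genes; minus-strand genes are mirrored):
#' 5'UTR (60 nt) and first CDS part inside exon 1 (150 nt), one intron
#' (150 nt), exon 2 carrying the remaining CDS and a 3'UTR (80 nt).
#' Crosslink sites sit inside exon 2 with cDNA counts `5 + Poisson(20)`;
#' the motif is written on the transcript strand starting 2 nt downstream
#' of each site.  The structure track is 0.85 everywhere within genes
#' except 0.15 within 10 nt of a site.
#'
#' @param dir Output directory (created if missing).
#' @param n_genes Number of genes.
#' @param gene_length Length of each gene (>= 400).
#' @param sites_per_gene Crosslink sites planted per gene.
#' @param n_other Number of co-binding experiments (sites shifted +/- 7 nt
#'   from the target sites on alternating genes).
#' @param motif Planted DNA motif.
#' @param seed Integer seed.
#' @return A list with the file `paths` (fasta, gtf, sites, other_sites,
#'   structure, gene_terms), the planted `sites` table, `genes` table,
#'   `motif` and the chromosome name.
#' @export
simulate_toy_genome <- function(dir = tempfile("toygenome"), n_genes = 12,
                                gene_length = 600, sites_per_gene = 2,
                                n_other = 2, motif = "TGTAAATA", seed = 1) {
  if (gene_length < 400) stop_input("gene_length must be >= 400")
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "chrT"
  gap <- 200L
  gene_length <- as.integer(gene_length)
  starts <- gap + (seq_len(n_genes) - 1L) * (gene_length + gap)
  strands <- rep(c("+", "-"), length.out = n_genes)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                      chrom = chrom, start = starts,
                      end = starts + gene_length, strand = strands,
                      stringsAsFactors = FALSE)
  glen <- tail(genes$end, 1L) + gap
  seqchars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  # region layout in transcript coordinates [0, L)
  u5 <- 60L; e1 <- 150L; intr <- 150L; u3 <- 80L
  tx2g <- function(g, t) if (g$strand == "+") g$start + t else g$end - 1L - t

  gtf <- character(0)
  gtf_row <- function(type, s, e, g)
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, type, s + 1L, e, g$strand, g$gene_id)  # GTF is 1-based
  sites <- NULL
  other <- NULL
  for (i in seq_len(n_genes)) {
    g <- genes[i, ]
    L <- gene_length
    # transcript-coordinate segments: [start, end) pairs
    seg <- list(gene = c(0L, L),
                exon1 = c(0L, u5 + e1), intron = c(u5 + e1, u5 + e1 + intr),
                exon2 = c(u5 + e1 + intr, L),
                utr5 = c(0L, u5),
                cds1 = c(u5, u5 + e1),
                cds2 = c(u5 + e1 + intr, L - u3),
                utr3 = c(L - u3, L))
    type_of <- c(gene = "gene", exon1 = "exon", intron = "intron",
                 exon2 = "exon", utr5 = "five_prime_utr", cds1 = "CDS",
                 cds2 = "CDS", utr3 = "three_prime_utr")
    for (nm in names(seg)) {
      if (nm == "intron") next  # introns are implied by gene minus exons
      tt <- seg[[nm]]
      gpos <- sort(c(tx2g(g, tt[1L]), tx2g(g, tt[2L] - 1L)))
      gtf <- c(gtf, gtf_row(type_of[[nm]], gpos[1L], gpos[2L] + 1L, g))
    }
    # plant crosslink sites inside exon 2, 40 nt apart
    t0 <- u5 + e1 + intr + 30L
    for (s in seq_len(sites_per_gene)) {
      tpos <- t0 + (s - 1L) * 40L
      if (tpos >= L - u3 - 10L) break
      gpos <- tx2g(g, tpos)
      count <- 5L + rpois(1L, 20)
      sites <- rbind(sites, data.frame(
        chrom = chrom, position = gpos, strand = g$strand,
        cdna_count = count, experiment_id = "target",
        gene_id = g$gene_id, stringsAsFactors = FALSE))
      # write the motif on the transcript strand, 2 nt downstream of site
      mseq <- strsplit(motif, "")[[1L]]
      for (j in seq_along(mseq)) {
        gp <- tx2g(g, tpos + 2L + (j - 1L))
        seqchars[gp + 1L] <- if (g$strand == "+") mseq[j] else
          chartr("ACGT", "TGCA", mseq[j])
      }
      # co-binding experiments crosslink nearby on alternating genes
      for (e in seq_len(n_other)) {
        if ((i + e) %% 2L == 0L) {
          shift <- if (e %% 2L == 0L) 7L else -7L
          other <- rbind(other, data.frame(
            chrom = chrom, position = tx2g(g, tpos + shift),
            strand = g$strand, cdna_count = 1L + rpois(1L, 5),
            experiment_id = sprintf("exp%s", LETTERS[e + 1L]),
            gene_id = g$gene_id, stringsAsFactors = FALSE))
        }
      }
    }
  }

  # structure track: double-strandedness over all gene bases
  track <- NULL
  for (i in seq_len(n_genes)) {
    pos <- genes$start[i]:(genes$end[i] - 1L)
    prob <- rep(0.85, length(pos))
    near <- sites$position[sites$gene_id == genes$gene_id[i]]
    for (p in near) prob[abs(pos - p) <= 10L] <- 0.15
    track <- rbind(track, data.frame(chrom = chrom, position = pos,
                                     probability = prob))
  }

  terms <- rbind(
    data.frame(gene_id = genes$gene_id, term = "GO:0005575"),
    data.frame(gene_id = genes$gene_id[seq(1L, n_genes, 2L)],
               term = "GO:0003729"),
    data.frame(gene_id = genes$gene_id[seq(1L, n_genes, 3L)],
               term = "GO:0008380"))

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    sites = file.path(dir, "sites.bed"),
    other_sites = file.path(dir, "other_sites.bed"),
    structure = file.path(dir, "structure.tsv"),
    gene_terms = file.path(dir, "gene_terms.tsv"))
  writeLines(c(paste0(">", chrom), paste(seqchars, collapse = "")),
             paths$fasta)
  writeLines(gtf, paths$gtf)
  write_sites_bed(sites, paths$sites)
  write_sites_bed(other, paths$other_sites)
  write.table(track, paths$structure, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(terms, paths$gene_terms, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(paths = paths, sites = sites, other_sites = other, genes = genes,
       motif = motif, chrom = chrom)
}
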