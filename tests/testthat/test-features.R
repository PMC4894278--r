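toy_sites <- function(chrom, position, strand, count = 1,
                      experiment_id = "target", gene_id = NA) {
  data.frame(chrom = chrom, position = position, strand = strand,
             cdna_count = count, experiment_id = experiment_id,
             gene_id = gene_id, stringsAsFactors = FALSE)
}

test_that("peak selection applies the spacing rule and matches brute force", {
  # worked case: 100 (count 5), 110 (count 3), 130 (count 4) -> {100, 130}
  s <- toy_sites("c1", c(100, 110, 130), "+", count = c(5, 3, 4))
  picked <- select_peak_sites(s, min_distance = 15)
  expect_identical(picked$position, c(100, 130))

  # random instances with distinct counts agree with the O(n^2) oracle
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60
    s <- toy_sites(sample(c("c1", "c2"), n, TRUE),
                   sample(0:400, n), sample(c("+", "-"), n, TRUE),
                   count = sample.int(10 * n, n))  # distinct counts
    got <- select_peak_sites(s, min_distance = 15, seed = seed)
    want <- naive_peak_selection(s, 15)
    expect_identical(got[order(got$chrom, got$strand, got$position), ],
                     want[order(want$chrom, want$strand, want$position), ])
  }
})

test_that("equal-count neighbors: exactly one survives, chosen by seed", {
  s <- toy_sites("c1", c(200, 205), "+", count = c(7, 7))
  survivors <- vapply(1:20, function(sd)
    select_peak_sites(s, seed = sd)$position, 0)
  expect_true(all(vapply(1:20, function(sd)
    nrow(select_peak_sites(s, seed = sd)), 0L) == 1L))
  expect_setequal(unique(survivors), c(200, 205))  # both outcomes occur
  expect_identical(select_peak_sites(s, seed = 5)$position,
                   select_peak_sites(s, seed = 5)$position)
})

test_that("peak selection honors caps and passes well-spaced sites through", {
  s <- toy_sites("c1", seq(0, 990, by = 30), "+",
                 count = seq_len(34))
  expect_identical(nrow(select_peak_sites(s)), 34L)  # all >= 15 nt apart
  expect_identical(nrow(select_peak_sites(s, cap = 10)), 10L)
  expect_identical(nrow(select_peak_sites(s, pool_cap = 5)), 5L)
  empty <- s[0, ]
  expect_identical(nrow(select_peak_sites(empty)), 0L)
})

test_that("negative sampling excludes interacting positions and reports deficits", {
  genes <- data.frame(chrom = "c1", start = 0, end = 100, strand = "+",
                      gene_id = "g1")
  inter <- toy_sites("c1", 0:9, "+")
  neg <- sample_negatives(genes, inter, n = 50, seed = 1)
  expect_identical(nrow(neg), 50L)
  expect_false(any(duplicated(neg$position)))
  expect_true(all(neg$position %in% 10:99))
  expect_identical(unique(neg$gene_id), "g1")

  expect_identical(nrow(sample_negatives(genes, inter, n = 0)), 0L)
  expect_error(sample_negatives(genes, inter, n = 91, seed = 1),
               "deficit 1", class = "ionmf_input_error")
  # documented default matches the sampling design
  expect_identical(formals(sample_negatives)$n, 40000)
})

test_that("gene-level splits never share a gene and default sites to train", {
  tab <- toy_sites("c1", 1:10, "+",
                   gene_id = c(rep("g1", 4), rep("g2", 4), NA, NA))
  tab$label <- 1L
  one <- split_by_gene(tab, test_fraction = 0.5, seed = 1)
  expect_identical(length(intersect(one$gene_id[one$split == "train"],
                                    one$gene_id[one$split == "test"])), 0L)
  expect_identical(sort(unique(one$split[!is.na(one$gene_id)])),
                   c("test", "train"))  # one gene per split at 0.5
  expect_true(all(one$split[is.na(one$gene_id)] == "train"))

  single <- split_by_gene(toy_sites("c1", 1:3, "+", gene_id = "g1"), 0.4, 1)
  expect_identical(unique(single$split), "train")
})

test_that("co-binding encoder is positional, strand-aware and group-exclusive", {
  w <- window_spec(50, 50)
  sites <- toy_sites("c1", 500, "+")
  other <- toy_sites("c1", 497, "+", experiment_id = "expB")
  enc <- encode_clip(sites, other, window = w)
  expect_identical(dim(enc$values), c(1L, 101L))
  # offset -3 maps to block column 47 (0-based), i.e. 48 in R indexing
  expect_identical(unname(which(enc$values[1, ] == 1)), 48L)
  expect_identical(enc$feature_labels[48], "expB@-3")

  # on the minus strand the same genomic shift flips sign
  other_m <- toy_sites("c1", 497, "-", experiment_id = "expB")
  enc_m <- encode_clip(toy_sites("c1", 500, "-"), other_m, window = w)
  expect_identical(unname(which(enc_m$values[1, ] == 1)), 54L)  # offset +3

  # replicate-group exclusion removes whole experiments
  groups <- data.frame(experiment_id = c("target", "expB", "expC"),
                       group = c("G1", "G1", "G2"))
  other2 <- rbind(other, toy_sites("c1", 510, "+", experiment_id = "expC"))
  enc2 <- encode_clip(sites, other2, replicate_groups = groups, window = w)
  expect_identical(dim(enc2$values), c(1L, 101L))
  expect_true(all(startsWith(enc2$feature_labels, "expC@")))
})

test_that("region encoder emits 5 channels with overlap semantics", {
  w <- window_spec(10, 10)
  # single-exon coding gene on c1:[100, 200); CDS [120, 180)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "c1\ttoy\tgene\t101\t200\t.\t+\t.\tgene_id \"g1\";",
    "c1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id \"g1\";",
    "c1\ttoy\tCDS\t121\t180\t.\t+\t.\tgene_id \"g1\";"), gtf)
  sites <- toy_sites("c1", 150, "+")
  enc <- encode_regions(sites, gtf, window = w)
  expect_identical(dim(enc$values), c(1L, 5L * 21L))
  prof <- parse_feature_labels(enc$feature_labels)
  val <- setNames(enc$values[1, ], NULL)
  expect_true(all(val[prof$feature == "exon"] == 1))
  expect_true(all(val[prof$feature == "CDS"] == 1))   # overlaps exon
  expect_true(all(val[prof$feature %in% c("intron", "5UTR", "3UTR")] == 0))

  # intergenic sites are all-zero rows
  enc0 <- encode_regions(toy_sites("c1", 500, "+"), gtf, window = w)
  expect_true(all(enc0$values == 0))

  # intron channel is gene minus exon
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    "c1\ttoy\tgene\t101\t300\t.\t+\t.\tgene_id \"g1\";",
    "c1\ttoy\texon\t101\t150\t.\t+\t.\tgene_id \"g1\";"), gtf2)
  enc_i <- encode_regions(toy_sites("c1", 160, "+"), gtf2, window = w)
  vi <- setNames(enc_i$values[1, ], NULL)
  expect_true(all(vi[parse_feature_labels(enc_i$feature_labels)$feature ==
                       "intron"] == 1))
})

test_that("structure encoder places probabilities at offsets, strand-reversed", {
  w <- window_spec(2, 2)
  track <- data.frame(chrom = "c1", position = 98:102,
                      probability = c(0.1, 0.2, 0.3, 0.4, 0.5))
  plus <- suppressWarnings(
    encode_structure(toy_sites("c1", 100, "+"), track, w))
  expect_identical(unname(plus$values[1, ]), c(0.1, 0.2, 0.3, 0.4, 0.5))
  minus <- suppressWarnings(
    encode_structure(toy_sites("c1", 100, "-"), track, w))
  expect_identical(unname(minus$values[1, ]), c(0.5, 0.4, 0.3, 0.2, 0.1))

  # missing bases become 0 with a warning; all-zero track stays zero
  expect_warning(far <- encode_structure(toy_sites("c1", 1000, "+"),
                                         track, w), "missing")
  expect_true(all(far$values == 0))
  expect_identical(dim(plus$values), c(1L, 5L))
})

test_that("k-mer encoder marks starts per offset on the transcript strand", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "AACGT"), fa)
  w <- window_spec(1, 1)
  # site at 0-based position 2 on +: window sequence ACGT, k = 2
  enc <- encode_kmers(toy_sites("c1", 2, "+"), fa, k = 2, window = w)
  expect_identical(dim(enc$values), c(1L, 16L * 3L))
  on <- enc$feature_labels[enc$values[1, ] == 1]
  expect_setequal(on, c("AC@-1", "CG@0", "GU@1"))

  # minus strand: transcript window is the reverse complement of the
  # genomic span [0..3] "AACG" -> "CGUU"
  enc_m <- encode_kmers(toy_sites("c1", 2, "-"), fa, k = 2, window = w)
  on_m <- enc_m$feature_labels[enc_m$values[1, ] == 1]
  expect_setequal(on_m, c("CG@-1", "GU@0", "UU@1"))

  # windows running off the chromosome produce no k-mers there
  enc_edge <- encode_kmers(toy_sites("c1", 0, "+"), fa, k = 2, window = w)
  expect_identical(sum(enc_edge$values), 2)  # offset -1 k-mer hits the N pad
})

test_that("strand symmetry: a minus-strand site equals its reverse-complement locus", {
  fa <- tempfile(fileext = ".fa")
  set.seed(33)
  fwd <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", fwd), "")[[1]]),
              collapse = "")
  writeLines(c(">fwd", fwd, ">rc", rc), fa)
  w <- window_spec(5, 5)
  minus <- encode_kmers(toy_sites("fwd", 30, "-"), fa, k = 3, window = w)
  # position 30 on fwd's minus strand is position 29 on the rc sequence
  plus <- encode_kmers(toy_sites("rc", 60 - 1 - 30, "+"), fa, k = 3,
                       window = w)
  expect_identical(minus$values, plus$values)
})

test_that("annotation-term encoder is gene-driven", {
  terms <- data.frame(gene_id = c("g1", "g1", "g2"),
                      term = c("GO:1", "GO:2", "GO:2"))
  sites <- toy_sites("c1", c(1, 2, 3), "+", gene_id = c("g1", "g1", NA))
  enc <- encode_go(sites, terms)
  expect_identical(dim(enc$values), c(3L, 2L))
  expect_identical(enc$values[1, ], enc$values[2, ])  # same gene, same row
  expect_true(all(enc$values[3, ] == 0))
  expect_identical(enc$feature_labels, c("GO:1", "GO:2"))
})

test_that("encoders agree on rows and binary ranges across a toy genome", {
  tg <- simulate_toy_genome(tempfile("tg"), n_genes = 4, seed = 7)
  sites <- assign_gene_ids(tg$sites, tg$genes)
  w <- window_spec(10, 10)
  src <- build_feature_matrices(sites, genome = tg$paths$fasta,
                                annotation = tg$paths$gtf,
                                other_sites = tg$other_sites,
                                structure_track = tg$paths$structure,
                                gene_terms = tg$paths$gene_terms,
                                k = 3, window = w)
  expect_setequal(names(src), c("CLIP", "RG", "RNA", "KMER", "GO"))
  m <- vapply(src, function(s) nrow(s$values), 0L)
  expect_true(all(m == nrow(sites)))
  for (nm in c("CLIP", "RG", "KMER", "GO"))
    expect_true(all(src[[nm]]$values %in% c(0, 1)))
  expect_true(all(src$RNA$values >= 0 & src$RNA$values <= 1))
  # label round trip through the parser
  for (nm in names(src)) {
    p <- parse_feature_labels(src[[nm]]$feature_labels)
    rebuilt <- ifelse(is.na(p$offset), p$feature,
                      paste0(p$feature, "@", p$offset))
    expect_identical(rebuilt, src[[nm]]$feature_labels)
  }
})

test_that("site windows around planted sites carry the planted motif", {
  tg <- simulate_toy_genome(tempfile("tg"), n_genes = 4, seed = 9)
  wins <- fetch_site_windows(tg$sites, tg$paths$fasta, window_spec(20, 20))
  expect_true(all(grepl(chartr("T", "U", tg$motif), wins)))
  # BED round trip preserves the sites
  bed <- read_crosslink_bed(tg$paths$sites)
  expect_identical(bed$position, tg$sites$position)
  expect_identical(bed$cdna_count, tg$sites$cdna_count)
})
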