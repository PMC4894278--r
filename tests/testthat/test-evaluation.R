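test_that("subset enumeration covers all non-empty combinations", {
  subs <- source_subsets(c("C", "K", "T", "G", "R"))
  expect_length(subs, 31)
  expect_identical(subs[[1]], "C")
  expect_identical(subs[[31]], c("C", "G", "K", "R", "T"))
  expect_false(any(duplicated(vapply(subs, paste, "", collapse = "+"))))
})

test_that("informative sources outscore noise sources at matched capacity", {
  sim <- simulate_multiview(m = 240, rank = 4, source_sizes = c(40, 50),
                            target_modules = 1:2, noise_rate = 0.02,
                            seed = 17)
  set.seed(99)
  noise <- data_source(matrix(rbinom(240 * 45, 1, 0.2), 240, 45), "NOISE")
  sources <- c(sim$sources, list(NOISE = noise))
  tab <- evaluate_subsets(sources, sim$target,
                          subsets = list("S1", "NOISE", c("S1", "S2")),
                          folds = 3, rank = 4, max_iter = 120,
                          n_restarts = 1, seed = 5)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$subset, c("S1", "NOISE", "S1+S2"))
  auc <- setNames(tab$mean_auc, tab$subset)
  expect_gt(auc[["S1"]], auc[["NOISE"]])
  expect_gt(auc[["S1+S2"]], auc[["NOISE"]])
  expect_true(all(tab$se >= 0))
  # matched capacity: smaller subsets get larger ranks
  expect_gte(tab$rank[1], tab$rank[3])
})

test_that("single-subset evaluation yields one row", {
  sim <- simulate_multiview(m = 120, rank = 3, source_sizes = c(20, 25),
                            target_modules = 1:2, seed = 23)
  tab <- evaluate_subsets(sim$sources, sim$target, subsets = list("S1"),
                          folds = 2, rank = 3, max_iter = 60,
                          n_restarts = 1, seed = 4)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$subset, "S1")
})

test_that("model and feature archives round-trip losslessly", {
  sim <- simulate_multiview(m = 80, rank = 3, source_sizes = c(12, 15),
                            seed = 31)
  fit <- ionmf(sim$sources, sim$target, rank = 3, max_iter = 40,
               n_restarts = 1, seed = 6)
  dir <- tempfile("model")
  write_model(fit, dir)
  back <- read_model(dir)
  expect_equal(unname(back$W), unname(fit$W))
  for (nm in names(fit$H)) {
    expect_identical(unname(back$H[[nm]]), unname(fit$H[[nm]]))
    expect_identical(rownames(back$H[[nm]]),
                     sim$sources[[nm]]$feature_labels)
  }
  expect_identical(unname(back$H_Y), unname(fit$H_Y))
  expect_identical(back$rank, fit$rank)
  expect_identical(back$alpha, fit$alpha)
  expect_identical(back$report$iterations_run,
                   fit$report$iterations_run)
  expect_equal(back$report$objective_trace$total,
               fit$report$objective_trace$total)

  sdir <- tempfile("sources")
  write_sources(sim$sources, sdir)
  src2 <- read_sources(sdir)
  expect_identical(names(src2), names(sim$sources))
  expect_equal(unname(src2$S1$values), unname(sim$sources$S1$values))
  expect_identical(src2$S1$feature_labels, sim$sources$S1$feature_labels)

  # a projected model scores identically after the round trip
  p1 <- ionmf_project(fit, sim$sources)
  p2 <- ionmf_project(back, sim$sources)
  expect_equal(p1$Y_hat, p2$Y_hat)
})

test_that("the simulated pipeline is deterministic and self-consistent", {
  out1 <- tempfile("run1")
  out2 <- tempfile("run2")
  cfg <- list(simulate = TRUE, m = 150, rank = 4, max_iter = 80,
              n_restarts = 1, seed = 3, test_fraction = 0.25)
  r1 <- run_pipeline(c(cfg, list(out_dir = out1)))
  r2 <- run_pipeline(c(cfg, list(out_dir = out2)))
  expect_gt(r1$auc, 0.8)
  expect_identical(r1$auc, r2$auc)

  # manifests agree except for the timestamp
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  m1$timestamp <- m2$timestamp <- NULL
  m1$config$out_dir <- m2$config$out_dir <- NULL
  expect_identical(m1, m2)
  expect_true(all(file.exists(file.path(out1,
                                        c("predictions.tsv",
                                          "module_summary.tsv",
                                          "manifest.json")))))
})

test_that("the genomic pipeline runs end to end on a toy genome", {
  tg <- simulate_toy_genome(tempfile("tg"), n_genes = 10,
                            gene_length = 600, sites_per_gene = 3,
                            seed = 18)
  out <- tempfile("run")
  # windows extending past gene edges fall off the structure track, which
  # the encoder reports; harmless here
  res <- suppressWarnings(run_pipeline(list(
    sites = tg$paths$sites, genome = tg$paths$fasta, gtf = tg$paths$gtf,
    other_sites = tg$paths$other_sites, structure = tg$paths$structure,
    go = tg$paths$gene_terms, window = 15, k = 3, rank = 4,
    n_negatives = 120, max_iter = 80, n_restarts = 1, seed = 2,
    out_dir = out)))
  expect_gt(res$auc, 0.8)
  expect_true(file.exists(file.path(out, "model", "meta.json")))
  expect_true(file.exists(res$paths$predictions))
  preds <- read.table(res$paths$predictions, header = TRUE)
  expect_identical(sort(names(preds)),
                   c("chrom", "position", "score", "strand"))
  # no gene is shared between train and test
  tr_genes <- unique(res$sites$gene_id[res$sites$split == "train"])
  te_genes <- unique(res$sites$gene_id[res$sites$split == "test"])
  expect_length(intersect(stats::na.omit(tr_genes),
                          stats::na.omit(te_genes)), 0)
})

test_that("missing pipeline inputs fail fast with a structured error", {
  expect_error(run_pipeline(list(sites = "/nonexistent.bed",
                                 genome = "/nonexistent.fa")),
               "missing input", class = "ionmf_input_error")
  expect_error(run_pipeline(list()), class = "ionmf_input_error")
})

test_that("the command-line interface drives a train/modules/motifs chain", {
  script <- system.file("scripts", "ionmf", package = "ionmf")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run_cli <- function(...) {
    system2(rscript, c(script, ...), stdout = TRUE, stderr = TRUE,
            env = libs)
  }
  simdir <- tempfile("sim")
  out <- run_cli("simulate", "--m", "120", "--rank", "3",
                 "--out", simdir, "--seed", "4")
  expect_true(file.exists(file.path(simdir, "target.tsv")))
  moddir <- tempfile("model")
  run_cli("train", "--features", simdir, "--rank", "3", "--max-iter", "60",
          "--restarts", "1", "--out", moddir, "--seed", "4")
  expect_true(file.exists(file.path(moddir, "meta.json")))
  mod_tsv <- tempfile(fileext = ".tsv")
  run_cli("modules", "--model", moddir, "--out", mod_tsv)
  expect_true(file.exists(mod_tsv))
  summ <- read.table(mod_tsv, header = TRUE, sep = "\t")
  expect_identical(nrow(summ), 3L)

  # unknown commands exit with the bad-input code
  bad <- suppressWarnings(system2(rscript, c(script, "frobnicate"),
                                  stdout = FALSE, stderr = FALSE,
                                  env = libs))
  expect_identical(bad, 2L)
})
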