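# a deliberately small configuration: easy cells, short alignments
smoke_config <- function(n_replicates = 2L, n_sites = 300, seed = 1L) {
  grid_config(topology = "A", sib_values = 0.3, long_values = c(0.1, 0.3),
              seq_lengths = n_sites, long_seq_lengths = numeric(0),
              models = list(gamma_inv_true =
                              model_spec("gamma_inv", alpha = 1, p_inv = 0.3)),
              correct_model = "gamma_inv_true",
              n_replicates = n_replicates, master_seed = seed)
}

test_that("the default grid enumerates the full factorial design", {
  cfg <- grid_config(topology = c("A", "B"))
  cells <- grid_cells(cfg)
  # 5 SiB x 8 elongation = 40 branch cells per topology per model per length
  base <- dplyr::filter(cells, .data$n_sites < 1e5)
  expect_identical(nrow(base), 2L * 40L * 4L * 4L)
  counts <- dplyr::count(base, .data$topology, .data$model, .data$n_sites)
  expect_true(all(counts$n == 40L))
  # the 100,000 tier exists only under the correct model
  tier <- dplyr::filter(cells, .data$n_sites == 1e5)
  expect_identical(unique(tier$model), "gamma_inv_true")
  expect_identical(nrow(tier), 2L * 40L)
})

test_that("replicate substream seeds are deterministic and distinct", {
  s1 <- lbasim:::replicate_seed(1L, "A", 0.1, 0.5, 10000L, "gamma_est", 3L)
  s2 <- lbasim:::replicate_seed(1L, "A", 0.1, 0.5, 10000L, "gamma_est", 3L)
  expect_identical(s1, s2)
  others <- c(
    lbasim:::replicate_seed(1L, "A", 0.1, 0.5, 10000L, "gamma_est", 4L),
    lbasim:::replicate_seed(1L, "B", 0.1, 0.5, 10000L, "gamma_est", 3L),
    lbasim:::replicate_seed(2L, "A", 0.1, 0.5, 10000L, "gamma_est", 3L),
    lbasim:::replicate_seed(1L, "A", 0.3, 0.5, 10000L, "gamma_est", 3L))
  expect_false(any(others == s1))
  expect_true(all(c(s1, others) >= 0 & c(s1, others) < 2^31))
})

test_that("run_replicate is reproducible and records a full pipeline", {
  cfg <- smoke_config()
  r1 <- run_replicate(cfg, "A", 0.3, 0.1, 300, "gamma_inv_true", 1)
  r2 <- run_replicate(cfg, "A", 0.3, 0.1, 300, "gamma_inv_true", 1)
  expect_identical(r1, r2)
  expect_true(is.finite(r1$loglik))
  expect_true(r1$class %in% error_classes())
  expect_s3_class(parse_newick(r1$inferred_newick), "phylo")
  expect_error(run_replicate(cfg, "A", 0.3, 0.1, 300, "nope", 1), "unknown model")
})

test_that("a smoke grid completes, summarizes, and is deterministic", {
  cfg <- smoke_config()
  out <- run_grid(cfg)
  expect_identical(nrow(out$records), 4L)   # 2 cells x 2 replicates
  expect_identical(nrow(out$summaries), 2L)
  expect_true(all(out$summaries$n == 2L))
  counts <- out$summaries$n_correct + out$summaries$n_class_I +
    out$summaries$n_class_II + out$summaries$n_class_III +
    out$summaries$n_other
  expect_identical(as.integer(counts), rep(2L, 2))
  # end-to-end determinism of the whole grid
  out2 <- run_grid(cfg)
  expect_identical(out$records, out2$records)
  expect_identical(as.data.frame(out$summaries), as.data.frame(out2$summaries))
})

test_that("run_grid resumes from on-disk records without recomputation", {
  cfg <- smoke_config()
  dir <- withr::local_tempdir()
  out1 <- run_grid(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "records.tsv")))
  t0 <- proc.time()
  out2 <- run_grid(cfg, out_dir = dir)
  elapsed <- (proc.time() - t0)[3]
  expect_lt(elapsed, 2)  # cached cells are skipped
  expect_equal(as.data.frame(out2$records), as.data.frame(out1$records),
               tolerance = 1e-9)
  # a partial cell (fewer rows than n_replicates) is detected and re-run
  rec <- readr::read_tsv(file.path(dir, "records.tsv"), show_col_types = FALSE)
  readr::write_tsv(rec[-1, ], file.path(dir, "records.tsv"))
  out3 <- run_grid(cfg, out_dir = dir)
  expect_equal(nrow(out3$records), 4L)
  expect_equal(as.data.frame(out3$records)$loglik,
               as.data.frame(out1$records)$loglik, tolerance = 1e-9)
})

test_that("summaries compute success, means, and dominance flags", {
  rec <- tibble::tibble(
    topology = "B", sib = 0.01, long_branch = 1.5, n_sites = 2000L,
    model = "gamma_inv_true", rep_index = 1:10,
    seed = 1:10, loglik = -1000, alpha_hat = 1, p_inv_hat = 0.3,
    n_rounds = 1L,
    class = c(rep("class_I", 6), rep("correct", 3), "class_II"),
    inferred_newick = "x;")
  s <- summarize_replicates(rec)
  expect_identical(s$n_class_I, 6L)
  expect_equal(s$success, 0.3)
  expect_identical(s$dominant_artefact, "class_I")
  # single correct record: success 1, no dominance
  s2 <- summarize_replicates(rec[7, ])
  expect_equal(s2$success, 1)
  expect_true(is.na(s2$dominant_artefact))
  # no class exceeding half leaves the flag unset
  rec3 <- rec
  rec3$class <- c(rep("class_I", 5), rep("correct", 5))
  expect_true(is.na(summarize_replicates(rec3)$dominant_artefact))
  expect_error(summarize_replicates(rec[0, ]), "no replicate records")
})

test_that("summary plots build without error", {
  cfg <- smoke_config()
  out <- run_grid(cfg)
  p1 <- plot_success(out$summaries)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_error_classes(out$summaries)
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(out$summaries)
  expect_s3_class(p3, "ggplot")
})

test_that("the symplesiomorphy artefact persists at very long alignments", {
  # the grouping of the focal short pair is a systematic bias: unlike the
  # long-terminal case, it does not vanish as sites accumulate
  cfg <- grid_config(topology = "B", n_replicates = 4L, master_seed = 303L)
  rec <- purrr::map_dfr(1:4, function(r)
    run_replicate(cfg, "B", sib = 0.01, long_branch = 1.5, n_sites = 100000,
                  model = "gamma_inv_true", rep_index = r))
  expect_lt(mean(rec$class == "correct"), 0.8)
})

test_that("modelling rate heterogeneity improves success at an artefact-prone cell", {
  cfg <- grid_config(topology = "B", n_replicates = 12L, master_seed = 404L)
  succ <- vapply(c("gamma_inv_true", "no_asrv"), function(m) {
    rec <- purrr::map_dfr(1:12, function(r)
      run_replicate(cfg, "B", sib = 0.05, long_branch = 0.9, n_sites = 2000,
                    model = m, rep_index = r))
    mean(rec$class == "correct")
  }, numeric(1))
  expect_gte(succ[["gamma_inv_true"]], succ[["no_asrv"]])
})

test_that("an easy cell yields mostly correct replicates", {
  cfg <- grid_config(topology = "A", n_replicates = 6L, master_seed = 505L)
  rec <- purrr::map_dfr(1:6, function(r)
    run_replicate(cfg, "A", sib = 0.5, long_branch = 0.1, n_sites = 10000,
                  model = "gamma_inv_true", rep_index = r))
  expect_gte(mean(rec$class == "correct"), 5 / 6)
})
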