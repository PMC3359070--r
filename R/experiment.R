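#' Grid experiment: simulate, infer, classify, aggregate
#'
#' [grid_config()] describes a factorial design over topology kind, short
#' internal branch length, elongated branch length, alignment length, and
#' analysis model setting; [run_grid()] executes it replicate by replicate
#' with fully reproducible per-replicate RNG substreams and returns tidy
#' tibbles of per-replicate records and per-cell summaries.
#'
#' @name experiment
NULL

#' Configure a branch-length grid experiment
#'
#' Defaults follow the full study design: short internal branch lengths
#' \{0.01, 0.05, 0.1, 0.3, 0.5\}, elongated branch 0.1 to 1.5 in steps of
#' 0.2, alignment lengths \{2000, 3000, 4000, 10000\} for all four analysis
#' settings plus 100,000 restricted to the correct-parameter model, and 100
#' replicates. Every simulated alignment is generated under JC + continuous
#' gamma (`sim_alpha`) + invariant sites (`sim_p_inv`).
#'
#' Replicate substream seeds are derived by hashing the master seed with
#' the cell coordinates and replicate index, so any single replicate can be
#' reproduced in isolation.
#'
#' @param topology `"A"`, `"B"`, or both.
#' @param sib_values Short-internal-branch grid.
#' @param long_values Elongated-branch grid (terminal for A, internal for B).
#' @param seq_lengths Alignment lengths applied to every model setting.
#' @param long_seq_lengths Alignment lengths restricted to the
#'   correct-parameter model (`correct_model`).
#' @param models Named list of [model_spec()] settings (default
#'   [standard_model_settings()]).
#' @param correct_model Name of the `models` entry regarded as the correct
#'   fixed-parameter setting.
#' @param n_replicates Replicates per cell.
#' @param master_seed Integer master seed.
#' @param rb Constant background branch length.
#' @param sim_alpha,sim_p_inv Generating gamma shape and invariant
#'   proportion.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(topology = c("A", "B"),
                        sib_values = c(0.01, 0.05, 0.1, 0.3, 0.5),
                        long_values = seq(0.1, 1.5, by = 0.2),
                        seq_lengths = c(2000, 3000, 4000, 10000),
                        long_seq_lengths = 100000,
                        models = standard_model_settings(),
                        correct_model = "gamma_inv_true",
                        n_replicates = 100L,
                        master_seed = 1L,
                        rb = 0.05,
                        sim_alpha = 1.0,
                        sim_p_inv = 0.3) {
  topology <- match.arg(topology, several.ok = TRUE)
  stopifnot(all(sib_values > 0), all(long_values > 0),
            all(seq_lengths >= 1), n_replicates >= 1, rb > 0,
            is.list(models), !is.null(names(models)))
  if (length(long_seq_lengths) && !correct_model %in% names(models))
    stop("correct_model '", correct_model, "' is not among the model settings",
         call. = FALSE)
  structure(
    list(topology = topology, sib_values = sib_values,
         long_values = long_values, seq_lengths = seq_lengths,
         long_seq_lengths = long_seq_lengths, models = models,
         correct_model = correct_model,
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed), rb = rb,
         sim_alpha = sim_alpha, sim_p_inv = sim_p_inv),
    class = "grid_config")
}

#' @export
print.grid_config <- function(x, ...) {
  cat("Grid experiment configuration\n")
  cat("  topologies:", paste(x$topology, collapse = ", "), "\n")
  cat("  SiB values:", paste(x$sib_values, collapse = ", "), "\n")
  cat("  elongated-branch values:", paste(x$long_values, collapse = ", "), "\n")
  cat("  alignment lengths:", paste(x$seq_lengths, collapse = ", "),
      if (length(x$long_seq_lengths))
        paste0("(+ ", paste(x$long_seq_lengths, collapse = ", "),
               " for ", x$correct_model, " only)"), "\n")
  cat("  model settings:", paste(names(x$models), collapse = ", "), "\n")
  cat("  replicates/cell:", x$n_replicates,
      " master seed:", x$master_seed, "\n")
  cat("  simulated as: alpha =", x$sim_alpha, ", p_inv =", x$sim_p_inv,
      ", RB =", x$rb, "\n")
  cells <- grid_cells(x)
  cat("  admissible cells:", nrow(cells), "\n")
  invisible(x)
}

#' Enumerate the admissible cells of a grid
#'
#' The long alignment tier (`long_seq_lengths`) is crossed only with the
#' correct-parameter model; all other lengths are crossed with every model
#' setting.
#'
#' @param config A [grid_config()].
#' @return Tibble with one row per cell: `topology`, `sib`, `long_branch`,
#'   `n_sites`, `model`.
#' @export
grid_cells <- function(config) {
  base <- tidyr::expand_grid(
    topology = config$topology, sib = config$sib_values,
    long_branch = config$long_values, n_sites = config$seq_lengths,
    model = names(config$models))
  if (length(config$long_seq_lengths)) {
    extra <- tidyr::expand_grid(
      topology = config$topology, sib = config$sib_values,
      long_branch = config$long_values, n_sites = config$long_seq_lengths,
      model = config$correct_model)
    base <- dplyr::bind_rows(base, extra)
  }
  dplyr::arrange(base, .data$topology, .data$sib, .data$long_branch,
                 .data$n_sites, .data$model)
}

# deterministic 31-bit substream seed from the master seed + coordinates
replicate_seed <- function(master_seed, topology, sib, long_branch,
                           n_sites, model, rep_index) {
  key <- sprintf("%d|%s|%.10g|%.10g|%d|%s|%d", as.integer(master_seed),
                 topology, sib, long_branch, as.integer(n_sites), model,
                 as.integer(rep_index))
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Run one replicate of the simulate-infer-classify pipeline
#'
#' Builds the model tree for the cell, simulates an alignment under the
#' generating model with the replicate's substream seed, runs [ml_search()]
#' under the cell's analysis setting, and classifies the inferred tree.
#'
#' @param config A [grid_config()].
#' @param topology `"A"` or `"B"`.
#' @param sib Short internal branch length.
#' @param long_branch Elongated branch length (LtB for A, LiB for B).
#' @param n_sites Alignment length.
#' @param model Name of the analysis model setting in `config$models`.
#' @param rep_index Replicate number (1-based).
#' @return One-row tibble (a replicate record).
#' @export
run_replicate <- function(config, topology, sib, long_branch, n_sites,
                          model, rep_index) {
  stopifnot(inherits(config, "grid_config"))
  if (!model %in% names(config$models))
    stop("unknown model setting '", model, "'", call. = FALSE)
  cell_id <- sprintf("topology %s, SiB %.10g, long %.10g, %d sites, %s, rep %d",
                     topology, sib, long_branch, n_sites, model, rep_index)
  seed <- replicate_seed(config$master_seed, topology, sib, long_branch,
                         n_sites, model, rep_index)
  rec <- tryCatch({
    true_tree <- if (topology == "A")
      build_topology_a(ltb = long_branch, sib = sib, rb = config$rb)
    else
      build_topology_b(lib = long_branch, sib = sib, rb = config$rb)
    spec <- topology_spec(topology)
    aln <- evolve_alignment(true_tree,
                            sim_params(n_sites, alpha = config$sim_alpha,
                                       p_inv = config$sim_p_inv, seed = seed))
    fit <- ml_search(aln, config$models[[model]])
    cls <- classify_tree(spec, true_tree, fit$tree)
    tibble::tibble(
      topology = topology, sib = sib, long_branch = long_branch,
      n_sites = as.integer(n_sites), model = model,
      rep_index = as.integer(rep_index), seed = seed,
      loglik = fit$loglik, alpha_hat = fit$alpha, p_inv_hat = fit$p_inv,
      n_rounds = fit$n_rounds, class = cls,
      inferred_newick = write_newick(fit$tree))
  }, error = function(e) {
    stop("replicate failed (", cell_id, "): ", conditionMessage(e),
         call. = FALSE)
  })
  rec
}

#' Run a grid of replicated cells
#'
#' Iterates all admissible cells times replicates. When `out_dir` is given,
#' records and summaries are written as TSV after every completed cell and
#' cells whose records are already present on disk are skipped on re-runs,
#' making long grids resumable; partially written cells (fewer records than
#' `n_replicates`) are detected and re-run.
#'
#' @param config A [grid_config()].
#' @param out_dir Optional output directory for `records.tsv` and
#'   `summary.tsv`.
#' @param progress Print one line per completed cell.
#' @return List of tibbles: `records` (one row per replicate) and
#'   `summaries` (one row per cell, see [summarize_replicates()]).
#' @export
run_grid <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  cells <- grid_cells(config)
  records_path <- if (!is.null(out_dir)) file.path(out_dir, "records.tsv")
  done <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.exists(records_path)) {
      done <- readr::read_tsv(records_path, show_col_types = FALSE)
      complete <- dplyr::filter(
        dplyr::count(done, .data$topology, .data$sib, .data$long_branch,
                     .data$n_sites, .data$model),
        .data$n == config$n_replicates)
      incomplete <- dplyr::anti_join(
        dplyr::distinct(done, .data$topology, .data$sib, .data$long_branch,
                        .data$n_sites, .data$model),
        complete,
        by = c("topology", "sib", "long_branch", "n_sites", "model"))
      if (nrow(incomplete) > 0)
        done <- dplyr::anti_join(
          done, incomplete,
          by = c("topology", "sib", "long_branch", "n_sites", "model"))
    }
  }
  all_records <- if (!is.null(done)) list(done) else list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (!is.null(done)) {
      prior <- dplyr::semi_join(
        done, cell, by = c("topology", "sib", "long_branch", "n_sites", "model"))
      if (nrow(prior) == config$n_replicates) {
        if (progress) message("cell ", i, "/", nrow(cells), ": cached")
        next
      }
    }
    recs <- purrr::map_dfr(seq_len(config$n_replicates), function(r)
      run_replicate(config, cell$topology, cell$sib, cell$long_branch,
                    cell$n_sites, cell$model, r))
    all_records <- c(all_records, list(recs))
    if (!is.null(out_dir)) {
      readr::write_tsv(recs, records_path,
                       append = file.exists(records_path))
    }
    if (progress)
      message("cell ", i, "/", nrow(cells), ": topology ", cell$topology,
              " SiB ", cell$sib, " long ", cell$long_branch, " n ",
              cell$n_sites, " ", cell$model, " done")
  }
  records <- dplyr::bind_rows(all_records)
  records <- dplyr::arrange(records, .data$topology, .data$sib,
                            .data$long_branch, .data$n_sites, .data$model,
                            .data$rep_index)
  summaries <- summarize_replicates(records)
  if (!is.null(out_dir)) {
    readr::write_tsv(records, records_path)
    readr::write_tsv(summaries, file.path(out_dir, "summary.tsv"))
  }
  list(records = records, summaries = summaries)
}

#' Summarize replicate records per grid cell
#'
#' Per-cell counts of every error class, the reconstruction-success
#' fraction, mean estimated rate parameters, and a dominance flag marking
#' cells where one artefact class holds a strict majority of replicates.
#'
#' @param records Tibble of replicate records from [run_replicate()] /
#'   [run_grid()].
#' @return A tibble (class `lba_summary`) with one row per cell.
#' @export
summarize_replicates <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no replicate records to summarize", call. = FALSE)
  stopifnot(all(records$class %in% error_classes()))
  out <- records |>
    dplyr::group_by(.data$topology, .data$sib, .data$long_branch,
                    .data$n_sites, .data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data$class == "correct"),
      n_class_I = sum(.data$class == "class_I"),
      n_class_II = sum(.data$class == "class_II"),
      n_class_III = sum(.data$class == "class_III"),
      n_other = sum(.data$class == "other"),
      success = mean(.data$class == "correct"),
      mean_alpha_hat = mean(.data$alpha_hat),
      mean_p_inv_hat = mean(.data$p_inv_hat),
      .groups = "drop")
  artefacts <- c("class_I", "class_II", "class_III")
  counts <- as.matrix(out[, paste0("n_", artefacts)])
  top <- max.col(counts, ties.method = "first")
  dominant <- counts[cbind(seq_len(nrow(out)), top)] > out$n / 2
  out$dominant_artefact <- ifelse(dominant, artefacts[top], NA_character_)
  class(out) <- c("lba_summary", class(out))
  out
}
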