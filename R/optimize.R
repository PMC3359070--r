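#' Branch-length and rate-parameter optimization, NNI tree search
#'
#' The engine optimizes each branch with Brent's bounded one-dimensional
#' method on a likelihood profile obtained by decomposing the tree at that
#' edge (partial likelihoods of the two half-trees are computed once; the
#' profile in the edge length is then closed-form cheap). Rate parameters
#' are optimized by the same line search in alternation with branch sweeps.
#'
#' @name optimizer
NULL

MIN_BL <- 1e-8
MAX_BL <- 20

# pruning likelihood for pre-compressed data / postorder arrays
lik_value <- function(pt, comp, rates, pinv, edge_len = pt$edge_len) {
  out <- cpp_pruning(pt$edge, edge_len, pt$ntip,
                     comp$tip_pat[pt$tip_order, , drop = FALSE],
                     rates, pinv, comp$const_state,
                     as.numeric(comp$weights))
  out$loglik
}

#' Optimize all branch lengths by round-robin Brent sweeps
#'
#' Sweeps every edge in postorder, maximizing the log-likelihood in that
#' edge's length (bounded to `[1e-8, 20]`), until a full sweep improves the
#' log-likelihood by less than `tol`. The log-likelihood never decreases
#' between sweeps.
#'
#' @inheritParams tree_log_likelihood
#' @param tol Sweep-improvement convergence tolerance (log-likelihood units).
#' @param max_sweeps Hard cap on sweeps.
#' @return List with the re-lengthed `tree` and a `lik_result`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model,
                                    alpha = NULL, p_inv = NULL,
                                    tol = 1e-6, max_sweeps = 50L) {
  comp <- compress_alignment(alignment)
  pt <- prep_tree(tree, rownames(alignment))
  rr <- model_rates(model, alpha, p_inv)
  pt <- optimize_bl_impl(pt, comp, rr$rates, rr$p_inv, tol, max_sweeps)
  res <- structure(
    list(loglik = attr(pt, "loglik"), site_loglik = NULL,
         alpha = if (model$asrv == "none") NA_real_ else
           if (!is.null(alpha)) alpha else model$alpha,
         p_inv = rr$p_inv),
    class = "lik_result")
  out_tree <- pt$tree
  out_tree$edge.length <- pt$edge_len
  list(tree = out_tree, result = res)
}

optimize_bl_impl <- function(pt, comp, rates, pinv, tol = 1e-6,
                             max_sweeps = 50L, opt_edges = integer(0)) {
  pt$edge_len <- pmin(pmax(pt$edge_len, MIN_BL), MAX_BL)
  out <- cpp_optimize_blens(pt$edge, pt$edge_len, pt$ntip,
                            comp$tip_pat[pt$tip_order, , drop = FALSE],
                            rates, pinv, comp$const_state,
                            as.numeric(comp$weights),
                            MIN_BL, MAX_BL, as.integer(max_sweeps), tol,
                            as.integer(opt_edges))
  pt$edge_len <- out$edge_len
  attr(pt, "loglik") <- out$loglik
  pt
}

#' Estimate gamma shape and invariant-sites proportion by ML
#'
#' Maximizes the log-likelihood over the parameters the model marks
#' `"estimate"` (`alpha` on `[0.01, 100]`, line-searched on the log scale;
#' `p_inv` on `[0, 0.99]`), alternating with branch-length sweeps until the
#' joint improvement falls below `tol`. Boundary solutions are returned as
#' such.
#'
#' @inheritParams tree_log_likelihood
#' @param tol Joint convergence tolerance (log-likelihood units).
#' @param optimize_bl If `FALSE`, branch lengths are held fixed.
#' @return List: `alpha`, `p_inv`, re-lengthed `tree`, and a `lik_result`.
#' @export
estimate_rate_parameters <- function(tree, alignment, model, tol = 1e-4,
                                     optimize_bl = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  if (!model$estimate_alpha && !model$estimate_p_inv)
    stop("model marks neither alpha nor p_inv as \"estimate\"", call. = FALSE)
  comp <- compress_alignment(alignment)
  pt <- prep_tree(tree, rownames(alignment))
  est <- estimate_params_impl(pt, comp, model, tol, optimize_bl)
  out_tree <- est$pt$tree
  out_tree$edge.length <- est$pt$edge_len
  list(alpha = est$alpha, p_inv = est$p_inv, tree = out_tree,
       result = structure(list(loglik = est$loglik, site_loglik = NULL,
                               alpha = est$alpha, p_inv = est$p_inv),
                          class = "lik_result"))
}

rates_for <- function(model, alpha, p_inv) {
  if (model$asrv == "none") return(list(rates = 1, p_inv = 0))
  r <- discrete_gamma_rates(alpha, model$n_categories)
  if (model$asrv == "gamma_inv") list(rates = r / (1 - p_inv), p_inv = p_inv)
  else list(rates = r, p_inv = 0)
}

estimate_params_impl <- function(pt, comp, model, tol = 1e-4,
                                 optimize_bl = TRUE, max_iter = 30L) {
  alpha <- if (model$estimate_alpha) 1.0 else model$alpha
  p_inv <- if (model$asrv != "gamma_inv") 0
           else if (model$estimate_p_inv) 0.2 else model$p_inv
  both <- model$estimate_alpha && model$estimate_p_inv &&
    model$asrv == "gamma_inv"
  rr <- rates_for(model, alpha, p_inv)
  ll <- lik_value(pt, comp, rr$rates, rr$p_inv)
  for (it in seq_len(max_iter)) {
    ll_before <- ll
    if (optimize_bl) {
      pt <- optimize_bl_impl(pt, comp, rr$rates, rr$p_inv, tol = tol)
      ll <- attr(pt, "loglik")
    }
    if (both) {
      # alpha and p_inv lie on a strong likelihood ridge; a joint
      # Nelder-Mead over (log alpha, p_inv) avoids the slow zig-zag of
      # coordinate-wise line searches
      f2 <- function(par) {
        if (par[1] < log(0.01) || par[1] > log(100) ||
            par[2] < 0 || par[2] > 0.99) return(1e10)
        rr2 <- rates_for(model, exp(par[1]), par[2])
        -lik_value(pt, comp, rr2$rates, rr2$p_inv)
      }
      opt <- stats::optim(c(log(alpha), p_inv), f2, method = "Nelder-Mead",
                          control = list(reltol = 1e-8, maxit = 200))
      if (-opt$value > ll) {
        alpha <- exp(opt$par[1])
        p_inv <- min(max(opt$par[2], 0), 0.99)
        ll <- -opt$value
      }
    } else {
      if (model$estimate_alpha) {
        f <- function(la) {
          rr2 <- rates_for(model, exp(la), p_inv)
          lik_value(pt, comp, rr2$rates, rr2$p_inv)
        }
        opt <- stats::optimize(f, log(c(0.01, 100)), maximum = TRUE,
                               tol = 1e-5)
        if (opt$objective > ll) {
          alpha <- exp(opt$maximum); ll <- opt$objective
        }
      }
      if (model$estimate_p_inv && model$asrv == "gamma_inv") {
        f <- function(pv) {
          rr2 <- rates_for(model, alpha, pv)
          lik_value(pt, comp, rr2$rates, rr2$p_inv)
        }
        opt <- stats::optimize(f, c(0, 0.99), maximum = TRUE, tol = 1e-6)
        if (opt$objective > ll) {
          p_inv <- opt$maximum; ll <- opt$objective
        }
      }
    }
    rr <- rates_for(model, alpha, p_inv)
    if (ll - ll_before < tol) break
  }
  list(alpha = if (model$asrv == "none") NA_real_ else alpha,
       p_inv = p_inv, pt = pt, loglik = ll)
}

# per-edge canonical split keys (NA for edges below tips)
edge_split_keys <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + po$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  keys <- rep(NA_character_, nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  labs <- po$tip.label
  for (k in seq_len(nrow(po$edge))) {
    ch <- po$edge[k, 2]
    if (ch > n) {
      side <- labs[below[[ch]]]
      if (length(side) > 1 && length(side) < n)
        keys[k] <- split_key(side, labs)
    }
  }
  list(tree = po, keys = keys)
}

# carry branch lengths from one topology to an NNI neighbor: shared splits
# and tip edges keep their lengths; the single new split inherits the
# length of the split it replaced
transfer_lengths <- function(from, to) {
  n <- length(from$tip.label)
  ef <- edge_split_keys(from)
  et <- edge_split_keys(to)
  tip_len <- numeric(n)
  for (k in seq_len(nrow(ef$tree$edge))) {
    ch <- ef$tree$edge[k, 2]
    if (ch <= n) tip_len[match(ef$tree$tip.label[ch], from$tip.label)] <-
        ef$tree$edge.length[k]
  }
  from_keys <- ef$keys[!is.na(ef$keys)]
  from_lens <- ef$tree$edge.length[!is.na(ef$keys)]
  lost <- setdiff(from_keys, et$keys[!is.na(et$keys)])
  lost_len <- if (length(lost)) from_lens[match(lost[1], from_keys)] else MIN_BL
  out <- et$tree
  new_key <- NA_character_
  el <- numeric(nrow(out$edge))
  for (k in seq_len(nrow(out$edge))) {
    ch <- out$edge[k, 2]
    if (ch <= n) {
      el[k] <- tip_len[match(out$tip.label[ch], from$tip.label)]
    } else if (is.na(et$keys[k])) {
      # root-adjacent internal edge with trivial split (unrooted storage)
      el[k] <- out$edge.length[k]
    } else {
      hit <- match(et$keys[k], from_keys)
      if (is.na(hit)) {
        el[k] <- lost_len
        new_key <- et$keys[k]
      } else el[k] <- from_lens[hit]
    }
  }
  out$edge.length <- pmin(pmax(el, MIN_BL), MAX_BL)
  list(tree = out, new_key = new_key)
}

#' Maximum-likelihood tree search (NJ start, NNI hill climbing)
#'
#' Starts from a neighbor-joining tree — on plain JC distances for a
#' homogeneous-rate model, otherwise on distances corrected for the
#' analysis model's rate heterogeneity ([model_distance_matrix()]; for
#' estimated parameters the JC-NJ tree is fitted first and the corrected
#' start rebuilt from the fitted values). The search then repeatedly
#' (1) optimizes branch lengths and any free rate parameters, (2) scores
#' every NNI neighbor of every internal edge with one optimization sweep
#' over the edges around the swap (re-optimizing the local neighborhood --
#' not just the move's central edge -- reveals improving moves even when
#' the current lengths are tuned to a wrong topology), and (3) moves to
#' the best neighbor if it improves the
#' log-likelihood by more than `tol`. Among equally improving neighbors the
#' one whose defining bipartition key is lexicographically smallest is
#' taken, making the search fully deterministic.
#'
#' @param alignment Character matrix (taxa x sites), >= 4 taxa.
#' @param model A [model_spec()]; parameters marked `"estimate"` are
#'   re-estimated in every round.
#' @param tol Minimum log-likelihood improvement to accept an NNI move.
#' @param max_rounds Hard cap on search rounds.
#' @return An object of class `ml_search_result`: `tree`, `loglik`,
#'   `alpha`, `p_inv`, `n_rounds`, `start_loglik`, `start_tree`.
#' @export
ml_search <- function(alignment, model, tol = 1e-4, max_rounds = 50L) {
  if (nrow(alignment) < 4) stop("need >= 4 taxa", call. = FALSE)
  comp <- compress_alignment(alignment)
  labels <- rownames(alignment)

  fit_current <- function(tree) {
    pt <- prep_tree(tree, labels)
    if (model$estimate_alpha || model$estimate_p_inv) {
      est <- estimate_params_impl(pt, comp, model)
      list(pt = est$pt, loglik = est$loglik, alpha = est$alpha,
           p_inv = est$p_inv)
    } else {
      rr <- model_rates(model)
      pt <- optimize_bl_impl(pt, comp, rr$rates, rr$p_inv, tol = 1e-4)
      list(pt = pt, loglik = attr(pt, "loglik"),
           alpha = if (model$asrv == "none") NA_real_ else model$alpha,
           p_inv = rr$p_inv)
    }
  }

  clamp_bl <- function(tree) {
    tree$edge.length <- pmin(pmax(tree$edge.length, MIN_BL), MAX_BL)
    tree
  }

  # starting tree: NJ on distances matching the analysis model; plain JC
  # distances are biased under ASRV and pull long branches together
  est_any <- model$estimate_alpha || model$estimate_p_inv
  if (model$asrv == "none") {
    start <- nj_tree(jc_distance_matrix(alignment))
    fit <- fit_current(clamp_bl(ape::unroot(start)))
  } else if (!est_any) {
    start <- nj_tree(model_distance_matrix(alignment, alpha = model$alpha,
                                           p_inv = model$p_inv))
    fit <- fit_current(clamp_bl(ape::unroot(start)))
  } else {
    # parameters unknown up front: fit the JC-NJ tree, then rebuild the
    # start from distances corrected with the fitted values
    start <- nj_tree(jc_distance_matrix(alignment))
    fit <- fit_current(clamp_bl(ape::unroot(start)))
    start2 <- nj_tree(model_distance_matrix(alignment, alpha = fit$alpha,
                                            p_inv = fit$p_inv))
    if (rf_distance(start2, fit$pt$tree) > 0) {
      fit2 <- fit_current(clamp_bl(ape::unroot(start2)))
      if (fit2$loglik > fit$loglik) {
        fit <- fit2
        start <- start2
      }
    }
  }
  cur <- fit$pt$tree; cur$edge.length <- fit$pt$edge_len
  start_ll <- fit$loglik
  ll <- start_ll
  n_rounds <- 0L
  repeat {
    n_rounds <- n_rounds + 1L
    rr <- rates_for(model, fit$alpha, fit$p_inv)
    # nni() returns a multiPhylo with a shared compressed TipLabel; expand
    # to plain phylo objects before iterating
    neighbors <- unclass(ape::.uncompressTipLabel(phangorn::nni(cur)))
    cand <- purrr::map(neighbors, function(nb) transfer_lengths(cur, nb))
    keys <- purrr::map_chr(cand, "new_key")
    ord <- order(keys)

    # score each neighbor with one optimization sweep restricted to the
    # edges around the swap (the rest carry lengths from the already
    # optimized current tree); re-optimizing the local edges -- not just
    # the move's central edge -- is what reveals improving moves when the
    # current lengths are tuned to a wrong topology
    best_ll <- -Inf; best <- NULL
    for (i in ord) {
      ptn <- prep_tree(cand[[i]]$tree, labels)
      ek <- edge_split_keys(ptn$tree)
      e_new <- which(ek$keys == keys[i])[1]
      local_e <- if (is.na(e_new)) integer(0) else {
        ends <- ptn$edge[e_new, ]
        which(ptn$edge[, 1] %in% ends | ptn$edge[, 2] %in% ends)
      }
      ptn <- optimize_bl_impl(ptn, comp, rr$rates, rr$p_inv,
                              tol = tol, max_sweeps = 1L,
                              opt_edges = local_e)
      ll_n <- attr(ptn, "loglik")
      if (ll_n > best_ll + 1e-12) {
        best_ll <- ll_n; best <- ptn
      }
    }
    sc <- list(ll = best_ll, ptn = best)
    if (is.null(sc$ptn) || sc$ll <= ll + tol || n_rounds >= max_rounds) break
    cur <- sc$ptn$tree; cur$edge.length <- sc$ptn$edge_len
    fit <- fit_current(cur)
    cur <- fit$pt$tree; cur$edge.length <- fit$pt$edge_len
    ll <- fit$loglik
  }
  structure(
    list(tree = cur, loglik = ll, alpha = fit$alpha, p_inv = fit$p_inv,
         n_rounds = n_rounds, start_loglik = start_ll, start_tree = start),
    class = "ml_search_result")
}

#' @export
print.ml_search_result <- function(x, ...) {
  cat("ML search result\n")
  cat("  log-likelihood:", format(x$loglik, digits = 12),
      " (start:", format(x$start_loglik, digits = 12), ")\n")
  if (!is.na(x$alpha)) cat("  alpha:", signif(x$alpha, 6), "\n")
  cat("  p_inv:", signif(x$p_inv, 6), "\n")
  cat("  NNI rounds:", x$n_rounds, "\n")
  cat("  tree:", write_newick(x$tree), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edges of a searched tree
#'
#' One row per edge of the maximum-likelihood tree: the canonical split key
#' (or the tip label for terminal edges) and the optimized length.
#'
#' @param x An `ml_search_result`.
#' @param ... Unused.
#' @return A tibble with columns `edge`, `type`, `length`.
#' @export
tidy.ml_search_result <- function(x, ...) {
  tr <- x$tree
  n <- length(tr$tip.label)
  ek <- edge_split_keys(tr)
  tibble::tibble(
    edge = ifelse(ek$tree$edge[, 2] <= n,
                  ek$tree$tip.label[pmin(ek$tree$edge[, 2], n)],
                  ek$keys),
    type = ifelse(ek$tree$edge[, 2] <= n, "terminal", "internal"),
    length = ek$tree$edge.length)
}

#' One-row summary of an ML search
#'
#' @param x An `ml_search_result`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `start_logLik`, `alpha`, `p_inv`,
#'   `n_rounds`.
#' @export
glance.ml_search_result <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, start_logLik = x$start_loglik,
                 alpha = x$alpha, p_inv = x$p_inv, n_rounds = x$n_rounds)
}
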