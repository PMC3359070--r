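#' Jukes-Cantor transition probability matrix
#'
#' @param edge_length Branch length in expected substitutions/site (>= 0).
#' @param rate Rate multiplier (>= 0).
#' @return A 4x4 stochastic matrix (rows = from, columns = to; order
#'   A, C, G, T): diagonal `1/4 + 3/4 exp(-4rt/3)`, off-diagonal
#'   `1/4 - 1/4 exp(-4rt/3)`.
#' @export
jc_transition <- function(edge_length, rate = 1) {
  stopifnot(edge_length >= 0, rate >= 0)
  e <- exp(-4 * rate * edge_length / 3)
  m <- matrix(0.25 * (1 - e), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- 0.25 + 0.75 * e
  m
}

#' Discrete-gamma rate categories
#'
#' Equal-probability categories whose rates are the means of the unit-mean
#' Gamma(`alpha`) density over consecutive inter-quantile intervals, so the
#' weighted mean rate is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param n_categories Number of categories (>= 1).
#' @return Numeric vector of category rates (equal weights `1/n`).
#' @export
discrete_gamma_rates <- function(alpha, n_categories = 4L) {
  stopifnot(alpha > 0, n_categories >= 1)
  k <- as.integer(n_categories)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean over [q_{i-1}, q_i] of the Gamma(alpha, alpha) density:
  # k * (F_{alpha+1}(q_i) - F_{alpha+1}(q_{i-1})), F at shape alpha + 1
  r <- k * diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
  r * k / sum(r)  # exact unit mean despite round-off
}

# rate multipliers + invariant proportion implied by a model spec
model_rates <- function(model, alpha = NULL, p_inv = NULL) {
  a <- if (!is.null(alpha)) alpha else model$alpha
  pv <- if (!is.null(p_inv)) p_inv else model$p_inv
  if (model$asrv == "none") return(list(rates = 1, p_inv = 0))
  if (is.na(a)) stop("alpha marked 'estimate' but no value supplied", call. = FALSE)
  r <- discrete_gamma_rates(a, model$n_categories)
  if (model$asrv == "gamma") return(list(rates = r, p_inv = 0))
  if (is.na(pv)) stop("p_inv marked 'estimate' but no value supplied", call. = FALSE)
  list(rates = r / (1 - pv), p_inv = pv)
}

# collapse alignment columns to weighted site patterns
compress_alignment <- function(alignment) {
  validate_alignment(alignment)
  codes <- matrix(match(alignment, c("A", "C", "G", "T")) - 1L,
                  nrow = nrow(alignment))
  rownames(codes) <- rownames(alignment)
  ntip <- nrow(codes)
  if (ntip <= 15L) {
    key <- as.vector(crossprod(codes, 4^(seq_len(ntip) - 1)))
  } else {
    key <- apply(codes, 2, paste, collapse = ",")
  }
  first <- which(!duplicated(key))
  idx <- match(key, key[first])
  pat <- codes[, first, drop = FALSE]
  cs <- pat[1, ]
  cs[colSums(pat != rep(cs, each = ntip)) > 0] <- -1L
  list(tip_pat = pat, weights = tabulate(idx, nbins = length(first)),
       const_state = as.integer(cs), site_pattern = idx)
}

# postorder edge arrays for the pruning core; tips indexed by `labels` order
prep_tree <- function(tree, labels) {
  if (!setequal(tree$tip.label, labels))
    stop("alignment taxa and tree leaves differ: only in tree: {",
         paste(setdiff(tree$tip.label, labels), collapse = ", "),
         "}, only in alignment: {",
         paste(setdiff(labels, tree$tip.label), collapse = ", "), "}",
         call. = FALSE)
  po <- ape::reorder.phylo(tree, "postorder")
  list(tree = po, edge = po$edge, edge_len = po$edge.length,
       ntip = length(po$tip.label),
       tip_order = match(po$tip.label, labels))
}

#' Tree log-likelihood under JC with a discrete-gamma(+I) mixture
#'
#' Felsenstein pruning with per-node rescaling. The per-site likelihood is
#' `p_inv * 1/4 * [site constant] + (1 - p_inv)/c * sum_k L_k`, where `L_k`
#' is the pruning likelihood at gamma-category rate `r_k / (1 - p_inv)` and
#' the root is weighted uniformly (1/4 per base).
#'
#' @param tree A `phylo` object with branch lengths; leaves must match the
#'   alignment's taxa.
#' @param alignment Character matrix (taxa x sites) over A/C/G/T.
#' @param model A [model_spec()].
#' @param alpha,p_inv Optional explicit values overriding the model's fixed
#'   values (required when the model marks them `"estimate"`).
#' @return An object of class `lik_result`: `loglik`, per-site `site_loglik`,
#'   and the `alpha`/`p_inv` used.
#' @export
tree_log_likelihood <- function(tree, alignment, model,
                                alpha = NULL, p_inv = NULL) {
  stopifnot(inherits(model, "model_spec"))
  comp <- compress_alignment(alignment)
  pt <- prep_tree(tree, rownames(alignment))
  rr <- model_rates(model, alpha, p_inv)
  out <- cpp_pruning(pt$edge, pt$edge_len, pt$ntip,
                     comp$tip_pat[pt$tip_order, , drop = FALSE],
                     rr$rates, rr$p_inv, comp$const_state,
                     as.numeric(comp$weights))
  structure(
    list(loglik = out$loglik,
         site_loglik = out$site_loglik[comp$site_pattern],
         alpha = if (model$asrv == "none") NA_real_ else
           if (!is.null(alpha)) alpha else model$alpha,
         p_inv = rr$p_inv),
    class = "lik_result")
}

#' @export
print.lik_result <- function(x, ...) {
  cat("log-likelihood:", format(x$loglik, digits = 12), "\n")
  if (!is.na(x$alpha)) cat("alpha:", x$alpha, " p_inv:", x$p_inv, "\n")
  invisible(x)
}

#' Brute-force log-likelihood by ancestral-state enumeration (test oracle)
#'
#' Sums the joint probability over all `4^m` assignments of states to the
#' `m` internal nodes, mixed over rate categories and the invariant class.
#' Exact-arithmetic equal to the pruning algorithm; refuses trees with more
#' than 8 internal nodes.
#'
#' @inheritParams tree_log_likelihood
#' @return Total log-likelihood (numeric scalar).
#' @export
brute_force_log_likelihood <- function(tree, alignment, model,
                                       alpha = NULL, p_inv = NULL) {
  comp_labels <- rownames(alignment)
  pt <- prep_tree(tree, comp_labels)
  ntip <- pt$ntip
  m <- pt$tree$Nnode
  if (m > 8L) stop("refusing brute-force enumeration for ", m,
                   " internal nodes (> 8)", call. = FALSE)
  rr <- model_rates(model, alpha, p_inv)
  rates <- rr$rates; pinv <- rr$p_inv; ncat <- length(rates)
  codes <- matrix(match(alignment, c("A", "C", "G", "T")),
                  nrow = nrow(alignment))
  codes <- codes[match(pt$tree$tip.label, comp_labels), , drop = FALSE]
  n_sites <- ncol(codes)
  root <- pt$edge[nrow(pt$edge), 1]
  assign_grid <- as.matrix(expand.grid(rep(list(1:4), m)))  # 4^m x m
  P_cat <- lapply(rates, function(r)
    lapply(seq_len(nrow(pt$edge)), function(e)
      jc_transition(pt$edge_len[e], r)))
  site_lik <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    state_of <- function(node) {
      if (node <= ntip) rep(codes[node, s], nrow(assign_grid))
      else assign_grid[, node - ntip]
    }
    mix <- 0
    for (k in seq_len(ncat)) {
      pr <- rep(0.25, nrow(assign_grid))  # root prior
      for (e in seq_len(nrow(pt$edge))) {
        P <- P_cat[[k]][[e]]
        pr <- pr * P[cbind(state_of(pt$edge[e, 1]), state_of(pt$edge[e, 2]))]
      }
      mix <- mix + sum(pr) / ncat
    }
    lik <- (1 - pinv) * mix
    if (pinv > 0 && all(codes[, s] == codes[1, s])) lik <- lik + pinv * 0.25
    site_lik[s] <- lik
  }
  sum(log(site_lik))
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' `d = -(3/4) log(1 - (4/3) p)` from the pairwise mismatch proportion
#' `p`; saturated pairs (`p >= 0.75`) are capped at distance 5.0 so that
#' neighbor joining stays defined.
#'
#' @param alignment Character matrix (taxa x sites).
#' @return Symmetric matrix with zero diagonal and the taxa as dimnames.
#' @export
jc_distance_matrix <- function(alignment) {
  n <- nrow(alignment)
  if (n < 2) stop("need >= 2 taxa", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(alignment[i, ] != alignment[j, ])
      d[i, j] <- d[j, i] <-
        if (p >= 0.75) 5.0 else -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Pairwise distances under JC with gamma(+invariant) site rates
#'
#' Inverts the expected-mismatch curve of the analysis model: with a
#' proportion `p_inv` of invariant sites and variable-site rates
#' Gamma(`alpha`, mean `1/(1 - p_inv)`), the expected mismatch at distance
#' `d` is `0.75 (1 - p_inv) (1 - (1 + 4d / (3 alpha (1 - p_inv)))^-alpha)`,
#' giving `d = (3/4) alpha (1 - p_inv) (ebar^(-1/alpha) - 1)` with
#' `ebar = 1 - p / (0.75 (1 - p_inv))`. Reduces to the plain JC distance as
#' `alpha` grows with `p_inv = 0`. Plain JC distances are systematically
#' biased under rate heterogeneity, which matters for distance-based
#' starting trees on saturated branches; this correction is consistent
#' under the generating model.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param alpha Gamma shape of the analysis model.
#' @param p_inv Invariant-sites proportion of the analysis model.
#' @param cap Distance assigned to saturated pairs (mismatch at or beyond
#'   its asymptote).
#' @return Symmetric matrix with zero diagonal.
#' @export
model_distance_matrix <- function(alignment, alpha, p_inv = 0, cap = 10) {
  stopifnot(alpha > 0, p_inv >= 0, p_inv < 1)
  n <- nrow(alignment)
  if (n < 2) stop("need >= 2 taxa", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  p_max <- 0.75 * (1 - p_inv)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(alignment[i, ] != alignment[j, ])
      dd <- if (p >= p_max * (1 - 1e-9)) cap else {
        ebar <- 1 - p / p_max
        min(0.75 * alpha * (1 - p_inv) * (ebar^(-1 / alpha) - 1), cap)
      }
      d[i, j] <- d[j, i] <- dd
    }
  }
  d
}

#' Neighbor-joining starting tree
#'
#' [ape::nj()] agglomeration with negative intermediate branch lengths
#' clamped to 0.
#'
#' @param dist_matrix Symmetric non-negative matrix with taxon dimnames.
#' @param labels Optional taxon labels overriding the dimnames.
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dist_matrix, labels = NULL) {
  if (!is.null(labels)) dimnames(dist_matrix) <- list(labels, labels)
  if (nrow(dist_matrix) < 3) stop("need >= 3 taxa for neighbor joining",
                                  call. = FALSE)
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-12 || any(dist_matrix < 0))
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)
  tr <- ape::nj(dist_matrix)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
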