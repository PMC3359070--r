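test_that("jc_transition matches its closed form", {
  expect_equal(jc_transition(0, 1), diag(4) * 1,
               ignore_attr = TRUE)
  expect_true(all(abs(jc_transition(1000, 1) - 0.25) < 1e-12))
  P <- jc_transition(0.1, 1)
  e <- exp(-4 * 0.1 / 3)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * e, 4), tolerance = 1e-12)
  expect_equal(P[1, 2], 0.25 - 0.25 * e, tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  # rate multiplier scales the exponent
  expect_equal(jc_transition(0.2, 0.5), jc_transition(0.1, 1))
})

test_that("discrete gamma categories have unit mean and analytic rates", {
  for (a in c(0.2, 1, 5, 100)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
  # alpha = 1: unit-mean exponential; interval mean over quartiles is
  # 4 * [(q0+1)e^-q0 - (q1+1)e^-q1], an independent analytic route
  q <- -log(1 - (0:4) / 4)
  g <- (q + 1) * exp(-q); g[5] <- 0
  expect_equal(discrete_gamma_rates(1, 4), 4 * (g[1:4] - g[2:5]),
               tolerance = 1e-6)
  # alpha = 100 approximates rate homogeneity; the four interval means of
  # Gamma(100) (sd 0.1) spread about +/- 0.13 around 1
  expect_true(all(abs(discrete_gamma_rates(100, 4) - 1) < 0.15))
  expect_lt(max(abs(discrete_gamma_rates(1000, 4) - 1)), 0.05)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(41)
  models <- fixed_model_settings()
  for (i in 1:12) {
    tr <- random_unrooted_tree(sample(4:6, 1))
    aln <- sim_fixture(tr, 30, seed = 1000 + i)
    m <- models[[((i - 1) %% length(models)) + 1]]
    ll <- tree_log_likelihood(tr, aln, m)
    expect_equal(ll$loglik, brute_force_log_likelihood(tr, aln, m),
                 tolerance = 1e-10)
    expect_equal(ll$loglik, sum(ll$site_loglik), tolerance = 1e-8)
  }
})

test_that("single constant column with zero branch lengths gives log(1/4)", {
  tr <- parse_newick("(a:0,b:0,(c:0,d:0):0);")
  aln <- matrix("A", 4, 1, dimnames = list(c("a", "b", "c", "d"), NULL))
  ll <- tree_log_likelihood(tr, aln, model_spec("none"))
  expect_equal(ll$loglik, log(0.25), tolerance = 1e-12)
})

test_that("two identical bases at divergence 0.75 match the closed form", {
  tr <- parse_newick("(a:0.375,b:0.375);")
  aln <- matrix("C", 2, 1, dimnames = list(c("a", "b"), NULL))
  got <- brute_force_log_likelihood(tr, aln, model_spec("none"))
  expect_equal(got, log(0.25 * (0.25 + 0.75 * exp(-1))), tolerance = 1e-12)
  expect_equal(tree_log_likelihood(tr, aln, model_spec("none"))$loglik, got,
               tolerance = 1e-10)
})

test_that("log-likelihood is invariant to the serialization root", {
  set.seed(43)
  tr <- random_unrooted_tree(7)
  aln <- sim_fixture(tr, 60, seed = 9)
  m <- model_spec("gamma_inv", alpha = 0.9, p_inv = 0.2)
  base <- tree_log_likelihood(tr, aln, m)$loglik
  for (node in c(1, 4)) {
    rerooted <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[node],
                                      resolve.root = TRUE))
    expect_equal(tree_log_likelihood(rerooted, aln, m)$loglik, base,
                 tolerance = 1e-8)
  }
})

test_that("gamma with alpha = 100 approximates the no-ASRV likelihood", {
  # checked in the small-branch-length-difference regime of the design
  tr <- build_topology_a(0.1, 0.1)
  aln <- sim_fixture(tr, 2000, seed = 10)
  l_none <- tree_log_likelihood(tr, aln, model_spec("none"))$loglik
  l_100 <- tree_log_likelihood(tr, aln, model_spec("gamma", alpha = 100))$loglik
  expect_lt(abs(l_100 - l_none) / abs(l_none), 0.001)
})

test_that("likelihood rejects taxon mismatches", {
  tr <- build_topology_a(0.5, 0.1)
  aln <- sim_fixture(tr, 50, seed = 11)
  rownames(aln)[1] <- "zz"
  expect_error(tree_log_likelihood(tr, aln, model_spec("none")), "zz")
})

test_that("branch-length optimization is monotone and recovers a divergence", {
  tr <- parse_newick("(a:0.15,b:0.15);")
  aln <- evolve_alignment(tr, sim_params(1e5, alpha = 1e6, p_inv = 0, seed = 12))
  # start far from the truth
  start <- parse_newick("(a:1.0,b:1.0);")
  m <- model_spec("none")
  before <- tree_log_likelihood(start, aln, m)$loglik
  fit <- optimize_branch_lengths(start, aln, m)
  expect_gte(fit$result$loglik, before)
  t_hat <- sum(fit$tree$edge.length)
  p <- 0.75 * (1 - exp(-0.4))
  se_d <- sqrt(p * (1 - p) / 1e5) / (1 - 4 * p / 3)  # delta method
  expect_lt(abs(t_hat - 0.3), 3 * se_d)
})

test_that("identical sequences drive branch lengths to the lower clamp", {
  row <- rep(c("A", "C", "G", "T"), length.out = 50)
  aln <- rbind(a = row, b = row, c = row)
  tr <- parse_newick("(a:0.1,b:0.1,c:0.1);")
  fit <- optimize_branch_lengths(tr, aln, model_spec("none"))
  expect_true(all(fit$tree$edge.length <= 1e-6))
})

test_that("rate-parameter estimation recovers and compensates as expected", {
  tr <- build_topology_a(0.5, 0.1)
  aln <- sim_fixture(tr, 20000, seed = 13)
  est <- estimate_rate_parameters(
    tr, aln, model_spec("gamma_inv", alpha = "estimate", p_inv = "estimate"))
  expect_lt(abs(est$alpha - 1.0), 0.25)
  expect_lt(abs(est$p_inv - 0.3), 0.06)
  # gamma-only fit to gamma+inv data compensates with a smaller shape
  est_g <- estimate_rate_parameters(tr, aln, model_spec("gamma", alpha = "estimate"))
  expect_lt(est_g$alpha, 1.0)
  # data without invariant sites yield a near-zero invariant estimate
  aln0 <- sim_fixture(tr, 5000, seed = 14, p_inv = 0)
  est0 <- estimate_rate_parameters(
    tr, aln0, model_spec("gamma_inv", alpha = "estimate", p_inv = "estimate"))
  expect_lte(est0$p_inv, 0.05)
})

test_that("jc distances follow the closed form and cap at saturation", {
  aln <- rbind(a = rep(c("A", "C"), 10), b = rep(c("A", "G"), 10))
  # p = 0.5
  d <- jc_distance_matrix(aln)
  expect_equal(d["a", "b"], -0.75 * log(1 - 2 / 3), tolerance = 1e-9)
  expect_equal(d["a", "b"], 0.8239592, tolerance = 1e-6)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_identical(d, t(d))
  # saturated pair capped
  aln2 <- rbind(a = rep("A", 20), b = rep("C", 20))
  expect_equal(jc_distance_matrix(aln2)["a", "b"], 5.0)
})

test_that("neighbor joining recovers additive trees and permutes labels", {
  tr <- parse_newick("((a:0.2,b:0.3):0.15,(c:0.25,d:0.1):0.2,e:0.4);")
  D <- ape::cophenetic.phylo(tr)
  nj1 <- nj_tree(D)
  expect_identical(rf_distance(nj1, tr), 0L)
  perm <- sample(rownames(D))
  nj2 <- nj_tree(D[perm, perm])
  expect_identical(rf_distance(nj2, tr), 0L)
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
  expect_true(all(nj_tree(D)$edge.length >= 0))
})

test_that("ml_search matches exhaustive evaluation on four taxa", {
  set.seed(47)
  tr <- parse_newick("((a:0.3,b:0.05):0.08,(c:0.3,d:0.05):0.08);")
  m <- model_spec("gamma_inv", alpha = 1, p_inv = 0.3)
  for (rep in 1:3) {
    aln <- sim_fixture(tr, 800, seed = 500 + rep)
    fit <- ml_search(aln, m)
    expect_gte(fit$loglik, fit$start_loglik)
    # exhaustive oracle over the 3 unrooted quartet topologies
    quartets <- list("((a:.1,b:.1):.1,(c:.1,d:.1):.1);",
                     "((a:.1,c:.1):.1,(b:.1,d:.1):.1);",
                     "((a:.1,d:.1):.1,(b:.1,c:.1):.1);")
    lls <- vapply(quartets, function(q) {
      optimize_branch_lengths(parse_newick(q), aln, m)$result$loglik
    }, numeric(1))
    expect_equal(fit$loglik, max(lls), tolerance = 1e-4)
    best_q <- parse_newick(quartets[[which.max(lls)]])
    expect_identical(rf_distance(fit$tree, best_q), 0L)
  }
})

test_that("search results expose tidy and glance methods", {
  tr <- build_topology_a(0.3, 0.1)
  aln <- sim_fixture(tr, 500, seed = 15)
  fit <- ml_search(aln, model_spec("gamma_inv", alpha = 1, p_inv = 0.3))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), nrow(fit$tree$edge))
  expect_true(all(c("edge", "type", "length") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$logLik, fit$loglik)
  expect_gte(gl$logLik, gl$start_logLik)
})

test_that("the search recovers easy cells in nearly all replicates", {
  # well-separated regime: equal moderate internal branches, true model
  tr <- build_topology_b(lib = 0.3, sib = 0.3)
  m <- model_spec("gamma_inv", alpha = 1, p_inv = 0.3)
  hits <- vapply(1:20, function(r) {
    aln <- sim_fixture(tr, 10000, seed = 600 + r)
    rf_distance(ml_search(aln, m)$tree, tr) == 0L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
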