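# shared fixtures: random trees and tiny simulated alignments

random_unrooted_tree <- function(n, labels = paste0("t", seq_len(n)),
                                 min_bl = 0.05, max_bl = 0.8) {
  tr <- ape::unroot(ape::rtree(n, tip.label = sample(labels)))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# alignment whose generating conditions match the study defaults unless
# overridden
sim_fixture <- function(tree, n_sites, seed, alpha = 1.0, p_inv = 0.3) {
  evolve_alignment(tree, sim_params(n_sites, alpha = alpha, p_inv = p_inv,
                                    seed = seed))
}

all_model_settings <- function() standard_model_settings()

# fixed-parameter variants usable for direct likelihood evaluation
fixed_model_settings <- function() {
  list(
    no_asrv        = model_spec("gamma", alpha = 100),
    gamma_inv_true = model_spec("gamma_inv", alpha = 1.0, p_inv = 0.3),
    gamma_inv_alt  = model_spec("gamma_inv", alpha = 0.6, p_inv = 0.15),
    gamma_alt      = model_spec("gamma", alpha = 0.8))
}
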