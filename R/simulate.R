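#' Synthetic sequence evolution under JC + continuous gamma + invariant sites
#'
#' The generator mirrors the statistical structure the downstream analysis
#' assumes: each site is independently invariant (rate exactly 0) with
#' probability `p_inv`, otherwise its rate multiplier is drawn from a
#' continuous Gamma(shape = alpha, mean 1) distribution rescaled by
#' `1/(1 - p_inv)` so that the expected rate over *all* sites is 1 and
#' branch lengths read as expected substitutions per site overall.
#' Sequences then evolve site-independently down the tree under
#' Jukes-Cantor. No indels are generated; alignments are gap-free.
#'
#' @name simulator
NULL

#' Simulation parameters
#'
#' @param n_sites Number of alignment columns (>= 1).
#' @param alpha Gamma shape of the continuous site-rate distribution (> 0).
#' @param p_inv Proportion of invariant sites in `[0, 1]`.
#' @param seed Optional integer seed; if supplied, [draw_site_rates()] and
#'   [evolve_alignment()] are fully deterministic.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_sites, alpha = 1.0, p_inv = 0.3, seed = NULL) {
  stopifnot(is.numeric(n_sites), n_sites >= 1,
            is.numeric(alpha), alpha > 0,
            is.numeric(p_inv), p_inv >= 0, p_inv <= 1)
  structure(list(n_sites = as.integer(n_sites), alpha = alpha,
                 p_inv = p_inv, seed = seed),
            class = "sim_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw per-site rate multipliers
#'
#' A site is invariant (rate exactly 0) with probability `p_inv`; otherwise
#' its rate is Gamma(alpha, mean 1) / (1 - p_inv), so the mean rate over
#' all sites is 1 in expectation.
#'
#' @param params A [sim_params()] object.
#' @return Numeric vector of length `n_sites`; zero entries mark invariant
#'   sites.
#' @export
draw_site_rates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, draw_site_rates_impl(params))
}

draw_site_rates_impl <- function(params) {
  n <- params$n_sites
  inv <- stats::runif(n) < params$p_inv
  rates <- numeric(n)
  n_var <- sum(!inv)
  if (n_var > 0) {
    scale <- if (params$p_inv < 1) 1 / (1 - params$p_inv) else 1
    rates[!inv] <- stats::rgamma(n_var, shape = params$alpha,
                                 rate = params$alpha) * scale
  }
  rates
}

#' Evolve a gap-free DNA alignment along a tree
#'
#' The root sequence is uniform over {A,C,G,T}; each site evolves
#' independently along each edge with Jukes-Cantor transition probabilities
#' at the site's rate multiplier: along an edge of length `t` at rate `r`
#' the base is retained with probability `1/4 + (3/4) exp(-4rt/3)` and
#' changes to each alternative with probability `1/4 - (1/4) exp(-4rt/3)`.
#' Invariant sites (rate 0) are identical across all taxa. The simulation
#' root is the tree's serialization root; under the reversible JC model the
#' sampling distribution does not depend on this choice.
#'
#' @param tree A `phylo` object with >= 2 leaves and branch lengths.
#' @param params A [sim_params()] object.
#' @return A character matrix (taxa x sites) over A/C/G/T with rownames the
#'   leaf labels, carrying the drawn rate vector as attribute
#'   `"site_rates"`.
#' @export
evolve_alignment <- function(tree, params) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2,
            !is.null(tree$edge.length), inherits(params, "sim_params"))
  with_seed(params$seed, {
    rates <- draw_site_rates_impl(params)
    evolve_alignment_impl(tree, rates)
  })
}

evolve_alignment_impl <- function(tree, rates) {
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_sites <- length(rates)
  pr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  root <- pr$edge[1, 1]
  seqs <- matrix(0L, nrow = n_node, ncol = n_sites)
  seqs[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (k in seq_len(nrow(pr$edge))) {
    parent <- pr$edge[k, 1]; child <- pr$edge[k, 2]
    t_edge <- pr$edge.length[k]
    p_change <- 0.75 * (1 - exp(-4 * rates * t_edge / 3))
    s <- seqs[parent, ]
    mut <- stats::runif(n_sites) < p_change
    n_mut <- sum(mut)
    if (n_mut > 0) {
      # pick uniformly among the 3 alternative bases
      shift <- sample.int(3L, n_mut, replace = TRUE)
      s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
    }
    seqs[child, ] <- s
  }
  out <- matrix(bases[seqs[seq_len(n_tip), , drop = FALSE]],
                nrow = n_tip, ncol = n_sites)
  rownames(out) <- tree$tip.label
  attr(out, "site_rates") <- rates
  out
}

validate_alignment <- function(mat, what = "alignment") {
  if (!is.matrix(mat) || !is.character(mat))
    stop(what, " must be a character matrix", call. = FALSE)
  bad <- which(matrix(!(mat %in% c("A", "C", "G", "T")), nrow(mat)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(what, ": invalid symbol '", mat[bad[1, 1], bad[1, 2]], "' in row ",
         bad[1, 1], " (", rownames(mat)[bad[1, 1]], "), column ", bad[1, 2],
         call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop(what, ": taxon labels must be present and unique", call. = FALSE)
  invisible(mat)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param alignment Character matrix (taxa x sites) over A/C/G/T.
#' @param file Output path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `file`, invisibly.
#' @export
write_alignment <- function(alignment, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  validate_alignment(alignment)
  seqs <- apply(alignment, 1, paste, collapse = "")
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", names(seqs)), seqs))
  } else {
    c(paste(nrow(alignment), ncol(alignment)),
      paste(names(seqs), seqs))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' Strict: rows must have equal length, symbols must be A/C/G/T (case
#' insensitive on input), taxon names must be unique, and a PHYLIP header
#' must match the matrix dimensions. Violations raise errors naming the
#' offending row/column.
#'
#' @param file Input path.
#' @param format `"fasta"` or `"phylip"`.
#' @return Character matrix (taxa x sites).
#' @export
read_alignment <- function(file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- ape::read.FASTA(file)
    if (anyDuplicated(names(x)))
      stop("duplicate FASTA header(s): ",
           paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
           call. = FALSE)
    lens <- lengths(x)
    if (length(unique(lens)) > 1)
      stop("unequal sequence lengths: row ", which(lens != lens[1])[1], " (",
           names(x)[which(lens != lens[1])[1]], ") has ",
           lens[which(lens != lens[1])[1]], " sites, expected ", lens[1],
           call. = FALSE)
    mat <- toupper(as.character(as.matrix(x)))
  } else {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
    if (length(hdr) != 2)
      stop("malformed PHYLIP header: ", lines[1], call. = FALSE)
    body <- strsplit(trimws(lines[-1]), "\\s+")
    if (length(body) != hdr[1])
      stop("PHYLIP header declares ", hdr[1], " taxa but file has ",
           length(body), call. = FALSE)
    nm <- vapply(body, `[[`, "", 1L)
    sq <- vapply(body, function(b) paste(b[-1], collapse = ""), "")
    if (any(nchar(sq) != hdr[2])) {
      i <- which(nchar(sq) != hdr[2])[1]
      stop("PHYLIP row ", i, " (", nm[i], ") has ", nchar(sq[i]),
           " sites, header declares ", hdr[2], call. = FALSE)
    }
    mat <- t(vapply(sq, function(s) strsplit(toupper(s), "")[[1]],
                    character(hdr[2])))
    rownames(mat) <- nm
  }
  validate_alignment(mat, what = basename(file))
}

#' Export a site-rate vector as TSV
#'
#' @param rates Numeric vector from [draw_site_rates()].
#' @param file Output path.
#' @export
write_site_rates <- function(rates, file) {
  readr::write_tsv(tibble::tibble(site = seq_along(rates), rate = rates), file)
  invisible(file)
}
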