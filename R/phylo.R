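# JTT-model phylogenetics: pairwise maximum-likelihood distances,
# neighbor-joining reconstruction with non-negative branch lengths,
# column-bootstrap supports with low-support collapse, and fixed-topology
# log-likelihood by Felsenstein pruning.

#' The JTT amino-acid substitution model
#'
#' Builds the reversible rate matrix Q from the Jones-Taylor-Thornton (1992)
#' exchangeabilities and equilibrium frequencies, `Q[i,j] = s[i,j] * pi[j]`
#' for `i != j`, rows summing to zero, scaled so the expected replacement
#' rate at equilibrium is one substitution per site per unit time.  The
#' spectral decomposition of the similarity-transformed (symmetric) matrix
#' is precomputed so that `P(t) = exp(Qt)` is a pair of matrix products.
#'
#' @return an object of class `aa_model` with elements `alphabet`, `s`
#'   (symmetric exchangeabilities), `pi`, `Q`, and the eigendecomposition.
#' @export
jtt_model <- function() {
  k <- 20L
  s <- matrix(0, k, k, dimnames = list(.aa_order, .aa_order))
  s[lower.tri(s)] <- .jtt_lower
  s <- s + t(s)
  pi <- .jtt_freq
  names(pi) <- .aa_order
  Q <- s * rep(pi, each = k)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # B = D^{1/2} Q D^{-1/2} is symmetric for a reversible Q
  rp <- sqrt(pi)
  B <- Q * (rp %o% (1 / rp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(alphabet = .aa_order, s = s, pi = pi, Q = Q,
                 values = eig$values,
                 left = (1 / rp) * eig$vectors,     # D^{-1/2} V
                 right = t(eig$vectors * rp)),      # V' D^{1/2}
            class = "aa_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model an `aa_model` from [jtt_model()].
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return a 20 x 20 stochastic matrix.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$left %*% (exp(model$values * t) * model$right)
  P[P < 0] <- 0
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

.aa_index <- function(x, alphabet) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  i <- match(x, alphabet)
  if (anyNA(i))
    stop("sequence contains symbols outside the 20-letter alphabet: ",
         paste(unique(x[is.na(i)]), collapse = ", "),
         " (apply complete_deletion first)")
  i
}

#' Maximum-likelihood pairwise distance under the JTT model
#'
#' Maximises the pairwise likelihood
#' `sum_k log(pi[a_k] * P[a_k, b_k](t))` over `t` in `[1e-6, 10]` by bounded
#' scalar optimisation (absolute tolerance `1e-6`).  Identical sequences
#' return the lower bound.  If the optimum sits against the upper bound the
#' returned value carries `attr(., "saturated") = TRUE` instead of failing.
#'
#' @param a,b equal-length gap-free amino-acid sequences (strings or
#'   character vectors).
#' @param model an `aa_model`; defaults to [jtt_model()].
#' @return the ML distance in substitutions/site, with attribute `saturated`.
#' @export
jtt_distance <- function(a, b, model = jtt_model()) {
  ia <- .aa_index(a, model$alphabet)
  ib <- .aa_index(b, model$alphabet)
  if (length(ia) != length(ib)) stop("sequences differ in length")
  lower <- 1e-6; upper <- 10
  if (all(ia == ib))
    return(structure(lower, saturated = FALSE))
  counts <- matrix(0, 20L, 20L)
  tab <- table(factor(ia, levels = 1:20), factor(ib, levels = 1:20))
  counts[] <- tab
  lpi <- log(model$pi)
  ll <- function(t) {
    P <- model$left %*% (exp(model$values * t) * model$right)
    P[P < 1e-300] <- 1e-300
    sum(counts * (lpi + log(P)))
  }
  opt <- stats::optimize(ll, c(lower, upper), maximum = TRUE, tol = 1e-6)
  d <- opt$maximum
  sat <- d > upper - 1e-3
  structure(if (d < lower + 1e-8) lower else d, saturated = sat)
}

#' Pairwise JTT distance matrix for an alignment
#'
#' @param aln a gap-free [msa] (apply [complete_deletion()] first).
#' @param model an `aa_model`.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal and a
#'   logical `saturated` attribute marking pairs whose optimum hit the upper
#'   search bound.
#' @export
jtt_dist_matrix <- function(aln, model = jtt_model()) {
  stopifnot(inherits(aln, "msa"))
  n <- nrow(aln)
  ids <- rownames(aln)
  idx <- lapply(seq_len(n), function(i) .aa_index(aln[i, ], model$alphabet))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- jtt_distance(aln[i, ], aln[j, ], model)
    D[i, j] <- D[j, i] <- as.numeric(d)
    sat[i, j] <- sat[j, i] <- attr(d, "saturated")
  }
  structure(D, class = c("dist_matrix", "matrix"), saturated = sat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}).  Negative intermediate
#' branch lengths are clamped to zero; the total clamped deficit is attached
#' as attribute `clamped_deficit`.
#'
#' @param D a symmetric distance matrix with ids as dimnames (at least 3
#'   taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) < 3L)
    stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(D)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  if (deficit > 0) {
    message(sprintf("nj_tree: clamped negative branch lengths (total %.3g)",
                    deficit))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Bootstrap supports with low-support collapse
#'
#' Alignment columns are resampled with replacement; replicate `r` uses RNG
#' seed `seed + r` so results are independent of execution order.  The
#' support of each internal branch of the full-data NJ tree is the percent
#' of replicate NJ trees containing the same bipartition; branches below
#' `collapse` percent are contracted to polytomies.
#'
#' @param aln a gap-free [msa] (complete deletion applied).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer master seed.
#' @param model an `aa_model`.
#' @param collapse support threshold in percent below which internal
#'   branches are collapsed (default 50); `NULL` disables collapsing.
#' @return an `ape::phylo` with integer percent supports in `node.label`.
#' @export
bootstrap_supports <- function(aln, n_reps, seed, model = jtt_model(),
                               collapse = 50) {
  stopifnot(inherits(aln, "msa"), n_reps >= 1L)
  if (nrow(aln) < 3L) stop("bootstrap needs at least 3 taxa")
  ref <- nj_tree(jtt_dist_matrix(aln, model))
  boot <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    rep_aln <- msa(unclass(aln)[, cols, drop = FALSE],
                   type = attr(aln, "type"))
    boot[[r]] <- nj_tree(jtt_dist_matrix(rep_aln, model))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- as.integer(round(100 * counts / n_reps))
  # the basal node of an unrooted tree is not a bipartition; full support
  sup[1L] <- 100L
  ref$node.label <- sup
  if (!is.null(collapse)) ref <- collapse_low_support(ref, collapse)
  ref
}

#' Collapse internal branches below a support threshold
#'
#' @param tree an `ape::phylo` with numeric `node.label` supports.
#' @param threshold branches with support strictly below this percent are
#'   contracted to polytomies.
#' @return the collapsed tree.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  repeat {
    nt <- length(tree$tip.label)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    child <- tree$edge[, 2L]
    internal <- child > nt
    supc <- rep(NA_real_, length(child))
    supc[internal] <- sup[child[internal] - nt]
    bad <- which(!is.na(supc) & supc < threshold & child != nt + 1L)
    if (length(bad) == 0L) break
    tree <- .contract_edge(tree, bad[1L])
  }
  tree
}

# Contract edge e (whose child is an internal node): the child's outgoing
# edges are reattached to its parent and the node removed.
.contract_edge <- function(tree, e) {
  nt <- length(tree$tip.label)
  v <- tree$edge[e, 2L]
  u <- tree$edge[e, 1L]
  keep <- setdiff(seq_len(nrow(tree$edge)), e)
  edge <- tree$edge[keep, , drop = FALSE]
  len <- tree$edge.length[keep]
  edge[edge[, 1L] == v, 1L] <- u
  # renumber internal nodes above v down by one
  edge[edge > v] <- edge[edge > v] - 1L
  lab <- tree$node.label[-(v - nt)]
  structure(list(edge = edge, edge.length = len,
                 tip.label = tree$tip.label, Nnode = tree$Nnode - 1L,
                 node.label = lab),
            class = "phylo", order = NULL)
}

#' Fixed-topology log-likelihood under the JTT model
#'
#' Felsenstein pruning with transition matrices from the spectral
#' decomposition of the reversible Q; per-site log-likelihoods are summed.
#' Duplicate site patterns are aggregated for speed.  By reversibility the
#' value is invariant to root placement.
#'
#' @param tree an `ape::phylo` whose tip labels are exactly the alignment
#'   ids, with non-negative branch lengths.
#' @param aln a gap-free [msa].
#' @param model an `aa_model`.
#' @return the log-likelihood (a scalar).
#' @export
tree_loglik <- function(tree, aln, model = jtt_model()) {
  stopifnot(inherits(aln, "msa"))
  if (!setequal(tree$tip.label, rownames(aln)) ||
      length(tree$tip.label) != nrow(aln))
    stop("tree tip labels and alignment ids do not match")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  idx <- matrix(match(unclass(aln), model$alphabet), nrow = nrow(aln),
                dimnames = list(rownames(aln), NULL))
  if (anyNA(idx))
    stop("alignment contains symbols outside the 20-letter alphabet",
         " (apply complete_deletion first)")
  pat_key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(pat_key)
  w <- as.vector(table(factor(pat_key, levels = pat_key[first])))
  pat <- idx[, first, drop = FALSE]
  np <- ncol(pat)
  tr <- stats::reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  partial <- vector("list", nn)
  logscale <- numeric(np)
  for (i in seq_len(nt)) {
    L <- matrix(0, 20L, np)
    L[cbind(pat[tr$tip.label[i], ], seq_len(np))] <- 1
    partial[[i]] <- L
  }
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]; pa <- tr$edge[e, 1L]
    P <- prob_matrix(model, tr$edge.length[e])
    contrib <- P %*% partial[[ch]]
    if (is.null(partial[[pa]])) partial[[pa]] <- contrib
    else partial[[pa]] <- partial[[pa]] * contrib
    mx <- apply(partial[[pa]], 2L, max)
    if (any(mx < 1e-200)) mx[mx < 1e-200] <- 1e-200
    partial[[pa]] <- sweep(partial[[pa]], 2L, mx, "/")
    logscale <- logscale + log(mx)
  }
  root <- tr$edge[nrow(tr$edge), 1L]
  site <- colSums(model$pi * partial[[root]])
  sum(w * (log(site) + logscale))
}

#' Write a distance matrix to TSV
#' @param D a `dist_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), unclass(D), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
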