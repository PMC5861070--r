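# Codon-alignment simulator: a paralogue family evolved along a clade tree
# under a GY94-style model (kappa = 1, uniform sense-codon frequencies) with
# domain-specific dN/dS, an injected basic NLS motif whose core is lost
# (R -> W) in one designated monophyletic subclade, and injected gap
# columns.  The generator's outputs are exactly the pipeline's inputs.

#' Simulation configuration
#'
#' Defaults emulate the study conditions this package is validated under: a
#' 16-taxon mammal-like clade, a strongly conserved pro domain
#' (`omega_pro = 0.1`) and a moderately conserved mature domain
#' (`omega_mature = 0.6`) of 200 codons each, mean root-to-tip divergence
#' 0.3 substitutions/site, a KKRR motif at pro position 70 (lost as KKWR in
#' a 4-taxon subclade, mirroring the toothed-whale scenario), and a 5
#' percent rate of gap-bearing columns.
#'
#' @param n_taxa number of taxa (ignored when `tree` is supplied).
#' @param tree optional `ape::phylo` or Newick string with branch lengths;
#'   `NULL` simulates a Yule tree rescaled to `depth`.
#' @param pro_codons,mature_codons domain lengths in codons.
#' @param omega_pro,omega_mature dN/dS of each domain (> 0).
#' @param depth mean root-to-tip length in expected substitutions per codon
#'   site (random trees only).
#' @param motif_core amino-acid core inserted in the pro domain.
#' @param motif_pos 1-based pro-domain position of the motif core.
#' @param loss_clade `"auto"` (pick the subclade whose size is closest to
#'   `loss_size`), a character vector of taxa (must be monophyletic), or
#'   `NULL` for no loss.
#' @param loss_size target clade size for `"auto"`.
#' @param gap_rate per-column probability of gap injection.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 16L, tree = NULL,
                       pro_codons = 200L, mature_codons = 200L,
                       omega_pro = 0.1, omega_mature = 0.6,
                       depth = 0.3,
                       motif_core = "KKRR", motif_pos = 70L,
                       loss_clade = "auto", loss_size = 4L,
                       gap_rate = 0.05, seed = 1L) {
  stopifnot(omega_pro > 0, omega_mature > 0,
            pro_codons >= 1L, mature_codons >= 1L,
            gap_rate >= 0, gap_rate < 1)
  if (!is.null(motif_core) &&
      motif_pos + nchar(motif_core) - 1L > pro_codons)
    stop("motif does not fit inside the pro domain")
  structure(list(n_taxa = as.integer(n_taxa), tree = tree,
                 pro_codons = as.integer(pro_codons),
                 mature_codons = as.integer(mature_codons),
                 omega_pro = omega_pro, omega_mature = omega_mature,
                 depth = depth, motif_core = motif_core,
                 motif_pos = as.integer(motif_pos),
                 loss_clade = loss_clade, loss_size = as.integer(loss_size),
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# 61 x 61 GY94 rate matrix (kappa = 1, uniform codon frequencies), scaled
# to one expected substitution per codon site; returns its symmetric
# eigendecomposition.
.codon_model <- function(omega) {
  sc <- .sense_codons
  k <- length(sc)
  nts <- do.call(rbind, strsplit(sc, ""))
  aa <- unname(.genetic_code[sc])
  Q <- matrix(0, k, k, dimnames = list(sc, sc))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    nd <- sum(nts[i, ] != nts[j, ])
    if (nd != 1L) next
    Q[i, j] <- if (aa[i] == aa[j]) 1 else omega
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / mean(-diag(Q))          # uniform frequencies
  eig <- eigen(Q, symmetric = TRUE)  # Q is symmetric under this model
  list(codons = sc, values = eig$values, vectors = eig$vectors)
}

.codon_prob <- function(cm, t) {
  P <- cm$vectors %*% (exp(cm$values * t) * t(cm$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# evolve integer codon states one branch; states grouped by parent value
.evolve <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    sel <- states == s
    out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a codon-alignment family with known ground truth
#'
#' Codon states evolve along the tree under the GY94-style model with the
#' configured per-domain omega; the NLS motif core is written over the
#' simulated codons afterwards (with the R -> W replacement in the loss
#' clade), so the motif contrast is deterministic; whole alignment columns
#' then receive gaps in a random subset of taxa (never inside the motif).
#'
#' @param config a [sim_config()].
#' @return object of class `il1_family_sim` with elements `proteins` (AA
#'   [msa]), `cds` (DNA [msa]), `metadata`, `partition` and `truth`
#'   (generating tree, per-domain omega, per-taxon motif status, seed).
#' @export
simulate_family <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # --- tree ---
  if (is.null(config$tree)) {
    tr <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    dep <- ape::node.depth.edgelength(tr)[seq_len(config$n_taxa)]
    tr$edge.length <- tr$edge.length * config$depth / mean(dep)
  } else {
    tr <- if (inherits(config$tree, "phylo")) config$tree
          else ape::read.tree(text = config$tree)
    if (is.null(tr$edge.length)) stop("supplied tree has no branch lengths")
  }
  nt <- length(tr$tip.label)
  # --- loss clade ---
  loss_taxa <- character()
  if (!is.null(config$loss_clade) && !is.null(config$motif_core)) {
    if (identical(config$loss_clade, "auto")) {
      clades <- ape::prop.part(tr)
      sizes <- lengths(clades)
      ok <- which(sizes < nt)
      pick <- ok[which.min(abs(sizes[ok] - config$loss_size))]
      loss_taxa <- tr$tip.label[clades[[pick]]]
    } else {
      loss_taxa <- config$loss_clade
      if (!all(loss_taxa %in% tr$tip.label))
        stop("loss_clade contains unknown taxa")
      if (length(loss_taxa) > 1L &&
          !ape::is.monophyletic(tr, loss_taxa))
        stop("loss_clade is not monophyletic in the tree; ",
             "the scenario assumes a single ancestral loss")
    }
  }
  # --- evolve codons ---
  n_pro <- config$pro_codons; n_mat <- config$mature_codons
  L <- n_pro + n_mat
  dom_id <- c(rep(1L, n_pro), rep(2L, n_mat))
  cms <- list(.codon_model(config$omega_pro),
              .codon_model(config$omega_mature))
  k <- length(.sense_codons)
  tro <- stats::reorder(tr, "cladewise")
  nn <- nt + tro$Nnode
  states <- matrix(NA_integer_, nn, L)
  root <- nt + 1L
  states[root, ] <- sample.int(k, L, replace = TRUE)
  for (e in seq_len(nrow(tro$edge))) {
    pa <- tro$edge[e, 1L]; ch <- tro$edge[e, 2L]
    t <- tro$edge.length[e]
    for (d in 1:2) {
      P <- .codon_prob(cms[[d]], t)
      sel <- dom_id == d
      states[ch, sel] <- .evolve(states[pa, sel], P)
    }
  }
  tip_states <- states[seq_len(nt), , drop = FALSE]
  rownames(tip_states) <- tro$tip.label
  codons <- matrix(.sense_codons[tip_states], nt, L,
                   dimnames = list(tro$tip.label, NULL))
  # --- motif overwrite ---
  motif_cols <- integer(); core_cols <- integer()
  if (!is.null(config$motif_core)) {
    core <- strsplit(config$motif_core, "")[[1]]
    # the two residues flanking the core are set to alanine so the score of
    # the overwritten motif does not depend on the random background (no
    # accidental flank bonus), keeping the intact/lost contrast exact
    spacer <- 2L
    pos <- config$motif_pos + seq_along(core) - 1L
    core_cols <- pos
    motif_cols <- max(1L, min(pos) - spacer):min(L, max(pos) + spacer)
    codons[, setdiff(motif_cols, pos)] <- "GCT"
    # fixed codon choice per residue keeps output deterministic
    codon_for <- vapply(core, function(a)
      .sense_codons[match(a, unname(.genetic_code[.sense_codons]))], "")
    for (i in seq_along(core)) codons[, pos[i]] <- codon_for[i]
    if (length(loss_taxa)) {
      # R -> W in the first R of the core (KKRR -> KKWR)
      r_pos <- which(core == "R")[1L]
      if (!is.na(r_pos))
        codons[loss_taxa, pos[r_pos]] <- "TGG"
    }
  }
  # --- translate ---
  prot <- matrix(unname(.genetic_code[codons]), nt, L,
                 dimnames = list(tro$tip.label, NULL))
  # --- gap injection (whole columns, random taxon subsets) ---
  gap_cols <- which(stats::runif(L) < config$gap_rate)
  gap_cols <- setdiff(gap_cols, motif_cols)
  for (j in gap_cols) {
    frac <- stats::runif(1, 0.2, 0.9)
    n_gap <- min(nt - 1L, max(1L, round(frac * nt)))
    who <- sample.int(nt, n_gap)
    prot[who, j] <- "-"
    codons[who, j] <- "---"
  }
  # --- assemble ---
  cds_mat <- matrix("", nt, 3L * L, dimnames = list(tro$tip.label, NULL))
  for (p in 1:3)
    cds_mat[, seq(p, 3L * L, by = 3L)] <- substring(codons, p, p)
  proteins <- msa(prot, type = "AA")
  cds <- msa(cds_mat, type = "DNA")
  meta <- data.frame(
    id = tro$tip.label, species = tro$tip.label, clade = "mammal",
    group = ifelse(tro$tip.label %in% loss_taxa,
                   "toothed_whale", "land_mammal"))
  # partition on the reference's ungapped coordinates
  reference <- setdiff(tro$tip.label, loss_taxa)[1L]
  u <- cumsum(prot[reference, ] != "-")
  iv <- function(cols) {
    cols <- cols[prot[reference, cols] != "-"]
    c(u[cols[1L]], u[cols[length(cols)]])
  }
  partition <- domain_partition(
    reference,
    pro = iv(seq_len(n_pro)),
    mature = iv(n_pro + seq_len(n_mat)),
    NLS = if (length(core_cols)) iv(core_cols) else NULL,
    HCPR = if (n_pro >= 40L) iv(1:40) else NULL)
  truth <- list(tree = ape::write.tree(tr),
                omega = c(pro = config$omega_pro,
                          mature = config$omega_mature),
                loss_clade = loss_taxa,
                motif_functional = stats::setNames(
                  !(tro$tip.label %in% loss_taxa), tro$tip.label),
                reference = reference,
                seed = config$seed)
  structure(list(proteins = proteins, cds = cds, metadata = meta,
                 partition = partition, truth = truth, config = config),
            class = "il1_family_sim")
}

#' @export
print.il1_family_sim <- function(x, ...) {
  cat(sprintf(
    "<il1_family_sim> %d taxa, %d codons (pro %d / mature %d), seed %d\n",
    nrow(x$proteins), ncol(x$proteins), x$config$pro_codons,
    x$config$mature_codons, x$config$seed))
  cat("  omega:", paste(sprintf("%s=%.2g", names(x$truth$omega),
                                x$truth$omega), collapse = ", "), "\n")
  cat("  NLS-loss clade:", if (length(x$truth$loss_clade))
    paste(x$truth$loss_clade, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Writes `proteins.fasta`, `cds.fasta`, `metadata.tsv`, `partition.json`
#' and `truth.json`; the same config and seed produce byte-identical files.
#'
#' @param sim an [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "il1_family_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.fasta"),
             cds = file.path(dir, "cds.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             partition = file.path(dir, "partition.json"),
             truth = file.path(dir, "truth.json"))
  write_fasta(sim$proteins, paths[["proteins"]])
  write_fasta(sim$cds, paths[["cds"]])
  utils::write.table(sim$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_partition(sim$partition, paths[["partition"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
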