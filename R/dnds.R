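# Nei-Gojobori synonymous/non-synonymous analysis with Jukes-Cantor
# correction.  Site fractions and pathway-averaged difference counts are
# precomputed over the 61 sense codons and cached.

.ng_cache <- new.env(parent = emptyenv())

.translate_codon <- function(codon) {
  aa <- .genetic_code[codon]
  if (is.na(aa)) stop("not a valid codon: ", codon)
  unname(aa)
}

.is_stop <- function(codon) !is.na(.genetic_code[codon]) &&
  .genetic_code[[codon]] == "*"

#' Potential synonymous and nonsynonymous sites of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous; `s` is the sum over
#' positions and `n = 3 - s`.  Changes creating stop codons count as
#' nonsynonymous.
#'
#' @param codon a sense codon (string over ACGT).
#' @return list with elements `s` and `n`, `s + n == 3`.
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("codon must be three of A/C/G/T, got: ", codon)
  if (.is_stop(codon)) stop("stop codon has no defined site counts: ", codon)
  aa <- .translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  nt <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(bases, nt[p])) {
    alt <- nt; alt[p] <- b
    alt <- paste(alt, collapse = "")
    if (!.is_stop(alt) && .translate_codon(alt) == aa) syn <- syn + 1
  }
  s <- syn / 3
  list(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' All orderings of the differing positions are enumerated as mutational
#' pathways; pathways passing through a stop codon are excluded and the
#' synonymous/nonsynonymous step counts averaged (unweighted) over the
#' remainder.  If every pathway hits a stop, all pathways are used with
#' stop-creating steps counted nonsynonymous, and attribute
#' `stop_fallback = TRUE` marks the result.
#'
#' @param a,b sense codons.
#' @return list with `sd` and `nd` (fractional difference counts).
#' @export
pairwise_codon_diffs <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  for (x in c(a, b)) {
    if (!grepl("^[ACGT]{3}$", x))
      stop("codon must be three of A/C/G/T, got: ", x)
    if (.is_stop(x)) stop("stop codon: ", x)
  }
  na <- strsplit(a, "")[[1]]; nb <- strsplit(b, "")[[1]]
  diff_pos <- which(na != nb)
  d <- length(diff_pos)
  if (d == 0L) return(list(sd = 0, nd = 0))
  perms <- .permutations(diff_pos)
  step_counts <- function(path, allow_stop) {
    cur <- na; sd <- 0; nd <- 0
    for (p in path) {
      nxt <- cur; nxt[p] <- nb[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (.is_stop(c2)) {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (.is_stop(c1)) {
        nd <- nd + 1
      } else if (.translate_codon(c1) == .translate_codon(c2)) {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counts <- lapply(perms, step_counts, allow_stop = FALSE)
  counts <- counts[!vapply(counts, is.null, TRUE)]
  fallback <- length(counts) == 0L
  if (fallback) counts <- lapply(perms, step_counts, allow_stop = TRUE)
  m <- Reduce(`+`, counts) / length(counts)
  structure(list(sd = m[1L], nd = m[2L]), stop_fallback = fallback)
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# Cached lookup tables over the 61 sense codons: site fractions and the
# 61 x 61 sd/nd matrices.
.ng_tables <- function() {
  if (!is.null(.ng_cache$s)) return(as.list(.ng_cache))
  sc <- .sense_codons
  s <- vapply(sc, function(cd) codon_sites(cd)$s, 0)
  k <- length(sc)
  sd <- matrix(0, k, k, dimnames = list(sc, sc))
  nd <- matrix(0, k, k, dimnames = list(sc, sc))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) next
    if (i == j) next
    dd <- pairwise_codon_diffs(sc[i], sc[j])
    sd[i, j] <- sd[j, i] <- dd$sd
    nd[i, j] <- nd[j, i] <- dd$nd
  }
  .ng_cache$s <- s; .ng_cache$sd <- sd; .ng_cache$nd <- nd
  as.list(.ng_cache)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`.  Proportions at or beyond the
#' saturation point 3/4 raise an error of class `saturation_error` carrying
#' the raw proportion in its `p` field.
#'
#' @param p observed proportion of differences, `0 <= p < 3/4`.
#' @return the corrected number of substitutions per site.
#' @export
jukes_cantor <- function(p) {
  if (p < 0) stop("negative proportion")
  if (p >= 3 / 4)
    stop(structure(
      list(message = sprintf(
        "Jukes-Cantor correction undefined at p = %.4f (>= 0.75)", p),
        call = sys.call(-1L), p = p),
      class = c("saturation_error", "error", "condition")))
  if (p == 0) return(0)
  -3 / 4 * log(1 - 4 / 3 * p)
}

# Split an in-frame CDS string into codons; returns character vector.
.codon_split <- function(x) {
  x <- toupper(x)
  if (nchar(x) %% 3 != 0) stop("CDS length not divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Nei-Gojobori dN/dS for a pair of coding sequences
#'
#' Codon columns where either sequence has a gap or ambiguous base are
#' dropped (codon-wise complete deletion).  `S` and `N` are the mean over
#' the two sequences of their summed per-codon potential sites; `Sd` and
#' `Nd` are summed pathway-averaged differences; `pS = Sd/S`, `pN = Nd/N`;
#' `dS`, `dN` apply the Jukes-Cantor correction.
#'
#' @param cdsA,cdsB equal-length in-frame coding sequences (strings over
#'   A/C/G/T plus gap `-` and ambiguity `N`).
#' @return an object of class `dnds` with fields `S, N, Sd, Nd, pS, pN,
#'   dS, dN, dN_dS, dS_dN, n_codons` and logical undefined-ratio flags.
#' @export
nei_gojobori_pair <- function(cdsA, cdsB) {
  cnt <- .ng_counts(cdsA, cdsB)
  .dnds_result(cnt[["S"]], cnt[["N"]], cnt[["Sd"]], cnt[["Nd"]],
               cnt[["n_codons"]])
}

# Raw Nei-Gojobori counts for a pair (no correction applied).
.ng_counts <- function(cdsA, cdsB) {
  ca <- .codon_split(cdsA); cb <- .codon_split(cdsB)
  if (length(ca) != length(cb)) stop("coding sequences differ in length")
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) == 0L) stop("no codon columns survive gap deletion")
  if (any(.genetic_code[ca] == "*") || any(.genetic_code[cb] == "*"))
    stop("internal stop codon in coding sequence")
  tab <- .ng_tables()
  S <- (sum(tab$s[ca]) + sum(tab$s[cb])) / 2
  c(S = S, N = 3 * length(ca) - S,
    Sd = sum(tab$sd[cbind(ca, cb)]), Nd = sum(tab$nd[cbind(ca, cb)]),
    n_codons = length(ca))
}

.dnds_result <- function(S, N, Sd, Nd, n_codons) {
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  dS <- if (is.nan(pS)) NaN else jukes_cantor(pS)
  dN <- if (is.nan(pN)) NaN else jukes_cantor(pN)
  und_NS <- is.nan(dS) || dS == 0
  und_SN <- is.nan(dN) || dN == 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN,
                 dN_dS = if (und_NS) NA_real_ else dN / dS,
                 dS_dN = if (und_SN) NA_real_ else dS / dN,
                 dN_dS_undefined = und_NS, dS_dN_undefined = und_SN,
                 n_codons = n_codons),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf(
    "<dnds> %d codons | S=%.2f N=%.2f Sd=%.2f Nd=%.2f | pS=%.4f pN=%.4f | dS=%.4f dN=%.4f",
    x$n_codons, x$S, x$N, x$Sd, x$Nd, x$pS, x$pN, x$dS, x$dN))
  if (!x$dN_dS_undefined) cat(sprintf(" | dN/dS=%.4f", x$dN_dS))
  else cat(" | dN/dS undefined")
  cat("\n")
  invisible(x)
}

#' Per-domain Nei-Gojobori dN/dS for a group of sequences
#'
#' The domain partition (ungapped reference amino-acid coordinates) is
#' projected through the reference's gap pattern onto codon columns.  With
#' the default pooled estimator the raw counts `S, N, Sd, Nd` are summed
#' over all unordered within-group pairs before normalisation and
#' correction, which is stable when per-pair synonymous sites are few;
#' `method = "mean"` instead averages per-pair `dS`/`dN`.
#'
#' @param cds_aln a DNA [msa] of aligned in-frame coding sequences; gap
#'   codons must be `---`.
#' @param partition a [domain_partition()] whose reference is in the
#'   alignment (amino-acid coordinates).
#' @param group_ids at least two sequence ids.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return `data.frame` of class `dnds_table`, one row per domain, with the
#'   [nei_gojobori_pair()] fields.
#' @export
group_domain_dnds <- function(cds_aln, partition, group_ids,
                              method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cds_aln, "msa"), inherits(partition, "domain_partition"))
  if (length(group_ids) < 2L) stop("need at least 2 group members")
  unknown <- setdiff(c(group_ids, partition$reference), rownames(cds_aln))
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  if (ncol(cds_aln) %% 3 != 0) stop("alignment length not divisible by 3")
  n_codon_cols <- ncol(cds_aln) %/% 3
  # translate to protein columns for the reference projection
  strings <- as.character(cds_aln)
  prot <- do.call(rbind, lapply(strings, function(s) {
    cods <- .codon_split(s)
    aa <- rep("X", length(cods))
    aa[cods == "---"] <- "-"
    ok <- grepl("^[ACGT]{3}$", cods)
    aa[ok] <- unname(.genetic_code[cods[ok]])
    aa
  }))
  rownames(prot) <- names(strings)
  prot_aln <- msa(prot, type = "AA")
  coord <- .ref_coords(prot_aln, partition$reference)
  pairs <- utils::combn(group_ids, 2L, simplify = FALSE)
  out <- lapply(names(partition$intervals), function(nm) {
    iv <- partition$intervals[[nm]]
    cods <- which(!is.na(coord) & coord >= iv[1L] & coord <= iv[2L])
    if (length(cods) == 0L) stop("domain '", nm, "' has zero codon columns")
    nt_idx <- as.vector(rbind(3L * cods - 2L, 3L * cods - 1L, 3L * cods))
    slice <- vapply(rownames(cds_aln), function(id)
      paste(cds_aln[id, nt_idx], collapse = ""), "")
    cnts <- lapply(pairs, function(pr)
      .ng_counts(slice[[pr[1L]]], slice[[pr[2L]]]))
    row <- if (method == "pooled") {
      tot <- Reduce(`+`, cnts)
      res <- tryCatch(
        .dnds_result(tot[["S"]], tot[["N"]], tot[["Sd"]], tot[["Nd"]],
                     max(vapply(cnts, `[[`, 0, "n_codons"))),
        saturation_error = function(e) NULL)
      if (is.null(res)) {
        # saturated proportion: report raw counts, corrected values as NA
        data.frame(domain = nm, S = tot[["S"]], N = tot[["N"]],
                   Sd = tot[["Sd"]], Nd = tot[["Nd"]],
                   pS = tot[["Sd"]] / tot[["S"]],
                   pN = tot[["Nd"]] / tot[["N"]],
                   dS = NA_real_, dN = NA_real_,
                   dN_dS = NA_real_, dS_dN = NA_real_, saturated = TRUE,
                   n_codons = max(vapply(cnts, `[[`, 0, "n_codons")),
                   n_pairs = length(pairs))
      } else {
        data.frame(domain = nm, S = res$S, N = res$N, Sd = res$Sd,
                   Nd = res$Nd, pS = res$pS, pN = res$pN,
                   dS = res$dS, dN = res$dN,
                   dN_dS = res$dN_dS, dS_dN = res$dS_dN, saturated = FALSE,
                   n_codons = res$n_codons, n_pairs = length(pairs))
      }
    } else {
      jc_or_na <- function(p) tryCatch(jukes_cantor(p),
                                       saturation_error = function(e) NA_real_)
      dSs <- vapply(cnts, function(x) jc_or_na(x[["Sd"]] / x[["S"]]), 0)
      dNs <- vapply(cnts, function(x) jc_or_na(x[["Nd"]] / x[["N"]]), 0)
      dS <- mean(dSs); dN <- mean(dNs)
      data.frame(domain = nm, S = mean(vapply(cnts, `[[`, 0, "S")),
                 N = mean(vapply(cnts, `[[`, 0, "N")),
                 Sd = mean(vapply(cnts, `[[`, 0, "Sd")),
                 Nd = mean(vapply(cnts, `[[`, 0, "Nd")),
                 pS = NA_real_, pN = NA_real_, dS = dS, dN = dN,
                 dN_dS = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
                 dS_dN = if (!is.na(dN) && dN > 0) dS / dN else NA_real_,
                 saturated = anyNA(c(dSs, dNs)),
                 n_codons = max(vapply(cnts, `[[`, 0, "n_codons")),
                 n_pairs = length(pairs))
    }
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("dnds_table", "data.frame")
  res
}
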