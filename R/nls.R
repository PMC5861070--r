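# Candidate classical nuclear-localisation-signal (cNLS) detection and a
# transparent 0-10 surrogate score.  The published position-specific
# activity matrices behind NLS-prediction servers are not reproduced;
# instead a documented additive scheme over basic residues is calibrated so
# that the canonical basic core KKRR is functional (score >= 2) and its
# tryptophan-substituted form KKWR is not (score < 2), with 2 as the
# functionality threshold.

.basic <- function(x) x %in% c("K", "R")

#' Scan a protein sequence for candidate NLS motifs
#'
#' Monopartite candidates are every 4-mer matching `K-(K/R)-X-(K/R)`.
#' Bipartite candidates are two basic clusters (at least two K/R within a
#' 3-residue window) separated by a 10-12 residue linker.  All candidates
#' (including overlaps) are reported, scored with [score_candidate()] and
#' sorted by score (descending) then position.
#'
#' @param residues an ungapped protein sequence (string), length >= 4.
#' @param region optional `c(start, end)` window (1-based inclusive) to
#'   restrict the scan, e.g. the pro-region NLS window.
#' @return `data.frame` of class `nls_candidates` with columns `kind`,
#'   `start`, `end`, `core`, `score`, `functional`.
#' @export
scan_nls <- function(residues, region = NULL) {
  s <- strsplit(toupper(residues), "")[[1]]
  if (any(!(s %in% .aa_alphabet)))
    stop("sequence contains non-amino-acid symbols: ",
         paste(unique(s[!(s %in% .aa_alphabet)]), collapse = ", "))
  if (length(s) < 4L) stop("sequence shorter than 4 residues")
  lo <- 1L; hi <- length(s)
  if (!is.null(region)) { lo <- max(1L, region[1L]); hi <- min(hi, region[2L]) }
  cands <- list()
  # monopartite: K-(K/R)-X-(K/R)
  for (i in lo:max(lo, hi - 3L)) {
    if (i + 3L > hi) break
    w <- s[i:(i + 3L)]
    if (w[1L] == "K" && .basic(w[2L]) && .basic(w[4L])) {
      cand <- .nls_candidate("monopartite", i, i + 3L, s)
      cands[[length(cands) + 1L]] <- cand
    }
  }
  # bipartite: basic clusters separated by a 10-12 residue linker
  clusters <- .basic_clusters(s)
  if (nrow(clusters) >= 2L) {
    for (i in seq_len(nrow(clusters) - 1L)) for (j in (i + 1L):nrow(clusters)) {
      linker <- clusters$start[j] - clusters$end[i] - 1L
      if (linker >= 10L && linker <= 12L &&
          clusters$start[i] >= lo && clusters$end[j] <= hi) {
        cand <- .nls_candidate("bipartite", clusters$start[i],
                               clusters$end[j], s,
                               clusters = rbind(clusters[i, ], clusters[j, ]))
        cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  if (length(cands) == 0L) {
    out <- data.frame(kind = character(), start = integer(), end = integer(),
                      core = character(), score = numeric(),
                      functional = logical())
  } else {
    out <- do.call(rbind, lapply(cands, function(cd)
      data.frame(kind = cd$kind, start = cd$start, end = cd$end,
                 core = cd$core, score = cd$score,
                 functional = cd$functional)))
    out <- out[order(-out$score, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("nls_candidates", "data.frame")
  attr(out, "sequence") <- paste(s, collapse = "")
  out
}

# maximal runs of K/R positions where successive basics are <= 2 apart,
# kept when they contain >= 2 basics within some 3-residue window (i.e.
# two basics at distance <= 2)
.basic_clusters <- function(s) {
  pos <- which(.basic(s))
  if (length(pos) < 2L)
    return(data.frame(start = integer(), end = integer(), n_basic = integer()))
  grp <- cumsum(c(1L, diff(pos) > 2L))
  runs <- split(pos, grp)
  runs <- runs[vapply(runs, length, 0L) >= 2L]
  if (length(runs) == 0L)
    return(data.frame(start = integer(), end = integer(), n_basic = integer()))
  data.frame(start = vapply(runs, min, 0L), end = vapply(runs, max, 0L),
             n_basic = vapply(runs, length, 0L), row.names = NULL)
}

.nls_candidate <- function(kind, start, end, s, clusters = NULL) {
  cand <- structure(list(kind = kind, start = start, end = end,
                         core = paste(s[start:end], collapse = ""),
                         sequence = s, clusters = clusters),
                    class = "nls_candidate")
  cand$score <- score_candidate(cand)
  cand$functional <- cand$score >= 2
  cand
}

#' Score a candidate NLS on the 0-10 scale
#'
#' Monopartite: number of K/R among the 4 core positions, minus 2 per
#' tryptophan in the core, plus 1 if an additional K/R lies within 2
#' positions of the core on either side; clamped to `[0, 10]`.  Bipartite:
#' the same terms computed over both basic clusters.  A score below 2 is
#' classed non-functional.
#'
#' @param candidate an `nls_candidate` produced by [scan_nls()].
#' @return numeric score in `[0, 10]`.
#' @export
score_candidate <- function(candidate) {
  stopifnot(inherits(candidate, "nls_candidate"))
  s <- candidate$sequence
  core_pos <-
    if (candidate$kind == "monopartite") candidate$start:candidate$end
    else unlist(lapply(seq_len(nrow(candidate$clusters)), function(k)
      candidate$clusters$start[k]:candidate$clusters$end[k]))
  core <- s[core_pos]
  sc <- sum(.basic(core)) - 2 * sum(core == "W")
  flank <- c(max(1L, candidate$start - 2L):max(1L, candidate$start - 1L),
             min(length(s), candidate$end + 1L):min(length(s),
                                                    candidate$end + 2L))
  flank <- setdiff(unique(flank), candidate$start:candidate$end)
  if (any(.basic(s[flank]))) sc <- sc + 1
  min(10, max(0, sc))
}

#' cNLS scores at the NLS locus of an alignment
#'
#' The partition's `NLS` interval (reference ungapped coordinates) is
#' projected through the alignment onto each sequence's own ungapped
#' coordinates, and the best-scoring candidate overlapping that window is
#' reported per sequence.  Sequences with no overlapping candidate get
#' score 0 and `functional = FALSE`.  This is the per-species contrast
#' between an intact basic core and its tryptophan-substituted form.
#'
#' @param aln a protein [msa].
#' @param partition a [domain_partition()] with an `NLS` interval.
#' @param flank extra residues added to each side of the projected window
#'   before matching candidates (default 3, so flank-bonus context is
#'   visible).
#' @param kind restrict to `"monopartite"` (the class of the classical
#'   basic-core signal this contrast concerns), `"bipartite"`, or `"any"`.
#' @return `data.frame` with columns `id`, `start`, `end`, `core`, `score`,
#'   `functional`.
#' @export
nls_window_scores <- function(aln, partition, flank = 3L,
                              kind = c("monopartite", "any", "bipartite")) {
  kind <- match.arg(kind)
  stopifnot(inherits(aln, "msa"), inherits(partition, "domain_partition"))
  if (is.null(partition$intervals$NLS))
    stop("partition has no NLS interval")
  iv <- partition$intervals$NLS
  coord <- .ref_coords(aln, partition$reference)
  cols <- which(!is.na(coord) & coord >= iv[1L] & coord <= iv[2L])
  if (length(cols) == 0L) stop("NLS interval maps to no alignment columns")
  out <- lapply(rownames(aln), function(id) {
    row <- aln[id, ]
    nongap <- !.is_gap(row)
    upos <- cumsum(nongap)
    wcols <- cols[nongap[cols]]
    if (length(wcols) == 0L)
      return(data.frame(id = id, start = NA_integer_, end = NA_integer_,
                        core = NA_character_, score = 0,
                        functional = FALSE))
    lo <- max(1L, min(upos[wcols]) - flank)
    hi <- min(sum(nongap), max(upos[wcols]) + flank)
    seq <- paste(row[nongap], collapse = "")
    cands <- scan_nls(seq)
    if (kind != "any") cands <- cands[cands$kind == kind, , drop = FALSE]
    hit <- cands[cands$start <= hi & cands$end >= lo, , drop = FALSE]
    if (nrow(hit) == 0L)
      return(data.frame(id = id, start = NA_integer_, end = NA_integer_,
                        core = NA_character_, score = 0,
                        functional = FALSE))
    data.frame(id = id, start = hit$start[1L], end = hit$end[1L],
               core = hit$core[1L], score = hit$score[1L],
               functional = hit$functional[1L])
  })
  do.call(rbind, out)
}

#' NLS candidate table for every sequence of an alignment
#'
#' Gaps are removed per sequence before scanning; positions refer to each
#' ungapped sequence.  The top-scoring candidate per sequence (if any) is
#' flagged.
#'
#' @param aln an [msa] of proteins.
#' @param region optional window passed to [scan_nls()] (ungapped
#'   coordinates).
#' @return `data.frame` with a leading `id` column and one row per
#'   candidate; sequences with no candidate get one row with `NA` fields and
#'   `functional = FALSE`.
#' @export
nls_table <- function(aln, region = NULL) {
  stopifnot(inherits(aln, "msa"))
  out <- lapply(rownames(aln), function(id) {
    seq <- paste(aln[id, !.is_gap(aln[id, ])], collapse = "")
    cands <- tryCatch(scan_nls(seq, region = region),
                      error = function(e) NULL)
    if (is.null(cands) || nrow(cands) == 0L)
      return(data.frame(id = id, kind = NA_character_, start = NA_integer_,
                        end = NA_integer_, core = NA_character_,
                        score = NA_real_, functional = FALSE, top = TRUE))
    cbind(id = id, as.data.frame(cands),
          top = seq_len(nrow(cands)) == 1L)
  })
  do.call(rbind, out)
}
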