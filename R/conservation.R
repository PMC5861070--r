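# Modal-residue conservation profiling, domain summaries, modal consensus
# sequences, and the clade-versus-modal-reference contrast.

#' Define a domain partition on a reference sequence
#'
#' Intervals are 1-based inclusive positions on the *ungapped* reference
#' sequence.  `pro` and `mature` must not overlap; `NLS` and `HCPR`, when
#' given, must lie inside `pro`.  Columns are later projected onto any
#' alignment through the reference's gap pattern.
#'
#' @param reference id of the reference sequence.
#' @param pro,mature,NLS,HCPR integer length-2 vectors `c(start, end)`;
#'   all but `pro` are optional.
#' @return an object of class `domain_partition`.
#' @export
domain_partition <- function(reference, pro, mature = NULL, NLS = NULL,
                             HCPR = NULL) {
  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.integer(x)
    if (length(x) != 2L || x[1L] < 1L || x[2L] < x[1L])
      stop("invalid interval for ", nm)
    x
  }
  pro <- chk(pro, "pro"); mature <- chk(mature, "mature")
  NLS <- chk(NLS, "NLS"); HCPR <- chk(HCPR, "HCPR")
  if (!is.null(mature) &&
      max(pro[1L], mature[1L]) <= min(pro[2L], mature[2L]))
    stop("pro and mature intervals overlap")
  inside <- function(x, y) x[1L] >= y[1L] && x[2L] <= y[2L]
  if (!is.null(NLS) && !inside(NLS, pro)) stop("NLS must lie within pro")
  if (!is.null(HCPR) && !inside(HCPR, pro)) stop("HCPR must lie within pro")
  iv <- list(pro = pro)
  if (!is.null(mature)) iv$mature <- mature
  if (!is.null(NLS)) iv$NLS <- NLS
  if (!is.null(HCPR)) iv$HCPR <- HCPR
  structure(list(reference = reference, intervals = iv),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> reference:", x$reference, "\n")
  for (nm in names(x$intervals))
    cat(sprintf("  %-7s %d-%d\n", nm, x$intervals[[nm]][1L],
                x$intervals[[nm]][2L]))
  invisible(x)
}

#' Read/write a domain partition as JSON
#' @param path JSON file with fields `reference` and named `[start, end]`
#'   intervals.
#' @return a `domain_partition`.
#' @export
read_partition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain_partition(j$reference, pro = j$pro, mature = j$mature,
                   NLS = j$NLS, HCPR = j$HCPR)
}

#' @rdname read_partition
#' @param partition a `domain_partition`.
#' @export
write_partition <- function(partition, path) {
  x <- c(list(reference = partition$reference), partition$intervals)
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

# Map alignment columns to ungapped reference coordinates (NA where the
# reference has a gap).
.ref_coords <- function(aln, reference) {
  if (!(reference %in% rownames(aln)))
    stop("reference id not in alignment: ", reference)
  ref <- aln[reference, ]
  nongap <- !.is_gap(ref)
  coord <- rep(NA_integer_, ncol(aln))
  coord[nongap] <- seq_len(sum(nongap))
  coord
}

.default_reference <- function(aln) {
  ids <- rownames(aln)
  hit <- grep("human|homo", ids, ignore.case = TRUE, value = TRUE)
  ref <- if (length(hit)) hit[1L] else ids[1L]
  message("conservation reference sequence: ", ref)
  ref
}

# Modal residue of a character vector, gaps excluded, alphabetical
# tie-break; returns "-" for an all-gap column.
.modal_residue <- function(x) {
  res <- x[!.is_gap(x)]
  if (length(res) == 0L) return("-")
  tab <- table(res)
  names(tab)[which.max(tab)]  # table names are sorted, so ties go alphabetically
}

#' Per-site modal-residue conservation profile
#'
#' For each alignment column the modal (most frequent non-gap) residue is
#' found and conservation is the percentage of sequences carrying it; gapped
#' sequences stay in the denominator.  Apply [modal_gap_deletion()] first so
#' no column is gap-dominated.
#'
#' @param aln an [msa] (after modal-gap deletion).
#' @param reference id used for reference coordinates; defaults to a
#'   sequence whose id contains "human"/"homo", else the first record.
#' @param source optional unfiltered [msa] the columns of `aln` were taken
#'   from (requires `aln` to carry the `retained` attribute written by the
#'   filtering functions).  When given, `ref_pos` uses the reference's
#'   ungapped coordinates in the *original* alignment, so domain partitions
#'   defined on the full sequence stay valid even if filtering removed
#'   reference residues.
#' @return a `data.frame` of class `conservation_profile` with columns
#'   `column`, `ref_pos`, `modal`, `conservation`; the reference id and its
#'   ungapped length are attached as attributes.
#' @export
site_conservation <- function(aln, reference = NULL, source = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (nrow(aln) == 0L || ncol(aln) == 0L) stop("empty alignment")
  if (is.null(reference)) reference <- .default_reference(aln)
  if (!is.null(source)) {
    ret <- attr(aln, "retained")
    if (is.null(ret))
      stop("'source' given but 'aln' has no retained-column attribute")
    coord <- .ref_coords(source, reference)[ret]
    ref_len <- sum(!.is_gap(source[reference, ]))
  } else {
    coord <- .ref_coords(aln, reference)
    ref_len <- sum(!is.na(coord))
  }
  n <- nrow(aln)
  modal <- character(ncol(aln))
  cons <- numeric(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    m <- .modal_residue(aln[, j])
    modal[j] <- m
    cons[j] <- 100 * sum(aln[, j] == m) / n
  }
  out <- data.frame(column = seq_len(ncol(aln)), ref_pos = coord,
                    modal = modal, conservation = cons)
  class(out) <- c("conservation_profile", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "ref_length") <- ref_len
  out
}

#' Mean conservation per domain
#'
#' @param profile a [site_conservation()] profile.
#' @param partition a [domain_partition()] on the profile's reference.
#' @return `data.frame` with columns `domain`, `mean_conservation`,
#'   `n_columns`.
#' @export
domain_summary <- function(profile, partition) {
  stopifnot(inherits(profile, "conservation_profile"),
            inherits(partition, "domain_partition"))
  ref_len <- attr(profile, "ref_length")
  res <- lapply(names(partition$intervals), function(nm) {
    iv <- partition$intervals[[nm]]
    if (iv[2L] > ref_len)
      stop("interval '", nm, "' extends beyond the reference length (",
           ref_len, ")")
    rows <- !is.na(profile$ref_pos) &
      profile$ref_pos >= iv[1L] & profile$ref_pos <= iv[2L]
    if (!any(rows))
      stop("interval '", nm, "' has zero surviving columns")
    data.frame(domain = nm,
               mean_conservation = mean(profile$conservation[rows]),
               n_columns = sum(rows))
  })
  do.call(rbind, res)
}

#' Modal consensus sequence over a subset of records
#'
#' Per column the modal residue over the subset, gaps excluded from
#' modality (alphabetical tie-break); all-gap columns emit `'-'` and are
#' flagged in attribute `all_gap_columns`.
#'
#' @param aln an [msa].
#' @param ids subset of sequence ids (non-empty).
#' @return a single consensus string with attribute `all_gap_columns`.
#' @export
modal_sequence <- function(aln, ids) {
  stopifnot(inherits(aln, "msa"))
  unknown <- setdiff(ids, rownames(aln))
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  if (length(ids) == 0L) stop("empty subset")
  sub <- unclass(aln)[ids, , drop = FALSE]
  cons <- vapply(seq_len(ncol(sub)), function(j) .modal_residue(sub[, j]), "")
  structure(paste(cons, collapse = ""),
            all_gap_columns = which(cons == "-"))
}

#' Per-domain identity of focal sequences to a reference-group modal sequence
#'
#' For each focal sequence and each domain, the percentage of domain columns
#' where the focal residue equals the modal residue of the reference group.
#' Columns where either symbol is a gap are excluded from numerator and
#' denominator.
#'
#' @param aln an [msa].
#' @param focal_ids,reference_ids disjoint id sets.
#' @param partition a [domain_partition()]; its reference must be in the
#'   alignment.
#' @return `data.frame` with columns `id`, `domain`, `identity`,
#'   `n_columns`.
#' @export
group_vs_modal <- function(aln, focal_ids, reference_ids, partition) {
  stopifnot(inherits(aln, "msa"), inherits(partition, "domain_partition"))
  if (length(intersect(focal_ids, reference_ids)))
    stop("focal and reference id sets must be disjoint")
  modal <- strsplit(modal_sequence(aln, reference_ids), "")[[1]]
  coord <- .ref_coords(aln, partition$reference)
  out <- list()
  for (nm in names(partition$intervals)) {
    iv <- partition$intervals[[nm]]
    cols <- which(!is.na(coord) & coord >= iv[1L] & coord <= iv[2L])
    for (id in focal_ids) {
      f <- aln[id, cols]
      m <- modal[cols]
      use <- !.is_gap(f) & !.is_gap(m)
      if (!any(use))
        stop("domain '", nm, "' is empty after gap exclusion for ", id)
      out[[length(out) + 1L]] <- data.frame(
        id = id, domain = nm,
        identity = 100 * sum(f[use] == m[use]) / sum(use),
        n_columns = sum(use))
    }
  }
  do.call(rbind, out)
}

#' Per-column conservation table with domain labels (heat-map values)
#'
#' Numeric output is exact; the `bin_*` columns only record the colour-scale
#' anchors (default 25--100 percent) used for rendering elsewhere.
#'
#' @param profile a [site_conservation()] profile.
#' @param partition a [domain_partition()].
#' @param bins length-2 numeric colour-scale anchors.
#' @return `data.frame` with one row per profile column.
#' @export
heatmap_table <- function(profile, partition, bins = c(25, 100)) {
  stopifnot(inherits(profile, "conservation_profile"),
            inherits(partition, "domain_partition"), length(bins) == 2L)
  dom <- rep(NA_character_, nrow(profile))
  # NLS/HCPR come after pro in the interval list, so narrower sub-intervals
  # override the broad pro label
  for (nm in names(partition$intervals)) {
    iv <- partition$intervals[[nm]]
    hit <- !is.na(profile$ref_pos) &
      profile$ref_pos >= iv[1L] & profile$ref_pos <= iv[2L]
    dom[hit] <- nm
  }
  data.frame(column = profile$column, ref_pos = profile$ref_pos,
             modal = profile$modal, conservation = profile$conservation,
             domain = dom, bin_low = bins[1L], bin_high = bins[2L])
}

#' Write a conservation table to TSV
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
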