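# Characters treated as "gaps and missing data" throughout the package.
# '-' is an alignment gap; 'X' marks an undetermined residue in protein
# sequences and 'N' an undetermined base in nucleotide sequences (where 'N'
# is a residue -- asparagine -- and must not be filtered).  Gaps and
# missing data are grouped for all filtering purposes.
.gap_chars <- function(type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (type == "AA") c("-", "X") else c("-", "N", "X")
}

.is_gap <- function(x, type = "AA") {
  if (is.object(x)) {
    if (!is.null(attr(x, "type"))) type <- attr(x, "type")
    x <- unclass(x)
  }
  x %in% .gap_chars(type)
}

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a multiple sequence alignment object
#'
#' An `msa` is a character matrix with one row per sequence (rownames are the
#' sequence ids) and one column per alignment site, each cell holding a single
#' upper-case symbol.  Column indices are 1-based inclusive in every
#' user-facing interface.
#'
#' @param seqs named character vector of equal-length aligned sequences, or a
#'   character matrix of single symbols with rownames.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide.
#' @return an object of class `msa`.
#' @export
msa <- function(seqs, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("all sequences must be named with non-empty ids")
    n <- nchar(seqs)
    if (length(unique(n)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(range(n), collapse = "-"), ")")
    if (any(n == 0L)) stop("empty sequences are not allowed")
    m <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(m) <- ids
  }
  m[] <- toupper(m)
  m[m == "."] <- "-"
  if (anyDuplicated(rownames(m)))
    stop("duplicate sequence id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  structure(m, class = "msa", type = type)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d %s sequences x %d columns\n",
              nrow(x), attr(x, "type"), ncol(x)))
  show <- utils::head(rownames(x), 5L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 50L))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Extract aligned sequences as strings
#' @param x an `msa`.
#' @param ... unused.
#' @return named character vector of aligned sequence strings.
#' @export
as.character.msa <- function(x, ...) {
  out <- apply(unclass(x), 1L, paste, collapse = "")
  names(out) <- rownames(x)
  out
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and `'.'` gap characters normalised to `'-'`.
#' Record order is preserved.  Duplicate ids and ragged lengths (when an
#' alignment is demanded) are errors.
#'
#' @param path path to a FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @param aligned require equal lengths (default `TRUE`); the package refuses
#'   unaligned input rather than aligning it.
#' @return an [msa].
#' @export
read_fasta <- function(path, type = c("AA", "DNA"), aligned = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  # normalise '.' gaps before handing the file to the parser ('.' is not a
  # symbol the AA/DNA bit-level representations keep)
  raw <- readLines(path)
  seq_lines <- !startsWith(raw, ">")
  raw[seq_lines] <- gsub(".", "-", raw[seq_lines], fixed = TRUE)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(raw, tmp)
  bin <- ape::read.FASTA(tmp, type = if (type == "AA") "AA" else "DNA")
  if (length(bin) == 0L) stop("no sequences in ", path)
  seqs <- vapply(as.character(bin), paste, "", collapse = "")
  seqs <- toupper(seqs)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (!aligned) return(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment in ", path,
         ": sequence lengths differ; supply pre-aligned input")
  msa(seqs, type = type)
}

#' Write an alignment to FASTA
#' @param aln an [msa].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- as.character(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Read a sequence metadata table
#'
#' Expects a TSV with header columns `id`, `species`, `clade`, `group`.
#' Clade values outside the controlled vocabulary (mammal, bird, reptile,
#' bony_fish, cartilaginous_fish, other) are stored as `"other"` with a
#' warning.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` with one row per sequence id.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "clade", "group")
  missing <- setdiff(need, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$id))
    stop("duplicate id(s) in metadata: ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  known <- c("mammal", "bird", "reptile", "bony_fish",
             "cartilaginous_fish", "other")
  bad <- !(md$clade %in% known)
  if (any(bad)) {
    warning("unknown clade value(s) mapped to 'other': ",
            paste(unique(md$clade[bad]), collapse = ", "))
    md$clade[bad] <- "other"
  }
  md$clade <- factor(md$clade, levels = known)
  md[need]
}

#' Join alignment ids against metadata
#'
#' Every alignment id must resolve; unresolvable ids are an error, never a
#' silent drop.
#'
#' @param aln an [msa].
#' @param metadata a table from [read_metadata()].
#' @return the metadata rows in alignment order.
#' @export
join_metadata <- function(aln, metadata) {
  ids <- rownames(aln)
  missing <- setdiff(ids, metadata$id)
  if (length(missing))
    stop("alignment id(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  metadata[match(ids, metadata$id), , drop = FALSE]
}

#' Read and write Newick trees
#'
#' Trees round-trip on topology, branch lengths (written with 10
#' significant digits, so 6-decimal identity is preserved) and integer
#' internal-node support labels.
#'
#' @param path file path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
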