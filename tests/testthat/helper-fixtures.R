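# Shared fixture builders; everything is generated in code.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# random protein alignment with optional gap/missing symbols
random_msa <- function(n_seq, n_col, gap_prob = 0, seed = NULL,
                       alphabet = aa20) {
  if (!is.null(seed)) set.seed(seed)
  pool <- alphabet
  m <- matrix(sample(pool, n_seq * n_col, replace = TRUE), n_seq, n_col)
  if (gap_prob > 0) {
    hit <- matrix(stats::runif(n_seq * n_col) < gap_prob, n_seq, n_col)
    m[hit] <- sample(c("-", "X"), sum(hit), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n_seq))
  msa(m, type = "AA")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# brute-force pathway enumerator used as the independent oracle for
# Nei-Gojobori difference counts: enumerates position orderings explicitly
# via expand.grid-style recursion on vectors, with its own translation step
oracle_codon_diffs <- function(a, b, code) {
  na <- strsplit(a, "")[[1]]
  nb <- strsplit(b, "")[[1]]
  dpos <- which(na != nb)
  if (length(dpos) == 0L) return(c(0, 0))
  orders <- if (length(dpos) == 1L) list(dpos) else {
    perm <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm(v[-i]), function(r) c(v[i], r))))
    }
    perm(dpos)
  }
  walk <- function(ord, allow_stop) {
    cur <- na; sdnd <- c(0, 0)
    for (p in ord) {
      nxt <- cur; nxt[p] <- nb[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2 && aa1 != "*") sdnd[1] <- sdnd[1] + 1
      else sdnd[2] <- sdnd[2] + 1
      cur <- nxt
    }
    sdnd
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(orders, walk, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

# the standard genetic code built independently of the package, from the
# classic RNA codon table layout
oracle_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  aas <- paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG")
  codons <- character(0)
  for (x in b) for (y in b) for (z in b)
    codons <- c(codons, paste0(x, y, z))
  stats::setNames(strsplit(aas, "")[[1]], codons)
}
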