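test_that("codon site fractions match hand enumeration of neighbours", {
  expect_equal(codon_sites("TTT")$s, 1 / 3)   # only TTT->TTC synonymous
  expect_equal(codon_sites("TTA")$s, 2 / 3)   # CTA (pos1), TTG (pos3); stops nonsyn
  expect_equal(codon_sites("ATG")$s, 0)       # every neighbour changes the aa
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("TTN"), "codon")
})

test_that("s + n = 3 for all 61 sense codons and matches a brute force", {
  code <- oracle_genetic_code()
  sense <- names(code)[code != "*"]
  expect_length(sense, 61L)
  b <- c("A", "C", "G", "T")
  for (cd in sense) {
    cs <- codon_sites(cd)
    expect_equal(cs$s + cs$n, 3)
    # independent neighbour enumeration
    nt <- strsplit(cd, "")[[1]]
    syn <- 0
    for (p in 1:3) for (alt in setdiff(b, nt[p])) {
      x <- nt; x[p] <- alt
      x <- paste(x, collapse = "")
      if (code[[x]] != "*" && code[[x]] == code[[cd]]) syn <- syn + 1
    }
    expect_equal(cs$s, syn / 3, info = cd)
  }
})

test_that("pathway-averaged differences match worked examples", {
  expect_equal(pairwise_codon_diffs("TTT", "TTA"), list(sd = 0, nd = 1),
               ignore_attr = TRUE)
  expect_equal(pairwise_codon_diffs("ATG", "ACA"), list(sd = 0.5, nd = 1.5),
               ignore_attr = TRUE)
  expect_equal(pairwise_codon_diffs("AAA", "AAA"), list(sd = 0, nd = 0),
               ignore_attr = TRUE)
  expect_error(pairwise_codon_diffs("AAR", "AAA"), "codon")
})

test_that("differences agree with the brute-force pathway oracle over all 61x61 pairs", {
  code <- oracle_genetic_code()
  sense <- names(code)[code != "*"]
  for (a in sense) for (b in sense) {
    got <- pairwise_codon_diffs(a, b)
    want <- oracle_codon_diffs(a, b, code)
    expect_equal(c(got$sd, got$nd), want, info = paste(a, b))
    # pathway-averaged total equals the nucleotide difference count
    nd_pos <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(got$sd + got$nd, nd_pos, info = paste(a, b))
  }
})

test_that("difference counting is symmetric in its arguments", {
  set.seed(42)
  sense <- sample(names(oracle_genetic_code())[oracle_genetic_code() != "*"])
  for (i in 1:30) {
    a <- sense[i]; b <- sense[61 - i]
    ab <- pairwise_codon_diffs(a, b)
    ba <- pairwise_codon_diffs(b, a)
    expect_equal(ab$sd, ba$sd)
    expect_equal(ab$nd, ba$nd)
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.4), -0.75 * log(1 - 4 / 3 * 0.4))
  expect_equal(jukes_cantor(0.4), 0.5716, tolerance = 1e-4)
  err <- tryCatch(jukes_cantor(0.75), saturation_error = function(e) e)
  expect_s3_class(err, "saturation_error")
  expect_equal(err$p, 0.75)
  expect_error(jukes_cantor(-0.1), "negative")
})

test_that("the worked single-codon pair composes sites, diffs and correction", {
  r <- nei_gojobori_pair("TTT", "TTA")
  expect_equal(r$S, 0.5)
  expect_equal(r$N, 2.5)
  expect_equal(r$pS, 0)
  expect_equal(r$pN, 0.4)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, -0.75 * log(1 - 4 / 3 * 0.4))
  expect_true(r$dN_dS_undefined)
})

test_that("identical coding sequences give an all-zero flagged result", {
  r <- nei_gojobori_pair("AAATTTGGG", "AAATTTGGG")
  expect_equal(c(r$Sd, r$Nd, r$dS, r$dN), c(0, 0, 0, 0))
  expect_true(r$dN_dS_undefined)
  expect_true(r$dS_dN_undefined)
})

test_that("gap codons are deleted pairwise and stops rejected", {
  r <- nei_gojobori_pair("AAA---TTT", "AAACCC---")
  expect_equal(r$n_codons, 1L)
  expect_error(nei_gojobori_pair("TAATTT", "TAATTC"), "stop")
  expect_error(nei_gojobori_pair("AAAA", "AAAA"), "divisible")
})

test_that("a simulated 300-codon pair matches codon-by-codon re-accumulation", {
  code <- oracle_genetic_code()
  sense <- names(code)[code != "*"]
  set.seed(7)
  a <- sample(sense, 300, replace = TRUE)
  b <- a
  mut <- sample(300, 60)
  b[mut] <- sample(sense, 60, replace = TRUE)
  r <- nei_gojobori_pair(paste(a, collapse = ""), paste(b, collapse = ""))
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(300)) {
    S <- S + (codon_sites(a[i])$s + codon_sites(b[i])$s) / 2
    d <- oracle_codon_diffs(a[i], b[i], code)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  expect_equal(r$S, S, tolerance = 1e-12)
  expect_equal(r$Sd, Sd, tolerance = 1e-12)
  expect_equal(r$Nd, Nd, tolerance = 1e-12)
  expect_equal(r$dN, jukes_cantor(Nd / (900 - S)), tolerance = 1e-12)
})

test_that("two-member group reduces to the pairwise result on a domain slice", {
  cds <- msa(c(r1 = "AAATTTGGGCCC", r2 = "AAATTAGGGCCA"), type = "DNA")
  part <- domain_partition("r1", pro = c(1, 2), mature = c(3, 4))
  tab <- group_domain_dnds(cds, part, c("r1", "r2"))
  pro_pair <- nei_gojobori_pair("AAATTT", "AAATTA")
  expect_equal(tab$dN[tab$domain == "pro"], pro_pair$dN)
  expect_equal(tab$dS[tab$domain == "pro"], pro_pair$dS)
  expect_equal(tab$S[tab$domain == "pro"], pro_pair$S)
})

test_that("identical group members give zero divergence in every domain", {
  cds <- msa(c(a = "AAATTTGGG", b = "AAATTTGGG", c = "AAATTTGGG"),
             type = "DNA")
  part <- domain_partition("a", pro = c(1, 2), mature = c(3, 3))
  tab <- group_domain_dnds(cds, part, c("a", "b", "c"))
  expect_equal(tab$dN, c(0, 0))
  expect_equal(tab$dS, c(0, 0))
  expect_equal(tab$n_pairs, c(3L, 3L))
})

test_that("dN/dS approaches the generating omega as divergence shrinks", {
  # short branches: counting bias is small, so pooled dN/dS tracks omega
  cfg <- sim_config(n_taxa = 8, pro_codons = 300, mature_codons = 300,
                    omega_pro = 0.2, omega_mature = 0.2, depth = 0.05,
                    motif_core = NULL, loss_clade = NULL, gap_rate = 0,
                    seed = 303)
  sim <- simulate_family(cfg)
  tab <- group_domain_dnds(sim$cds, sim$partition, sim$metadata$id)
  expect_equal(tab$dN_dS[tab$domain == "pro"], 0.2, tolerance = 0.35)
  expect_false(any(tab$saturated))
})
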