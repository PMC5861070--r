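test_that("per-site conservation is the modal-residue percentage", {
  aln <- msa(c(a = "AAA", b = "AAA", c = "AAV", d = "VAV"))
  pr <- site_conservation(aln, reference = "a")
  # col1 {A,A,A,V} -> 75; col2 unanimity -> 100; col3 {A,A,V,V} tie -> 'A', 50
  expect_equal(pr$conservation, c(75, 100, 50))
  expect_equal(pr$modal, c("A", "A", "A"))
})

test_that("tie-break is alphabetical and the percentage is tie-order invariant", {
  # every arrangement of 2 A's and 2 V's in a column gives the same result
  perms <- unique(combinat_perms <- t(utils::combn(4, 2)))
  for (i in seq_len(nrow(perms))) {
    col <- rep("V", 4)
    col[perms[i, ]] <- "A"
    aln <- msa(matrix(col, 4, 1, dimnames = list(paste0("s", 1:4), NULL)))
    pr <- site_conservation(aln, reference = "s1")
    expect_equal(pr$conservation, 50)
    expect_equal(pr$modal, "A")
  }
})

test_that("gapped sequences stay in the denominator", {
  aln <- msa(c(a = "A", b = "A", c = "A", d = "-"))
  pr <- site_conservation(aln, reference = "a")
  expect_equal(pr$conservation, 75)
})

test_that("domain summaries are arithmetic means over interval columns", {
  aln <- msa(c(ref = "AAK", s2 = "AAK", s3 = "AVK", s4 = "VAK"))
  pr <- site_conservation(aln, reference = "ref")
  # conservation: {A,A,A,V}=75... col1 75, col2 75, col3 100
  part <- domain_partition("ref", pro = c(1, 2), mature = c(3, 3))
  ds <- domain_summary(pr, part)
  expect_equal(ds$mean_conservation[ds$domain == "pro"], 75)
  expect_equal(ds$mean_conservation[ds$domain == "mature"], 100)
  expect_equal(ds$n_columns, c(2L, 1L))

  whole <- domain_partition("ref", pro = c(1, 3), mature = NULL)
  expect_error(domain_partition("ref", pro = c(1, 3), mature = c(2, 3)),
               "overlap")
  all_part <- domain_partition("ref", pro = c(1, 2), mature = c(3, 3))
  expect_equal(mean(pr$conservation),
               sum(ds$mean_conservation * ds$n_columns) / sum(ds$n_columns))
  out <- domain_partition("ref", pro = c(1, 2), mature = c(3, 9))
  expect_error(domain_summary(pr, out), "beyond the reference")
})

test_that("modal consensus extraction follows hand-computed modality", {
  aln <- msa(c(a = "AK", b = "AR", c = "VR"))
  expect_equal(as.character(modal_sequence(aln, c("a", "b", "c"))), "AR")
  expect_equal(as.character(modal_sequence(aln, c("a", "a2" = "a"))),
               as.character(modal_sequence(aln, "a")))
  sub <- modal_sequence(aln, c("a", "b"))
  expect_equal(as.character(sub), "AK")  # K vs R tie -> alphabetical
  expect_error(modal_sequence(aln, "zz"), "unknown")

  gappy <- msa(c(a = "A-", b = "A-", c = "A-"))
  ms <- modal_sequence(gappy, c("a", "b", "c"))
  expect_equal(as.character(ms), "A-")
  expect_equal(attr(ms, "all_gap_columns"), 2L)
})

test_that("identity to the reference modal sequence excludes gapped columns", {
  ref_block <- c(r1 = "AAAAAAAAAA", r2 = "AAAAAAAAAA")
  aln <- msa(c(ref_block,
               f_same = "AAAAAAAAAA",
               f_one  = "AAAAAAAAAV",
               f_gap  = "--AAAAAAAA"))
  part <- domain_partition("r1", pro = c(1, 10), mature = NULL)
  gv <- group_vs_modal(aln, c("f_same", "f_one", "f_gap"),
                       c("r1", "r2"), part)
  expect_equal(gv$identity[gv$id == "f_same"], 100)
  expect_equal(gv$identity[gv$id == "f_one"], 90)
  expect_equal(gv$identity[gv$id == "f_gap"], 100)
  expect_equal(gv$n_columns[gv$id == "f_gap"], 8L)
  expect_error(group_vs_modal(aln, "r1", c("r1", "r2"), part), "disjoint")
})

test_that("heat-map table carries exact values and domain labels", {
  aln <- msa(c(ref = "AAKK", s2 = "AVKK", s3 = "AVKR"))
  pr <- site_conservation(aln, reference = "ref")
  part <- domain_partition("ref", pro = c(1, 2), mature = c(3, 4))
  hm <- heatmap_table(pr, part)
  expect_equal(hm$conservation, pr$conservation)
  expect_equal(hm$domain, c("pro", "pro", "mature", "mature"))
  expect_equal(unique(hm$bin_low), 25)
  expect_equal(unique(hm$bin_high), 100)
})

test_that("global mean conservation is invariant under reordering and duplication", {
  aln <- random_msa(6, 25, seed = 9)
  pr <- site_conservation(aln, reference = "s1")
  perm <- msa(unclass(aln)[sample(6), , drop = FALSE])
  pr2 <- site_conservation(perm, reference = "s1")
  expect_equal(mean(pr2$conservation), mean(pr$conservation))
  dup <- unclass(aln)
  rownames(dup) <- paste0(rownames(dup), "_copy")
  both <- msa(rbind(unclass(aln), dup))
  pr3 <- site_conservation(both, reference = "s1")
  expect_equal(mean(pr3$conservation), mean(pr$conservation))
})

test_that("adding a copy of the modal consensus never lowers conservation", {
  set.seed(31)
  for (rep in 1:5) {
    aln <- random_msa(5, 20)
    pr <- site_conservation(aln, reference = "s1")
    consensus <- strsplit(as.character(modal_sequence(
      aln, rownames(aln))), "")[[1]]
    extra <- rbind(unclass(aln), dup = consensus)
    pr2 <- site_conservation(msa(extra), reference = "s1")
    expect_true(all(pr2$conservation >= pr$conservation - 1e-9))
  }
})

test_that("reference coordinates survive filtering via the source alignment", {
  aln <- msa(c(ref = "AKVD", s2 = "-KVD", s3 = "-KVD", s4 = "-KVD"))
  kept <- modal_gap_deletion(aln)   # column 1 dropped (gap-modal)
  pr <- site_conservation(kept, reference = "ref", source = aln)
  expect_equal(pr$ref_pos, c(2L, 3L, 4L))
  expect_equal(attr(pr, "ref_length"), 4L)
  part <- domain_partition("ref", pro = c(1, 2), mature = c(3, 4))
  ds <- domain_summary(pr, part)
  expect_equal(ds$n_columns[ds$domain == "pro"], 1L)
})

test_that("partition JSON round-trips", {
  part <- domain_partition("hu", pro = c(1, 112), mature = c(113, 271),
                           NLS = c(70, 85), HCPR = c(1, 40))
  f <- tempfile(fileext = ".json")
  write_partition(part, f)
  back <- read_partition(f)
  expect_equal(back$reference, "hu")
  expect_equal(back$intervals, part$intervals)
})
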