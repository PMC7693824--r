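test_that("alignment percentages reproduce the printed pinned pairs", {
  al <- global_align("GVLDIFKDAAKQILAHAAEKI", "GVLDIFKDAAKQILAHAAEQI")
  expect_equal(al$identity_pct, 95.2)
  expect_equal(al$similarity_pct, 100.0)
  al2 <- global_align("GLLDFLKAAGKGLVSNLIEKV", "GLLDFLKAAGKGLVSNLLEK")
  expect_equal(al2$identity_pct, 90.5)   # 19/21, gap column in denominator
  expect_equal(al2$similarity_pct, 95.2) # I/L conservative
  self <- global_align("GVVDILKDTGKKLLSHLMEKI", "GVVDILKDTGKKLLSHLMEKI")
  expect_equal(self$identity_pct, 100.0)
  expect_equal(self$similarity_pct, 100.0)
  expect_error(global_align("", "AA"), "non-empty")
})

test_that("alignment counts satisfy the type invariants and symmetry", {
  fam <- cached_family()
  set.seed(7)
  pairs <- cbind(sample(nrow(fam), 8, replace = TRUE),
                 sample(nrow(fam), 8, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- fam$sequence[pairs[k, 1]]; b <- fam$sequence[pairs[k, 2]]
    al <- global_align(a, b); ba <- global_align(b, a)
    expect_lte(al$n_identical, al$n_similar)
    expect_lte(al$n_similar, al$length)
    expect_equal(al$identity_pct, round(100 * al$n_identical / al$length, 1))
    expect_equal(al$identity_pct, ba$identity_pct)
    expect_equal(al$similarity_pct, ba$similarity_pct)
  }
})

test_that("gapless optimal alignments agree with the Hamming oracle", {
  fam <- cached_family()
  lens <- nchar(fam$sequence)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) < 2) next
    for (i in idx) for (j in idx[idx > i]) {
      al <- global_align(fam$sequence[i], fam$sequence[j])
      if (!grepl("-", al$aligned_a, fixed = TRUE) &&
          !grepl("-", al$aligned_b, fixed = TRUE)) {
        hamming <- sum(strsplit(fam$sequence[i], "")[[1]] ==
                         strsplit(fam$sequence[j], "")[[1]])
        expect_equal(al$n_identical, hamming)
      }
    }
  }
})

test_that("conservation: six invariants among the novel five, one in the family", {
  fam <- cached_family()
  novel <- fam$sequence[match(novel_peptides(), fam$name)]
  cp <- conservation_profile(novel)
  expect_equal(cp$invariant_positions, c(1L, 4L, 7L, 11L, 19L, 20L))
  cp28 <- conservation_profile(fam$sequence, mode = "left_flush")
  expect_equal(cp28$invariant_positions, 4L)
  expect_equal(length(cp28$columns), 21L)  # shortest family member
})

test_that("conservation profile frequencies are well-formed and order-free", {
  fam <- cached_family()
  cp <- conservation_profile(fam$sequence)
  for (col in cp$columns) expect_equal(sum(col), 1)
  set.seed(3)
  cp_perm <- conservation_profile(sample(fam$sequence))
  expect_equal(cp_perm$columns, cp$columns)
  expect_equal(cp_perm$consensus, cp$consensus)
  # identical sequences: every position invariant
  twin <- conservation_profile(rep("GVLDIF", 2))
  expect_equal(twin$invariant_positions, 1:6)
  m <- conservation_matrix(cp)
  expect_equal(dim(m), c(20L, 21L))
  expect_equal(unname(colSums(m)), rep(1, 21))
})

test_that("N-terminal motif scan distinguishes strict and relaxed variants", {
  expect_true(motif_scan("GVVDILKDTGKKLLSHLMEKI", strict = TRUE)$match)
  oc4 <- motif_scan("GLLDFVTGVGKDIFAQLIKQI", strict = TRUE)
  expect_false(oc4$match)  # position 7 is Thr
  expect_true(motif_scan("GLLDFVTGVGKDIFAQLIKQI", strict = FALSE)$match)
  expect_false(motif_scan("AAAAAAA", strict = FALSE)$match)
  hit <- motif_scan("GVVDILK")
  expect_equal(hit$span, c(1L, 7L))
  # most family members carry the relaxed motif
  fam <- cached_family()
  hits <- vapply(fam$sequence, function(s) motif_scan(s, strict = FALSE)$match,
                 logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("fragment classification finds the parent span or nothing", {
  cat <- cached_catalogue()
  ocf22 <- substr(cat$sequence[cat$name == "ocellatin-F"], 1, 22)
  hit <- fragment_classify(ocf22, cat)
  expect_equal(hit$parent, "ocellatin-F")
  expect_equal(c(hit$start, hit$end), c(1L, 22L))
  self <- fragment_classify(cat$sequence[cat$name == "ocellatin-11"], cat)
  expect_equal(self$parent, "ocellatin-11")
  expect_equal(c(self$start, self$end), c(1L, 21L))
  # rejection-sampled non-member 21-mer
  set.seed(41)
  repeat {
    rand <- paste(sample(names(KD_HYDROPATHY), 21, replace = TRUE),
                  collapse = "")
    if (!any(vapply(cat$sequence, grepl, logical(1), pattern = rand,
                    fixed = TRUE))) break
  }
  expect_null(fragment_classify(rand, cat))
  expect_error(fragment_classify("GVLDIF", cat[0, ]), "empty")
})
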