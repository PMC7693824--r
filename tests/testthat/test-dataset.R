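test_that("packaged catalogue has 28 family members with the expected flags", {
  cat <- cached_catalogue()
  fam <- cat[cat$group == "family_member", ]
  expect_equal(nrow(fam), 28L)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cat$sequence)))
  expect_true(all(nchar(cat$sequence) >= 13 & nchar(cat$sequence) <= 32))
  expect_false(anyDuplicated(cat$name) > 0)
  # only the long acidic-C-terminus peptides are non-amidated
  expect_setequal(fam$name[!fam$amidated],
                  c("ocellatin-PT6", "ocellatin-PT7", "ocellatin-PT8"))
  oc11 <- fam[fam$name == "ocellatin-11", ]
  expect_equal(oc11$sequence, "GVLDIFKDAAKQILAHAAEKI")
  expect_true(oc11$amidated)
})

test_that("packaged sequences are identical to the family transcription", {
  fam <- cached_family()
  expect_equal(stats::setNames(fam$sequence, fam$name), FAMILY_TRANSCRIPTION)
})

test_that("novel-peptide table letters agree with the family alignment", {
  cat <- cached_catalogue()
  got <- stats::setNames(cat$sequence, cat$name)[names(NOVEL_TABLE_SEQS)]
  expect_equal(got, NOVEL_TABLE_SEQS)
})

test_that("catalogue loader validates input", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("name\tspecies\tsequence\tamidated\tgroup", empty)
  expect_equal(nrow(load_catalogue(empty)), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tspecies\tsequence\tamidated\tgroup",
               "pep-1\tsp\tGVLDZFK\tTRUE\tnovel"), bad)
  expect_error(load_catalogue(bad), "pep-1.*Z")
})

test_that("MIC table parses values and qualifier tokens per the legend", {
  act <- cached_activity()
  oc5 <- act[act$peptide_name == "ocellatin-5" & act$organism == "E_coli", ]
  expect_equal(oc5$mic_ug_ml, 64)
  expect_equal(oc5$mic_um, 28)
  expect_equal(oc5$qualifier, "exact")
  expect_true(all(act$qualifier[act$peptide_name == "ocellatin-K1"] ==
                    "not_informed"))
  expect_true(all(act$qualifier[act$peptide_name == "ocellatin-L2"] ==
                    "inactive"))
  expect_true(all(act$qualifier[act$peptide_name == "ocellatin-S"] %in%
                    c("not_tested", "inactive")))
  pt2 <- act[act$peptide_name == "ocellatin-PT2" & act$organism == "E_coli", ]
  expect_equal(pt2$qualifier, "greater_than")
  expect_equal(pt2$mic_ug_ml, 800)
  # record invariant: values present iff qualifier usable
  usable <- act$qualifier %in% c("exact", "greater_than")
  expect_true(all(!is.na(act$mic_ug_ml[usable]) | !is.na(act$mic_um[usable])))
  expect_true(all(is.na(act$mic_ug_ml[!usable]) & is.na(act$mic_um[!usable])))
  expect_error(load_activity(local({
    f <- tempfile(); writeLines(c(
      "name\tecoli_ug_ml\tecoli_um\tsaureus_ug_ml\tsaureus_um",
      "x\t??\t1\t1\t1"), f); f
  })), "unknown MIC qualifier")
})

test_that("fragment records derive their letters from the parent catalogue", {
  frags <- load_fragments(catalogue = cached_catalogue())
  expect_true(all(frags$group == "fragment"))
  f22 <- frags[frags$name == "ocellatin-F(1-22)", ]
  expect_equal(f22$sequence, substr(FAMILY_TRANSCRIPTION[["ocellatin-F"]], 1, 22))
  s1625 <- frags[frags$name == "ocellatin-S(16-25)", ]
  expect_equal(nchar(s1625$sequence), 10L)
  # every fragment is a substring of its parent
  cat <- cached_catalogue()
  parent_seq <- cat$sequence[match(frags$parent, cat$name)]
  expect_true(all(mapply(grepl, frags$sequence, parent_seq, fixed = TRUE)))
})

test_that("FASTA export round-trips names and sequences", {
  fam <- cached_family()[1:4, ]
  f <- tempfile(fileext = ".fasta")
  write_peptides_fasta(fam, f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(names(back), fam$name)
  expect_equal(as.character(back), stats::setNames(fam$sequence, fam$name))
})
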