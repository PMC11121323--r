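test_that("editable window positions separate target from bystanders", {
  fx <- fixture_AB(); fc <- fixture_C()

  r1 <- fixture_guides(fx, 2, "KKH-nSaCas9-ABE8e")
  ed1 <- editable_positions(r1$guides[[1]], r1$construct)
  expect_equal(ed1$target, 5L)
  expect_equal(ed1$bystanders, c(3L, 7L, 12L, 13L))

  r3 <- fixture_guides(fc, 1, "nSpCas9-ABE8e")
  ed3 <- editable_positions(r3$guides[[1]], r3$construct)
  expect_equal(ed3$target, 8L)
  expect_equal(ed3$bystanders, c(4L, 5L))

  # a window holding only the target has no bystanders
  t <- mini_transcript(list(list(kind = "exon",
                                 sequence = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC")), 1)
  t <- apply_edit(t, 15, "A")
  v <- be_variant(15, "G", "A")
  strategy <- classify_variant("G", "A")[[1]]
  ec <- editor_construct("lab-ABE", "NNN", "3prime", 20L, c(4L, 8L), c("A", "G"))
  g <- suppressWarnings(enumerate_guides(t, v, ec, strategy))
  ed <- editable_positions(g[[1]], ec)
  expect_length(ed$bystanders, 0L)
})

test_that("edit annotation classifies splice, silent and missense outcomes", {
  fx <- fixture_AB()
  mt <- apply_edit(fx$transcript, 2843, "A")

  splice <- annotate_edit(mt, "2843-2", "forward", c(from = "A", to = "G"))
  expect_equal(splice$c_label, "c.2843-2A>G")
  expect_equal(splice$consequence_class, "canonical_splice")
  expect_equal(splice$p_label, "")

  mis <- annotate_edit(mt, 2845, "forward", c(from = "A", to = "G"))
  expect_equal(mis$c_label, "c.2845A>G")
  expect_equal(mis$consequence_class, "missense")
  expect_equal(mis$p_label, "p.Ile949Val")

  sil <- annotate_edit(mt, 2850, "forward", c(from = "A", to = "G"))
  expect_equal(sil$consequence_class, "silent")
  expect_equal(sil$p_label, "p.Ala950Ala")

  # reverse-strand A>G projects as T>C on the coding strand
  fc <- fixture_C()
  mtc <- apply_edit(fc$transcript, 2234, "T")
  rev <- annotate_edit(mtc, 2237, "reverse", c(from = "A", to = "G"))
  expect_equal(rev$c_label, "c.2237T>C")
  expect_equal(rev$consequence_class, "missense")
  expect_equal(rev$p_label, "p.Leu746Pro")

  # splice-region band and deep-intronic class
  donor3 <- annotate_edit(apply_edit(mt, "2842+3", "A"), "2842+3",
                          "forward", c(from = "A", to = "G"))
  expect_equal(donor3$consequence_class, "splice_region")
  deep <- annotate_edit(apply_edit(mt, "2842+9", "A"), "2842+9",
                        "forward", c(from = "A", to = "G"))
  expect_equal(deep$consequence_class, "intronic")

  # incomplete codon at the slice edge warns and is not translated
  mte <- apply_edit(fc$transcript, 2219, "T")
  expect_warning(
    inc <- annotate_edit(mte, 2219, "reverse", c(from = "A", to = "G")),
    "incomplete")
  expect_equal(inc$consequence_class, "incomplete_codon")
  expect_equal(inc$p_label, "")
})

test_that("silent classification is consistent with translation", {
  fx <- fixture_AB()
  mt <- apply_edit(fx$transcript, 2843, "A")
  for (pos in c(2845, 2850, 2851)) {
    e <- annotate_edit(mt, pos, "forward", c(from = "A", to = "G"))
    idx <- e$codon_index
    before <- codon_sequence(mt, idx)$aa
    after <- codon_sequence(apply_edit(mt, pos, "G"), idx)$aa
    expect_equal(e$consequence_class == "silent", before == after)
  }
})

test_that("codon outcome sets reproduce the published slash notation", {
  fx <- fixture_AB()
  r2 <- fixture_guides(fx, 1, "nSaCas9-ABE8e")
  out2 <- codon_outcomes(fx$transcript, r2$guides[[1]], r2$construct, r2$variant)
  expect_length(out2, 2L)
  idx <- vapply(out2, `[[`, 0L, "codon_index")
  expect_equal(idx, c(944L, 945L))
  expect_equal(out2[[1]]$outcomes, c("Q", "R"))
  expect_equal(out2[[1]]$wt_aa, "Q")
  expect_equal(out2[[2]]$outcomes, c("G", "R"))
  expect_equal(out2[[2]]$wt_aa, "G") # wild type, although the baseline is mutant
  expect_equal(out2[[1]]$label, "Q944Q/R")
  expect_equal(out2[[2]]$label, "G945G/R")

  fc <- fixture_C()
  r3 <- fixture_guides(fc, 1, "nSpCas9-ABE8e")
  out3 <- codon_outcomes(fc$transcript, r3$guides[[1]], r3$construct, r3$variant)
  expect_length(out3, 1L)
  expect_equal(out3[[1]]$codon_index, 746L)
  expect_equal(out3[[1]]$outcomes, c("L", "P"))
  # the target codon 745 (no bystander in it) is not a bystander outcome
  expect_false(745L %in% vapply(out3, `[[`, 0L, "codon_index"))
})

test_that("outcome enumeration matches brute-force 2^k translation", {
  fx <- fixture_AB()
  mt <- apply_edit(fx$transcript, 2833, "A")
  r2 <- fixture_guides(fx, 1, "nSaCas9-ABE8e")
  g <- r2$guides[[1]]
  # codon 944 is edited by window positions 5 and 6
  expect_equal(
    oracle_codon_outcomes(mt, g, r2$construct, c(5L, 6L), 944L),
    codon_outcomes(fx$transcript, g, r2$construct, r2$variant)[[1]]$outcomes)
  # codon 945 by positions 7 (target) and 9
  expect_equal(
    oracle_codon_outcomes(mt, g, r2$construct, c(7L, 9L), 945L),
    codon_outcomes(fx$transcript, g, r2$construct, r2$variant)[[2]]$outcomes)

  fc <- fixture_C()
  mtc <- apply_edit(fc$transcript, 2234, "T")
  r3 <- fixture_guides(fc, 1, "nSpCas9-ABE8e")
  expect_equal(
    oracle_codon_outcomes(mtc, r3$guides[[1]], r3$construct, c(4L, 5L), 746L),
    codon_outcomes(fc$transcript, r3$guides[[1]], r3$construct,
                   r3$variant)[[1]]$outcomes)
})

test_that("bystander reports carry the full published lists in window order", {
  fx <- fixture_AB()
  r1 <- fixture_guides(fx, 2, "KKH-nSaCas9-ABE8e")
  br1 <- bystander_report(fx$transcript, r1$guides[[1]], r1$construct, r1$variant)
  expect_equal(br1$edits$window_position, c(3L, 7L, 12L, 13L))
  expect_equal(br1$edits$c_label,
               c("c.2843-2A>G", "c.2845A>G", "c.2850A>G", "c.2851A>G"))
  expect_equal(br1$edits$consequence_class,
               c("canonical_splice", "missense", "silent", "missense"))
  expect_equal(br1$edits$p_label,
               c("", "p.Ile949Val", "p.Ala950Ala", "p.Asn951Asp"))
  expect_true(br1$target_restores_wt)

  r2 <- fixture_guides(fx, 1, "nSaCas9-ABE8e")
  br2 <- bystander_report(fx$transcript, r2$guides[[1]], r2$construct, r2$variant)
  expect_equal(br2$edits$window_position, c(5L, 6L, 9L))
  expect_equal(vapply(br2$outcomes, `[[`, "", "label"),
               c("Q944Q/R", "G945G/R"))
  expect_true(br2$target_restores_wt)

  # bystander count = editable window positions - 1
  ed <- editable_positions(r2$guides[[1]], r2$construct)
  expect_equal(nrow(br2$edits), length(ed$bystanders))
  expect_equal(length(ed$bystanders) + 1L,
               length(c(ed$target, ed$bystanders)))
})

test_that("target edit restores the wild-type amino acid on all fixtures", {
  cases <- list(
    fixture_guides(fixture_AB(), 2, "KKH-nSaCas9-ABE8e"),
    fixture_guides(fixture_AB(), 1, "nSaCas9-ABE8e"),
    fixture_guides(fixture_AB(), 1, "KKH-nSaCas9-ABE8e"),
    fixture_guides(fixture_C(), 1, "nSpCas9-ABE8e")
  )
  for (r in cases) {
    fxt <- if (r$variant$position$base > 2800) fixture_AB() else fixture_C()
    br <- bystander_report(fxt$transcript, r$guides[[1]], r$construct, r$variant)
    expect_true(br$target_restores_wt, label = format_variant(r$variant))
  }
})
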