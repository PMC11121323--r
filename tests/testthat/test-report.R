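test_that("display strings resolve back to protospacer + PAM", {
  cases <- list(
    fixture_guides(fixture_AB(), 2, "KKH-nSaCas9-ABE8e"),
    fixture_guides(fixture_AB(), 1, "nSaCas9-ABE8e"),
    fixture_guides(fixture_C(), 1, "nSpCas9-ABE8e")
  )
  for (r in cases) {
    g <- r$guides[[1]]
    disp <- format_guide_display(g, r$variant, r$strategy, r$construct)
    resolved <- toupper(gsub("\\[.>(.)\\]", "\\1", as.character(disp)))
    expect_identical(resolved, paste0(g$protospacer, g$pam)) # mutant allele kept
    expect_equal(attr(disp, "window"), unname(as.integer(r$construct$window)))
  }
})

test_that("5'-PAM constructs render the PAM before the protospacer", {
  ec <- get_construct("CasMINI-ABE8e")
  t <- random_transcript(1L, c(120L, 120L), c(30L, 40L), 0.4, seed = 5L)
  case <- plant_amenable_variant(t, ec, "ABE", seed = 5L, strand = "forward",
                                 window_position = 5L)
  g <- suppressWarnings(enumerate_guides(case$transcript, case$variant, ec,
                                         case$expected_strategy))
  stopifnot(length(g) >= 1L)
  planted <- Filter(function(x) identical(as.integer(x$pam_range),
                                          as.integer(case$expected$pam_range)),
                    g)[[1]]
  disp <- as.character(format_guide_display(planted, case$variant,
                                            case$expected_strategy))
  expect_match(disp, "^[acgt]{4}")            # 4-nt PAM rendered first, lowercase
  expect_match(disp, ">A\\]", fixed = FALSE)  # bracketed target in the body
  expect_equal(substr(disp, 1, 4), tolower(substr(disp, 1, 4)))
})

test_that("screen_variants produces the fixed-column table for the fixtures", {
  fx <- fixture_AB()
  rep <- suppressWarnings(screen_variants(fx$transcript, fx$variants))
  expect_s3_class(rep, "screen_report")
  expect_equal(names(rep$table),
               c("variant", "construct", "n_guides", "strand", "protospacer",
                 "pam", "target_pos", "display_string", "n_bystanders",
                 "bystander_labels", "codon_outcome_labels", "coding_change"))
  expect_equal(nrow(rep$table), 8L) # 2 variants x 4 constructs

  row <- rep$table[rep$table$variant == "c.2843G>A" &
                     rep$table$construct == "KKH-nSaCas9-ABE8e", ]
  expect_equal(row$n_guides, 1L)
  expect_equal(row$n_bystanders, 4L)
  expect_equal(row$display_string, "TTAG[G>A]TATTGCAAATGCTGTTtttaat")
  expect_equal(row$bystander_labels,
               "c.2843-2A>G;p.Ile949Val;p.Ala950Ala;p.Asn951Asp")
  expect_equal(row$coding_change, "c.2843G>A")

  # regenerating the report is byte-identical
  rep2 <- suppressWarnings(screen_variants(fx$transcript, fx$variants))
  expect_identical(write_report(rep, NULL, "tsv"), write_report(rep2, NULL, "tsv"))
})

test_that("JSON reports round-trip and TSV has header + stable columns", {
  fc <- fixture_C()
  rep <- suppressWarnings(screen_variants(fc$transcript, fc$variants))

  jp <- withr::local_tempfile(fileext = ".json")
  write_report(rep, jp, "json")
  back <- read_report(jp)
  expect_equal(back$table, rep$table)
  expect_equal(back$metadata$registry_hash, rep$metadata$registry_hash)

  tp <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tp, "tsv")
  lines <- readLines(tp)
  expect_equal(strsplit(lines[1], "\t")[[1]][1:3],
               c("variant", "construct", "n_guides"))
  expect_equal(length(lines), nrow(rep$table) + 1L)

  # the guide-3 row reports the reverse-strand guide with coding-strand change
  df <- utils::read.delim(tp, stringsAsFactors = FALSE)
  row <- df[df$construct == "nSpCas9-ABE8e", ]
  expect_equal(row$display_string, "TTGAAGC[G>A]TTCGGACAAACAtgg")
  expect_equal(row$coding_change, "c.2234C>T")
  expect_equal(row$n_guides, 1L)
})

test_that("the CLI screens fixture files end to end", {
  dir <- withr::local_tempdir()
  expect_equal(run_cli(c("fixtures", "--out", dir)), 0L)
  expect_true(file.exists(file.path(dir, "fixture_AB.yaml")))
  expect_true(file.exists(file.path(dir, "fixture_AB_variants.tsv")))

  # single-letter ref/alt columns must survive TSV parsing (no logical coercion)
  vC <- read_variants(file.path(dir, "fixture_C_variants.tsv"), "fixture_C")
  expect_equal(vC[[1]]$ref, "C")
  expect_equal(vC[[1]]$alt, "T")
  cout <- file.path(dir, "report_C.tsv")
  expect_equal(run_cli(c("screen",
                         "--transcript", file.path(dir, "fixture_C.yaml"),
                         "--variants", file.path(dir, "fixture_C_variants.tsv"),
                         "--out", cout)), 0L)
  dfc <- utils::read.delim(cout, stringsAsFactors = FALSE)
  expect_equal(dfc$n_guides[dfc$construct == "nSpCas9-ABE8e"], 1L)

  out <- file.path(dir, "report.tsv")
  code <- run_cli(c("screen",
                    "--transcript", file.path(dir, "fixture_AB.yaml"),
                    "--variants", file.path(dir, "fixture_AB_variants.tsv"),
                    "--out", out))
  expect_equal(code, 0L)
  df <- utils::read.delim(out, stringsAsFactors = FALSE)
  expect_equal(df$n_guides[df$variant == "c.2843G>A" &
                             df$construct == "KKH-nSaCas9-ABE8e"], 1L)

  jout <- file.path(dir, "report.json")
  expect_equal(run_cli(c("screen",
                         "--transcript", file.path(dir, "fixture_AB.yaml"),
                         "--variants", file.path(dir, "fixture_AB_variants.tsv"),
                         "--format", "json", "--out", jout)), 0L)
  expect_equal(sum(read_report(jout)$table$n_guides), 3L)
})

test_that("the CLI exits 2 on validation problems", {
  dir <- withr::local_tempdir()
  run_cli(c("fixtures", "--out", dir))

  empty <- file.path(dir, "empty.tsv")
  writeLines("transcript_name\tc_position\tref\talt", empty)
  expect_message(
    code <- run_cli(c("screen",
                      "--transcript", file.path(dir, "fixture_AB.yaml"),
                      "--variants", empty)),
    "no variants")
  expect_equal(code, 2L)

  expect_equal(suppressMessages(run_cli(character(0))), 2L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("screen", "--variants", empty))), 2L)
})

test_that("the CLI writes simulated planted bundles with ground truth", {
  dir <- withr::local_tempdir()
  expect_equal(run_cli(c("simulate", "--out", dir, "--n", "2", "--seed", "9")), 0L)
  expect_true(file.exists(file.path(dir, "planted_001.yaml")))
  truth <- jsonlite::fromJSON(file.path(dir, "planted_001_truth.json"))
  expect_equal(truth$construct, "nSpCas9-ABE8e")
  t <- read_transcript(file.path(dir, "planted_001.yaml"))
  v <- read_variants(file.path(dir, "planted_001_variants.tsv"), t$name)
  expect_length(v, 1L)
  strategy <- classify_variant(v[[1]]$ref, v[[1]]$alt)[[1]]
  g <- suppressWarnings(enumerate_guides(t, v[[1]],
                                         get_construct(truth$construct),
                                         strategy))
  expect_true(truth$target_window_position %in%
                vapply(g, `[[`, 0L, "target_window_position"))
})
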