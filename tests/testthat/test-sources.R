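make_fixture_file <- function(dir, name, seed) {
  fx <- generate_star_fixture(fixture_spec(seed))
  path <- file.path(dir, name)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(fx$text, path, sep = "")
  fx
}

test_that("source kinds are inferred with deterministic precedence", {
  d <- withr::local_tempdir()
  f <- file.path(d, "one.str"); writeLines("data_1", f)
  expect_identical(star_source(f)$kind, "LOCAL_FILE")
  expect_identical(star_source(d)$kind, "LOCAL_DIR")
  z <- file.path(d, "x.zip"); file.create(z)
  expect_identical(star_source(z)$kind, "LOCAL_ARCHIVE")
  expect_identical(star_source("http://example.org/a.str")$kind, "URL_FILE")
  expect_identical(star_source("file:///tmp/a.tar.gz")$kind, "URL_ARCHIVE")
  expect_identical(star_source("18569")$kind, "BMRB_ID")
  # an existing local path that is all digits wins over the BMRB id reading
  digits <- file.path(d, "12345"); writeLines("data_1", digits)
  withr::local_dir(d)
  expect_identical(star_source("12345")$kind, "LOCAL_FILE")
  expect_error(star_source("no/such/thing_xyz"), "cannot resolve")
})

test_that("files, directories and archives resolve to named documents", {
  d <- withr::local_tempdir()
  make_fixture_file(d, "b.str", 1)
  make_fixture_file(d, "a.str", 2)
  make_fixture_file(d, "sub/c.str", 3)
  writeLines("ignore me", file.path(d, "notes.md"))
  writeLines("hidden", file.path(d, ".hidden.str"))

  members <- resolve_source(star_source(d))
  expect_identical(vapply(members, `[[`, character(1), "name"),
                   c("a.str", "b.str", "sub/c.str"))
  one <- resolve_source(star_source(file.path(d, "a.str")))
  expect_length(one, 1L)
  expect_match(one[[1]]$read(), "^data_")

  empty <- withr::local_tempdir()
  expect_length(resolve_source(star_source(empty)), 0L)
})

test_that("tar and zip archives stream members without manual extraction", {
  for (ext in c(".zip", ".tar.gz", ".tar.bz2")) {
    arc <- file.path(withr::local_tempdir(), paste0("corpus", ext))
    generate_corpus(5, 11, arc)
    members <- resolve_source(star_source(arc))
    expect_length(members, 5L)
    expect_identical(vapply(members, `[[`, character(1), "name"),
                     sprintf("fixture_%04d.str", 1:5))
    expect_match(members[[3]]$read(), "^data_")
  }
})

test_that("entry streaming is lazy: k entries read k documents", {
  d <- withr::local_tempdir()
  for (i in 1:6) make_fixture_file(d, sprintf("f%d.str", i), 700 + i)
  s <- read_star_entries(d)
  expect_identical(s$state$docs_read, 0L)
  e1 <- next_entry(s)
  expect_identical(s$state$docs_read, 1L)
  invisible(next_entry(s)); invisible(next_entry(s))
  expect_identical(s$state$docs_read, 3L)
  rest <- collect_entries(s)
  expect_length(rest, 3L)
  expect_identical(s$state$docs_read, 6L)
  expect_null(next_entry(s))
})

test_that("mixed NMR-STAR and JSON documents are autodetected", {
  d <- file.path(withr::local_tempdir(), "mixed")
  idx <- generate_corpus(8, 21, d, format = "mixed")
  entries <- collect_entries(read_star_entries(d))
  expect_length(entries, 8L)
  for (i in seq_along(entries)) {
    exp <- from_json_star(idx$files[[i]]$entry_json)
    expect_true(structurally_equal(entries[[i]], exp))
    expect_identical(attr(entries[[i]], "source"), idx$files[[i]]$name)
  }
})

test_that("multiple heterogeneous sources stream in order", {
  d <- withr::local_tempdir()
  f1 <- make_fixture_file(d, "single.str", 31)
  sub <- file.path(d, "dirsrc")
  make_fixture_file(sub, "x.str", 32)
  make_fixture_file(sub, "y.str", 33)
  arc <- file.path(d, "two.tar.gz")
  generate_corpus(2, 34, arc)
  entries <- collect_entries(
    read_star_entries(c(file.path(d, "single.str"), sub, arc)))
  expect_length(entries, 5L)  # 1 file + 2 in the directory + 2 in the archive
  expect_true(structurally_equal(entries[[1]], f1$entry))
})

test_that("parse failures obey the on_error policy", {
  d <- withr::local_tempdir()
  make_fixture_file(d, "ok.str", 41)
  writeLines("definitely not star", file.path(d, "broken.str"))
  expect_error(collect_entries(read_star_entries(d)), "before data_")
  s <- read_star_entries(d, on_error = "skip")
  expect_warning(entries <- collect_entries(s), "skipping")
  expect_length(entries, 1L)
  expect_identical(s$state$failed, 1L)
})

test_that("BMRB ids resolve through the configured URL template", {
  d <- withr::local_tempdir()
  fx <- make_fixture_file(d, "bmr18569_3.str", 51)
  fx21 <- make_fixture_file(d, "bmr18569_21.str", 52)
  withr::local_options(
    nmrstar.bmrb_url_template_3_1 = paste0("file://", d, "/bmr%s_3.str"),
    nmrstar.bmrb_url_template_2_1 = paste0("file://", d, "/bmr%s_21.str"))
  e31 <- next_entry(read_star_entries("18569"))
  expect_true(structurally_equal(e31, fx$entry))
  expect_identical(attr(e31, "source"), "bmrb:18569")
  e21 <- next_entry(read_star_entries("18569", bmrb_version = "2.1"))
  expect_true(structurally_equal(e21, fx21$entry))
})

test_that("file:// URLs resolve to single documents", {
  d <- withr::local_tempdir()
  fx <- make_fixture_file(d, "u.str", 61)
  e <- next_entry(read_star_entries(paste0("file://", d, "/u.str")))
  expect_true(structurally_equal(e, fx$entry))
})
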