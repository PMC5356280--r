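test_that("minimal documents parse to the expected structure", {
  e <- parse_star("data_X\nsave_A\n_T v\nsave_\n")
  expect_s3_class(e, "star_entry")
  expect_identical(e$data, "X")
  expect_identical(names(e), c("data", "A"))
  expect_identical(e$A$`_T`, "v")
})

test_that("saveframes alternate tags and delegate loops in order", {
  doc <- paste0("data_9\n",
                "save_one\n_A 1\n_B 2\n",
                "loop_\n_a\n_b\n1 2\n3 4\nstop_\n",
                "loop_\n_c\nx\nstop_\nsave_\n",
                "save_two\n_C 3\nsave_\n",
                "save_three\nsave_\n")
  e <- parse_star(doc)
  expect_identical(names(e), c("data", "one", "two", "three"))
  expect_identical(names(e$one), c("_A", "_B", "loop_0", "loop_1"))
  l0 <- e$one$loop_0
  expect_identical(l0$fields, c("_a", "_b"))
  expect_identical(l0$records,
                   list(c(`_a` = "1", `_b` = "2"), c(`_a` = "3", `_b` = "4")))
  expect_identical(e$one$loop_1$records, list(c(`_c` = "x")))
})

test_that("multiline tag values keep internal newlines", {
  e <- parse_star("data_1\nsave_A\n_Seq\n;\nMKVL\nAHGI\n;\nsave_\n")
  expect_identical(e$A$`_Seq`, "MKVL\nAHGI")
})

test_that("tags and loops at data-block level are kept in the entry body", {
  e <- parse_star("data_1\n_Top level\nloop_\n_f\nv1\nv2\nstop_\nsave_A\nsave_\n")
  expect_identical(names(e), c("data", "_Top", "loop_0", "A"))
  expect_identical(e$`_Top`, "level")
  expect_identical(e$loop_0$records, list(c(`_f` = "v1"), c(`_f` = "v2")))
})

test_that("structural format errors are reported with context", {
  expect_error(parse_star("just words\n"), "before data_")
  expect_error(parse_star(""), "no data_ header")
  expect_error(parse_star("data_1\nsave_A\n_T\nsave_\n"),
               "tag '_T' has no value")
  expect_error(parse_star("data_1\nsave_A\n_T _U v\nsave_\n"), "_T")
  expect_error(parse_star("data_1\nsave_A\n_T v\n"), "missing save_")
  expect_error(parse_star("data_1\nsave_A\nloop_\nv1\nstop_\nsave_\n"),
               "no field tags")
  expect_error(parse_star("data_1\nsave_A\nloop_\n_f\nv1\n_g\nstop_\nsave_\n"),
               "among loop values")
})

test_that("stray values are an error in strict mode, skipped in lenient", {
  doc <- "data_1\nsave_A\norphan\n_T v\nsave_\n"
  expect_error(parse_star(doc), "without a preceding tag")
  expect_warning(e <- parse_star(doc, strict = FALSE), "stray value")
  expect_identical(e$A$`_T`, "v")
})

test_that("duplicate tags error in strict mode, keep first in lenient", {
  doc <- "data_1\nsave_A\n_T v1\n_T v2\nsave_\n"
  expect_error(parse_star(doc), "duplicate tag '_T'")
  expect_warning(e <- parse_star(doc, strict = FALSE), "keeping first")
  expect_identical(e$A$`_T`, "v1")
})

test_that("ragged loops error in strict mode, truncate in lenient", {
  doc <- "data_1\nsave_A\nloop_\n_a\n_b\n1 2 3\nstop_\nsave_\n"
  expect_error(parse_star(doc), "not divisible")
  expect_warning(e <- parse_star(doc, strict = FALSE), "truncating")
  expect_identical(e$A$loop_0$records, list(c(`_a` = "1", `_b` = "2")))
})

test_that("empty loops are tolerated with a warning", {
  expect_warning(
    e <- parse_star("data_1\nsave_A\nloop_\n_a\nstop_\nsave_\n"),
    "empty loop")
  expect_identical(e$A$loop_0$fields, "_a")
  expect_length(e$A$loop_0$records, 0L)
})

test_that("a loop terminated by save_ is accepted only in lenient mode", {
  doc <- "data_1\nsave_A\nloop_\n_a\nv1\nsave_\n"
  expect_error(parse_star(doc), "unexpected SAVE_END")
  expect_warning(e <- parse_star(doc, strict = FALSE), "missing stop_")
  expect_identical(e$A$loop_0$records, list(c(`_a` = "v1")))
})

test_that("only the first of multiple data blocks is parsed, with a warning", {
  doc <- "data_1\nsave_A\n_T v\nsave_\ndata_2\nsave_B\nsave_\n"
  expect_warning(e <- parse_star(doc), "multiple data_ blocks")
  expect_identical(e$data, "1")
  expect_identical(names(e), c("data", "A"))
})

test_that("comments are captured as comment_N members when requested", {
  doc <- "data_1\n# top note\nsave_A\n# inner\n_T v\nsave_\n"
  e <- parse_star(doc)
  expect_false(any(grepl("^comment_", unlist(lapply(e, names)))))
  ec <- parse_star(doc, capture_comments = TRUE)
  expect_identical(names(ec), c("data", "comment_0", "A"))
  expect_identical(ec$comment_0, "top note")
  expect_identical(names(ec$A), c("comment_0", "_T"))
  expect_identical(star_counts(ec)$comments, 2L)
})

test_that("parsed fixtures match the generator's ground truth", {
  flags <- c("EMBEDDED_SEMICOLON", "MULTILINE_THEN_LOOP",
             "QUOTES_IN_VALUES", "EMPTY_LOOP")
  for (s in seq(301, 340)) {
    picked <- unique(flags[c(s %% 4L + 1L, (s %/% 4L) %% 4L + 1L)])
    fx <- generate_star_fixture(fixture_spec(s, edge_flags = picked))
    p <- suppressWarnings(parse_star(fx$text))
    expect_identical(validate_star(p), character(0))
    expect_true(structurally_equal(p, fx$entry), info = paste("seed", s))
    expect_identical(star_counts(p), fx$manifest$counts)
    expect_identical(star_key_order(p), unlist(fx$manifest$key_order))
  }
})

test_that("loop value counts equal fields x records for random loops", {
  for (s in seq(401, 420)) {
    fx <- generate_star_fixture(fixture_spec(s, n_saveframes = 1L,
                                             loops_per_saveframe = c(1L, 3L)))
    toks <- tokenize(fx$text)
    p <- suppressWarnings(parse_star(fx$text))
    shapes <- star_loop_shapes(p)
    # independently count VALUE tokens inside each loop_ ... stop_ span
    in_loop <- FALSE; counts <- integer(0); k <- 0L
    for (i in seq_len(length(toks))) {
      kind <- toks$kind[i]
      if (kind == "LOOP_BEGIN") { in_loop <- TRUE; k <- k + 1L; counts[k] <- 0L }
      else if (kind == "LOOP_END") in_loop <- FALSE
      else if (in_loop && kind == "VALUE") counts[k] <- counts[k] + 1L
    }
    expect_identical(length(shapes), length(counts))
    expect_identical(counts,
                     vapply(shapes, function(s) s$n_fields * s$n_records,
                            integer(1)))
  }
})
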