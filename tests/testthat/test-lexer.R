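test_that("keywords, tags and plain values classify correctly", {
  df <- tok_df("data_18569\nsave_entry\n_Tag val . ? $frame\nloop_\nstop_\nsave_\n")
  expect_identical(df$kind,
                   c("DATA_HEADER", "SAVE_BEGIN", "TAG", "VALUE", "VALUE",
                     "VALUE", "VALUE", "LOOP_BEGIN", "LOOP_END", "SAVE_END"))
  expect_identical(df$text[1:2], c("18569", "entry"))
  # placeholders and framecodes survive verbatim
  expect_identical(df$text[4:7], c("val", ".", "?", "$frame"))
})

test_that("keywords match case-insensitively", {
  df <- tok_df("DATA_9\nSAVE_x\nLOOP_\nStop_\nSAVE_\n")
  expect_identical(df$kind, c("DATA_HEADER", "SAVE_BEGIN", "LOOP_BEGIN",
                              "LOOP_END", "SAVE_END"))
  # a bare "data_" with no identifier is just a word, not a header
  expect_identical(tok_df("data_\n")$kind, "VALUE")
})

test_that("quoted values close only at quote followed by whitespace", {
  df <- tok_df("'it's fine' x")
  expect_identical(df$kind, c("VALUE", "VALUE"))
  expect_identical(df$text, c("it's fine", "x"))
  df2 <- tok_df('"say "hi"" y')
  expect_identical(df2$text, c('say "hi"', "y"))
  expect_identical(tok_df("''")$text, "")
  # a quote inside a bare word is literal content
  expect_identical(tok_df("ab'cd\n")$text, "ab'cd")
})

test_that("multiline blocks keep interior semicolons and newlines", {
  df <- tok_df(";\nHelix is ;near the C-term\n;\n")
  expect_identical(df$kind, "VALUE")
  expect_identical(df$text, "Helix is ;near the C-term")
  df2 <- tok_df(";\nline one\nline two\n;\n")
  expect_identical(df2$text, "line one\nline two")
  # opening-line content and blank interior lines are preserved
  expect_identical(tok_df(";rest\nmore\n;\n")$text, "rest\nmore")
  expect_identical(tok_df(";\n\nx\n;\n")$text, "\nx")
  expect_identical(tok_df(";\n;\n")$text, "")
})

test_that("closing semicolon line may be followed directly by tokens", {
  df <- tok_df(";\ntext\n;loop_\n_T\nv\nstop_\n")
  expect_identical(df$kind,
                   c("VALUE", "LOOP_BEGIN", "TAG", "VALUE", "LOOP_END"))
  expect_identical(df$text[1], "text")
})

test_that("multiline block at end of file needs no trailing newline", {
  df <- tok_df("_T\n;\nfinal text\n;")
  expect_identical(df$kind, c("TAG", "VALUE"))
  expect_identical(df$text[2], "final text")
})

test_that("comments are positional and off by default", {
  expect_identical(nrow(tok_df("# whole line\n")), 0L)
  df <- tok_df("# note here\nv1 #trailing\n", emit_comments = TRUE)
  expect_identical(df$kind, c("COMMENT", "VALUE", "COMMENT"))
  expect_identical(df$text[1], "note here")
  # '#' inside words, quotes and blocks is content
  expect_identical(tok_df("a#b '# quoted' ;x\n")$text,
                   c("a#b", "# quoted", ";x"))
  expect_identical(tok_df(";\n# not a comment\n;\n")$text, "# not a comment")
})

test_that("CRLF is normalized before column-1 semicolon detection", {
  expect_token_stream_equal(tokenize(";\r\na b\r\n;\r\n"),
                            tokenize(";\na b\n;\n"))
})

test_that("lexing errors carry line numbers", {
  err <- tryCatch(tokenize("ok\n'unterminated\n"), error = identity)
  expect_s3_class(err, "nmrstar_lex_error")
  expect_identical(err$line, 2L)
  expect_match(conditionMessage(err), "line 2")
  err2 <- tryCatch(tokenize("x\n;\nnever closed\n"), error = identity)
  expect_s3_class(err2, "nmrstar_lex_error")
  expect_identical(err2$line, 2L)
})

test_that("line numbers are 1-based and non-decreasing", {
  toks <- tokenize("data_1\n\n_T\n;\nm\n;\nv w\n")
  expect_identical(toks$line[1], 1L)
  expect_true(all(diff(toks$line) >= 0L))
  expect_identical(toks$line[length(toks)], 7L)
})

test_that("empty input and invalid UTF-8 are handled", {
  expect_identical(length(tokenize("")), 0L)
  bad <- rawToChar(as.raw(c(0x61, 0xff, 0x62)))
  expect_warning(toks <- tokenize(bad), "UTF-8")
  expect_identical(length(toks), 1L)
})

test_that("production lexer matches the character automaton on random documents", {
  for (s in 1:300) {
    expect_true(lexers_agree(generate_lex_document(s)),
                info = paste("seed", s))
  }
})

test_that("the automaton is single-pass (bounded character touches)", {
  for (s in c(3L, 17L, 101L)) {
    d <- generate_lex_document(s)
    r <- tokenize_reference(d)
    expect_lte(attr(r, "touches"), 3L * nchar(gsub("\r\n", "\n", d)))
  }
})

test_that("re-tokenizing a re-quoted stream is stable (lex idempotence)", {
  for (s in c(5L, 23L)) {
    toks <- tokenize(generate_lex_document(s))
    vals <- toks$text[toks$kind == "VALUE"]
    vals <- vals[!grepl("(^|\n);", vals)]
    doc2 <- paste(vapply(vals, format_value, character(1)), collapse = " ")
    re <- tokenize(paste0(doc2, "\n"))
    expect_identical(re$text[re$kind == "VALUE"], unname(vals))
  }
})
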