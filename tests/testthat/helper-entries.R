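# shared builders for hand-made entries and documents

minimal_entry <- function() {
  star_entry("X", A = star_saveframe(`_T` = "v"))
}

two_loop_entry <- function() {
  star_entry(
    "77",
    frame_a = star_saveframe(
      `_Name` = "alpha",
      loop_0 = star_loop(c("_a", "_b"),
                         list(c(`_a` = "1", `_b` = "2"),
                              c(`_a` = "3", `_b` = "4"))),
      loop_1 = star_loop("_c", list(c(`_c` = "only")))),
    frame_b = star_saveframe(`_Note` = "two words")
  )
}

# tokens as a plain data.frame without line numbers, for compact assertions
tok_df <- function(text, ...) {
  df <- as.data.frame(tokenize(text, ...))
  df[c("kind", "text")]
}

expect_token_stream_equal <- function(a, b) {
  expect_identical(unclass(a)[c("kind", "text", "line")],
                   unclass(b)[c("kind", "text", "line")])
}

# both-lexers comparison allowing for matched errors
lexers_agree <- function(doc, emit_comments = TRUE) {
  a <- tryCatch(tokenize(doc, emit_comments), error = function(e) e)
  b <- tryCatch(tokenize_reference(doc, emit_comments), error = function(e) e)
  if (inherits(a, "error") || inherits(b, "error"))
    return(inherits(a, "error") && inherits(b, "error"))
  identical(unclass(a)[c("kind", "text", "line")],
            unclass(b)[c("kind", "text", "line")])
}
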