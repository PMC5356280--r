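#' @title STAR lexical analysis
#'
#' @description
#' `tokenize()` converts NMR-STAR document text into an ordered stream of
#' classified tokens.  The STAR grammar is whitespace-delimited with four
#' quoting forms, and the subtleties live entirely in the quoting rules:
#'
#' * A single- or double-quoted string closes only at a quote character that
#'   is immediately followed by whitespace or end-of-line; a quote anywhere
#'   else is literal content (`'it's fine'` is one value).
#' * A `;` in column 1 opens a multiline value that runs to the next `;` in
#'   column 1.  Interior semicolons not in column 1 are content, the closing
#'   delimiter line may be immediately followed by further tokens
#'   (`;loop_`), and the block may sit at end-of-file without a trailing
#'   newline.  These are exactly the three cases known to break naive
#'   regex-based NMR-STAR parsers.
#'
#' Keywords `data_`/`save_`/`loop_`/`stop_` are matched case-insensitively.
#' `.` and `?` (null/unknown placeholders) and `$framecode` references are
#' ordinary VALUE tokens preserved verbatim, so that a parsed entry can be
#' re-serialized losslessly.
#'
#' @name star-lexer
NULL

lex_error <- function(msg, line) {
  stop(errorCondition(sprintf("NMR-STAR lexing error at line %d: %s", line, msg),
                      line = line,
                      class = c("nmrstar_lex_error", "nmrstar_error")))
}

new_token_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$kind <- character(64L)
  env$text <- character(64L)
  env$line <- integer(64L)
  env$n <- 0L
  env
}

sink_push <- function(env, kind, text, line) {
  n <- env$n + 1L
  if (n > length(env$kind)) {
    len <- length(env$kind) * 2L
    length(env$kind) <- len
    length(env$text) <- len
    length(env$line) <- len
  }
  env$kind[n] <- kind
  env$text[n] <- text
  env$line[n] <- line
  env$n <- n
  invisible(env)
}

sink_tokens <- function(env) {
  idx <- seq_len(env$n)
  structure(list(kind = env$kind[idx], text = env$text[idx],
                 line = env$line[idx]),
            class = "star_tokens")
}

#' @export
length.star_tokens <- function(x) length(x$kind)

#' @export
as.data.frame.star_tokens <- function(x, ...) {
  data.frame(kind = x$kind, text = x$text, line = x$line,
             stringsAsFactors = FALSE)
}

#' @export
print.star_tokens <- function(x, ...) {
  cat("<star_tokens> ", length(x), " tokens\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

# Classify a whitespace-delimited bare word.  Returns c(kind, text).
classify_word <- function(w) {
  lw <- tolower(w)
  if (lw == "loop_") return(c("LOOP_BEGIN", ""))
  if (lw == "stop_") return(c("LOOP_END", ""))
  if (lw == "save_") return(c("SAVE_END", ""))
  if (startsWith(lw, "save_")) return(c("SAVE_BEGIN", substring(w, 6L)))
  if (startsWith(lw, "data_") && nchar(w) > 5L)
    return(c("DATA_HEADER", substring(w, 6L)))
  if (startsWith(w, "_")) return(c("TAG", w))
  c("VALUE", w)
}

# Multiline block content rule: everything between the opening ';' and the
# closing column-1 ';', excluding the newline immediately before the closing
# delimiter, and stripping one leading newline when present (i.e. when the
# opening ';' has no trailing content on its own line).
assemble_multiline <- function(openrest, mids) {
  value <- paste(c(openrest, mids), collapse = "\n")
  if (!nzchar(openrest) && length(mids) > 0L) value <- substring(value, 2L)
  value
}

scan_inline <- function(s, lineno, sink, emit_comments) {
  rest <- s
  repeat {
    nws <- attr(regexpr("^[ \t]*", rest), "match.length")
    if (nws > 0L) rest <- substring(rest, nws + 1L)
    if (!nzchar(rest)) break
    c1 <- substr(rest, 1L, 1L)
    if (c1 == "#") {
      if (emit_comments)
        sink_push(sink, "COMMENT", sub("^#[ ]?", "", rest), lineno)
      break
    }
    if (c1 == "'" || c1 == "\"") {
      pat <- if (c1 == "'")
        "^'((?:[^']|'(?![ \t]|$))*)'(?=[ \t]|$)"
      else
        "^\"((?:[^\"]|\"(?![ \t]|$))*)\"(?=[ \t]|$)"
      m <- regexpr(pat, rest, perl = TRUE)
      if (m == -1L)
        lex_error("unterminated quoted string", lineno)
      cs <- attr(m, "capture.start")[1L]
      cl <- attr(m, "capture.length")[1L]
      sink_push(sink, "VALUE", substr(rest, cs, cs + cl - 1L), lineno)
      rest <- substring(rest, attr(m, "match.length") + 1L)
      next
    }
    m <- regexpr("^[^ \t]+", rest)
    w <- substr(rest, 1L, attr(m, "match.length"))
    kt <- classify_word(w)
    sink_push(sink, kt[1L], kt[2L], lineno)
    rest <- substring(rest, attr(m, "match.length") + 1L)
  }
  invisible(NULL)
}

#' Tokenize NMR-STAR document text
#'
#' Splits a complete NMR-STAR document into an ordered stream of classified
#' tokens, applying the full STAR quoting grammar (see [star-lexer]).  CRLF
#' line endings are normalized to LF before column-1 semicolon detection, and
#' text with invalid UTF-8 byte sequences is repaired by replacement (with a
#' warning) rather than aborting.
#'
#' @param text Character scalar: the complete document (may be empty).
#' @param emit_comments If `TRUE`, `#` comments are emitted as COMMENT tokens;
#'   otherwise they are discarded.  A `#` is a comment only at the start of a
#'   whitespace-delimited position; inside quoted or multiline values it is
#'   content.
#' @return A `star_tokens` object: parallel vectors `kind` (one of
#'   DATA_HEADER, SAVE_BEGIN, SAVE_END, LOOP_BEGIN, LOOP_END, TAG, VALUE,
#'   COMMENT), `text` (payload with delimiters removed; for DATA_HEADER and
#'   SAVE_BEGIN the identifier after the keyword prefix) and `line` (1-based
#'   line of token start, non-decreasing).
#' @examples
#' tokenize("data_18569\nsave_entry\n_Title 'an example'\nsave_\n")
#' @seealso [tokenize_reference()] for the brute-force verification automaton.
#' @export
tokenize <- function(text, emit_comments = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!all(validUTF8(text))) {
    warning("input contains invalid UTF-8 byte sequences; replacing them")
    text <- iconv(text, from = "UTF-8", to = "UTF-8", sub = "�")
  }
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  sink <- new_token_sink()
  if (!nzchar(text)) return(sink_tokens(sink))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  nlines <- length(lines)
  i <- 1L
  while (i <= nlines) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      openrest <- substring(line, 2L)
      j <- i + 1L
      while (j <= nlines && !startsWith(lines[[j]], ";")) j <- j + 1L
      if (j > nlines)
        lex_error("unterminated multiline value (no closing ';' in column 1)", i)
      mids <- if (j > i + 1L) lines[(i + 1L):(j - 1L)] else character(0)
      sink_push(sink, "VALUE", assemble_multiline(openrest, mids), i)
      # the closing ';' line may carry further tokens (e.g. ";loop_")
      scan_inline(substring(lines[[j]], 2L), j, sink, emit_comments)
      i <- j + 1L
    } else {
      scan_inline(line, i, sink, emit_comments)
      i <- i + 1L
    }
  }
  sink_tokens(sink)
}
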