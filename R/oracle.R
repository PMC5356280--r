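#' Brute-force character-automaton tokenizer (verification reference)
#'
#' An independently written, deliberately simple single-pass state machine
#' over individual characters that implements the same STAR token grammar as
#' [tokenize()].  It exists purely as a cross-check: the production lexer is
#' line- and regex-driven for speed, while this automaton walks the document
#' one character at a time with explicit states (between-tokens, word,
#' comment, quoted, multiline).  Agreement between the two on randomized
#' documents is part of the package's verification suite.
#'
#' The automaton also counts how many times it examines a character
#' (`attr(result, "touches")`), demonstrating that tokenization is single
#' pass: the count is bounded by a small constant multiple of the document
#' length.
#'
#' @param text Character scalar: complete document.
#' @param emit_comments If `TRUE`, emit COMMENT tokens.
#' @return A `star_tokens` object with attribute `"touches"` (number of
#'   character examinations performed).
#' @seealso [tokenize()]
#' @export
tokenize_reference <- function(text, emit_comments = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  kinds <- character(0); texts <- character(0); lines <- integer(0)
  emit <- function(kind, txt, ln) {
    kinds[[length(kinds) + 1L]] <<- kind
    texts[[length(texts) + 1L]] <<- txt
    lines[[length(lines) + 1L]] <<- ln
  }
  # independent keyword classification (lookup table rather than prefix logic)
  emit_word <- function(from, to, ln) {
    w <- substr(text, from, to)
    lw <- tolower(w)
    exact <- c(loop_ = "LOOP_BEGIN", stop_ = "LOOP_END", save_ = "SAVE_END")
    if (lw %in% names(exact)) {
      emit(exact[[lw]], "", ln)
    } else if (nchar(w) > 5L && substr(lw, 1L, 5L) == "save_") {
      emit("SAVE_BEGIN", substr(w, 6L, nchar(w)), ln)
    } else if (nchar(w) > 5L && substr(lw, 1L, 5L) == "data_") {
      emit("DATA_HEADER", substr(w, 6L, nchar(w)), ln)
    } else if (substr(w, 1L, 1L) == "_") {
      emit("TAG", w, ln)
    } else {
      emit("VALUE", w, ln)
    }
  }

  touches <- 0L
  i <- 1L
  line <- 1L
  col <- 1L           # column of chars[i]
  while (i <= n) {
    ch <- chars[[i]]; touches <- touches + 1L
    if (ch == "\n") {
      i <- i + 1L; line <- line + 1L; col <- 1L
    } else if (ch == " " || ch == "\t") {
      i <- i + 1L; col <- col + 1L
    } else if (ch == ";" && col == 1L) {
      # multiline: scan forward for "\n;" (or error at EOF)
      start_line <- line
      content_from <- i + 1L
      j <- i + 1L
      close_at <- NA_integer_
      while (j <= n) {
        touches <- touches + 1L
        if (chars[[j]] == "\n") {
          line <- line + 1L
          if (j + 1L <= n) { touches <- touches + 1L }
          if (j + 1L <= n && chars[[j + 1L]] == ";") { close_at <- j; break }
        }
        j <- j + 1L
      }
      if (is.na(close_at))
        lex_error("unterminated multiline value (no closing ';' in column 1)",
                  start_line)
      raw <- if (close_at - 1L >= content_from)
        substr(text, content_from, close_at - 1L) else ""
      if (substr(raw, 1L, 1L) == "\n") raw <- substr(raw, 2L, nchar(raw))
      emit("VALUE", raw, start_line)
      i <- close_at + 2L   # past the closing ';'
      col <- 2L            # rest of the closing line may hold more tokens
    } else if (ch == "#") {
      start <- i
      while (i <= n && chars[[i]] != "\n") { touches <- touches + 1L; i <- i + 1L }
      if (emit_comments) {
        txt <- substr(text, start + 1L, i - 1L)
        emit("COMMENT", sub("^ ", "", txt), line)
      }
      # leave the newline for the main loop
      col <- col + (i - start)
    } else if (ch == "'" || ch == "\"") {
      q <- ch
      j <- i + 1L
      close_at <- NA_integer_
      while (j <= n) {
        touches <- touches + 1L
        cj <- chars[[j]]
        if (cj == "\n") break
        if (cj == q) {
          nxt <- if (j + 1L <= n) chars[[j + 1L]] else "\n"
          touches <- touches + 1L
          if (nxt == " " || nxt == "\t" || nxt == "\n") { close_at <- j; break }
        }
        j <- j + 1L
      }
      if (is.na(close_at))
        lex_error("unterminated quoted string", line)
      emit("VALUE", if (close_at - 1L >= i + 1L)
        substr(text, i + 1L, close_at - 1L) else "", line)
      col <- col + (close_at + 1L - i)
      i <- close_at + 1L
    } else {
      start <- i
      while (i <= n && !(chars[[i]] %in% c(" ", "\t", "\n"))) {
        touches <- touches + 1L
        i <- i + 1L
      }
      emit_word(start, i - 1L, line)
      col <- col + (i - start)
    }
  }
  structure(list(kind = kinds, text = texts, line = lines),
            class = "star_tokens", touches = touches)
}
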