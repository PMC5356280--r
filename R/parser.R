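#' @title Token-driven construction of NMR-STAR entries
#'
#' @description
#' The parser consumes the token stream through a pull-based cursor and
#' builds the ordered model three levels deep, dispatching on token kind:
#' the entry builder handles the `data_` header and top-level members, the
#' saveframe builder alternates tag/value pairs and delegates loops, and the
#' loop builder collects field tags followed by row-major values.
#'
#' @name star-parser
NULL

parse_error <- function(msg, line = NA_integer_) {
  at <- if (is.na(line)) "" else sprintf(" at line %d", line)
  stop(errorCondition(sprintf("NMR-STAR format error%s: %s", at, msg),
                      line = line,
                      class = c("nmrstar_parse_error", "nmrstar_error")))
}

# pull-based cursor over a star_tokens stream
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 0L
  env$n <- length(tokens)
  env
}

cur_next <- function(cur) {
  if (cur$i >= cur$n) return(NULL)
  cur$i <- cur$i + 1L
  list(kind = cur$tokens$kind[cur$i], text = cur$tokens$text[cur$i],
       line = cur$tokens$line[cur$i])
}

cur_pushback <- function(cur) {
  cur$i <- cur$i - 1L
  invisible(NULL)
}

# mutable ordered-member accumulator shared by entry body and saveframes
new_members <- function() {
  env <- new.env(parent = emptyenv())
  env$keys <- character(0)
  env$vals <- list()
  env$n_loops <- 0L
  env$n_comments <- 0L
  env
}

members_add <- function(env, key, value) {
  env$keys <- c(env$keys, key)
  env$vals[[length(env$vals) + 1L]] <- value
  invisible(env)
}

members_list <- function(env) {
  setNames(env$vals, env$keys)
}

add_tag <- function(members, tag, value, line, strict) {
  if (tag %in% members$keys) {
    if (strict)
      parse_error(sprintf("duplicate tag '%s'", tag), line)
    warning(sprintf("duplicate tag '%s' at line %d: keeping first occurrence",
                    tag, line))
    return(invisible(members))
  }
  members_add(members, tag, value)
}

add_loop <- function(members, loop) {
  key <- paste0("loop_", members$n_loops)
  members$n_loops <- members$n_loops + 1L
  members_add(members, key, loop)
}

add_comment <- function(members, text) {
  key <- paste0("comment_", members$n_comments)
  members$n_comments <- members$n_comments + 1L
  members_add(members, key, text)
}

build_loop <- function(cur, strict) {
  fields <- character(0)
  open_line <- cur$tokens$line[cur$i]
  # leading TAG tokens are the loop fields
  repeat {
    tok <- cur_next(cur)
    if (is.null(tok))
      parse_error("end of input inside loop (missing stop_)", open_line)
    if (tok$kind == "TAG") {
      fields <- c(fields, tok$text)
    } else if (tok$kind == "COMMENT") {
      next
    } else {
      cur_pushback(cur)
      break
    }
  }
  if (length(fields) == 0L)
    parse_error("loop with no field tags", open_line)
  values <- character(0)
  repeat {
    tok <- cur_next(cur)
    if (is.null(tok))
      parse_error("end of input inside loop (missing stop_)", open_line)
    if (tok$kind == "VALUE") {
      values <- c(values, tok$text)
    } else if (tok$kind == "COMMENT") {
      next
    } else if (tok$kind == "LOOP_END") {
      break
    } else if (tok$kind == "SAVE_END" && !strict) {
      # some historical files omit stop_; accept the saveframe end as the
      # loop terminator and leave it for the saveframe builder
      warning(sprintf("loop at line %d terminated by save_ (missing stop_)",
                      open_line))
      cur_pushback(cur)
      break
    } else if (tok$kind == "TAG") {
      parse_error(sprintf("tag '%s' among loop values", tok$text), tok$line)
    } else {
      parse_error(sprintf("unexpected %s inside loop", tok$kind), tok$line)
    }
  }
  nf <- length(fields)
  nv <- length(values)
  if (nv == 0L)
    warning(sprintf("loop at line %d has no values (empty loop)", open_line))
  if (nv %% nf != 0L) {
    if (strict)
      parse_error(sprintf(
        "loop at line %d has %d values, not divisible by %d fields",
        open_line, nv, nf), open_line)
    warning(sprintf(
      "loop at line %d has %d values for %d fields: truncating final record",
      open_line, nv, nf))
    nv <- (nv %/% nf) * nf
    values <- values[seq_len(nv)]
  }
  nrec <- nv %/% nf
  records <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    rec <- values[((r - 1L) * nf + 1L):(r * nf)]
    names(rec) <- fields
    records[[r]] <- rec
  }
  star_loop(fields, records)
}

# shared tag/value + loop + comment handling for saveframe bodies and the
# data-block level; `terminators` names token kinds that end the scope
consume_members <- function(cur, members, strict, scope, terminators) {
  repeat {
    tok <- cur_next(cur)
    if (is.null(tok)) {
      if ("EOF" %in% terminators) return("EOF")
      parse_error(sprintf("end of input inside %s (missing save_)", scope))
    }
    switch(tok$kind,
      TAG = {
        val <- cur_next(cur)
        if (is.null(val) || val$kind != "VALUE") {
          parse_error(sprintf("tag '%s' has no value", tok$text), tok$line)
        }
        add_tag(members, tok$text, val$text, tok$line, strict)
      },
      LOOP_BEGIN = {
        add_loop(members, build_loop(cur, strict))
      },
      COMMENT = {
        add_comment(members, tok$text)
      },
      VALUE = {
        if (strict)
          parse_error(sprintf("value '%s' without a preceding tag",
                              abbreviate_value(tok$text)), tok$line)
        warning(sprintf("skipping stray value at line %d", tok$line))
      },
      {
        if (tok$kind %in% terminators) {
          cur_pushback(cur)
          return(tok$kind)
        }
        parse_error(sprintf("unexpected %s in %s", tok$kind, scope), tok$line)
      }
    )
  }
}

abbreviate_value <- function(x) {
  x <- gsub("\n", "\\\\n", x)
  if (nchar(x) > 30L) paste0(substr(x, 1L, 30L), "...") else x
}

build_saveframe <- function(cur, name, strict) {
  members <- new_members()
  ended <- consume_members(cur, members, strict,
                           scope = sprintf("saveframe '%s'", name),
                           terminators = "SAVE_END")
  stopifnot(ended == "SAVE_END")
  invisible(cur_next(cur))  # consume the SAVE_END
  structure(members_list(members), class = "star_saveframe")
}

#' Parse NMR-STAR text into an entry object
#'
#' Tokenizes the document and constructs a [star_entry] whose flattened key
#' structure corresponds one-to-one to the document: the data-block
#' identifier under the reserved key `"data"`, then saveframes, tags and
#' loops in document order.  Tags and loops appearing at data-block level
#' (outside any saveframe, which is legal STAR) are stored directly in the
#' entry body.
#'
#' @param text Character scalar: complete NMR-STAR document.
#' @param strict If `TRUE` (default), malformed structure (duplicate tags,
#'   stray values, ragged loops, missing `stop_`) is an error; if `FALSE`,
#'   these are repaired with a warning where a reasonable repair exists.
#' @param capture_comments If `TRUE`, `#` comments become `comment_N` members
#'   at the nesting level where they occur (comments inside a loop attach to
#'   the enclosing scope).
#' @param source Provenance string stamped on the returned entry.
#' @return A [star_entry].
#' @examples
#' e <- parse_star("data_X\nsave_A\n_T v\nsave_\n")
#' e$A$`_T`
#' @export
parse_star <- function(text, strict = TRUE, capture_comments = FALSE,
                       source = "") {
  tokens <- tokenize(text, emit_comments = capture_comments)
  cur <- new_cursor(tokens)
  # locate the data header; only comments may precede it
  repeat {
    tok <- cur_next(cur)
    if (is.null(tok))
      parse_error("no data_ header found (empty or non-STAR input)")
    if (tok$kind == "COMMENT") next
    if (tok$kind == "DATA_HEADER") break
    parse_error(sprintf("%s before data_ header", tok$kind), tok$line)
  }
  id <- tok$text
  members <- new_members()
  frame_names <- character(0)
  repeat {
    tok <- cur_next(cur)
    if (is.null(tok)) break
    if (tok$kind == "SAVE_BEGIN") {
      if (tok$text %in% frame_names)
        parse_error(sprintf("duplicate saveframe name '%s'", tok$text),
                    tok$line)
      frame <- build_saveframe(cur, tok$text, strict)
      frame_names <- c(frame_names, tok$text)
      members_add(members, tok$text, frame)
    } else if (tok$kind == "DATA_HEADER") {
      warning(sprintf(
        "multiple data_ blocks: parsing first block only (second at line %d)",
        tok$line))
      break
    } else {
      cur_pushback(cur)
      ended <- consume_members(cur, members, strict,
                               scope = "data block",
                               terminators = c("EOF", "SAVE_BEGIN",
                                               "DATA_HEADER"))
      if (ended == "EOF") break
      # SAVE_BEGIN / DATA_HEADER handled on next iteration
    }
  }
  x <- c(list(data = id), members_list(members))
  attr(x, "source") <- source
  class(x) <- "star_entry"
  x
}
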