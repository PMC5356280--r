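#' @title Serializing entries back to NMR-STAR text
#'
#' @description
#' The writer crawls the ordered entry structure and prints each key and
#' value sequentially, so the output file preserves the sequential order of
#' the original document.  Values are re-quoted by a minimal-encoding policy
#' ([format_value()]); byte-identical reproduction of the input's whitespace
#' is explicitly not the goal -- structural equality under re-parsing is the
#' round-trip contract.
#'
#' @name star-writer
NULL

star_keywords_re <- "^(data_.+|save_.*|loop_|stop_|global_)$"

# does the value need quoting at all?
needs_quoting <- function(v) {
  if (!nzchar(v)) return(TRUE)
  if (grepl("[ \t\n'\"]", v)) return(TRUE)
  first <- substr(v, 1L, 1L)
  if (first %in% c("_", "#", "$", ";")) return(TRUE)
  if (grepl(star_keywords_re, tolower(v))) return(TRUE)
  FALSE
}

#' Choose the minimal safe NMR-STAR encoding for a value
#'
#' Encoding precedence: bare word if the value contains no whitespace and no
#' quote character, does not begin with `_`, `#`, `$` or `;`, and is not a
#' STAR keyword or empty; else single-quoted if it contains no single quote and no
#' newline; else double-quoted if it contains no double quote and no newline;
#' else a column-1 semicolon-delimited multiline block.  Values that look
#' like keywords (`stop_`, `save_x`, ...) are always quoted so they cannot
#' re-lex as keywords; an empty string is written as `''`.
#'
#' A string containing a line that begins with `;` cannot be represented in
#' STAR at all (a column-1 semicolon always terminates the enclosing
#' multiline block) and is rejected with an error.
#'
#' @param value Character scalar.
#' @return Character scalar: the formatted fragment.  Multiline encodings
#'   start with `"\n;"` and end with `";\n"` so they land in column 1 when
#'   concatenated after a line in progress.
#' @examples
#' format_value("12.5")
#' format_value("a b")
#' format_value("it's")
#' format_value("two\nlines")
#' @export
format_value <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (!needs_quoting(value)) return(value)
  has_nl <- grepl("\n", value, fixed = TRUE)
  if (!has_nl) {
    if (!grepl("'", value, fixed = TRUE)) return(paste0("'", value, "'"))
    if (!grepl("\"", value, fixed = TRUE)) return(paste0("\"", value, "\""))
  }
  if (grepl("(^|\n);", value))
    stop("value contains a line beginning with ';' and cannot be ",
         "represented in NMR-STAR")
  # the lexer strips exactly one newline after the opening ";", so always
  # emit one: this round-trips values that themselves start with a newline
  paste0("\n;\n", value, "\n;\n")
}

format_loop <- function(loop) {
  out <- character(0)
  out <- c(out, "loop_\n")
  out <- c(out, paste0("  ", loop$fields, "\n"))
  for (rec in loop$records) {
    row <- "  "
    at_line_start <- FALSE
    for (v in rec) {
      frag <- format_value(v)
      if (startsWith(frag, "\n;")) {
        out <- c(out, sub("^ +$", "", row), frag)
        row <- "  "
        at_line_start <- TRUE
      } else {
        row <- paste0(row, frag, " ")
        at_line_start <- FALSE
      }
    }
    if (!at_line_start || nzchar(trimws(row)))
      out <- c(out, sub(" $", "", row), "\n")
  }
  c(out, "stop_\n")
}

format_members <- function(members) {
  out <- character(0)
  for (k in names(members)) {
    v <- members[[k]]
    if (is_star_loop(v)) {
      out <- c(out, format_loop(v))
    } else if (grepl("^comment_[0-9]+$", k)) {
      out <- c(out, paste0("# ", v, "\n"))
    } else {
      frag <- format_value(v)
      if (startsWith(frag, "\n;")) {
        out <- c(out, k, frag)
      } else {
        out <- c(out, k, " ", frag, "\n")
      }
    }
  }
  out
}

#' Serialize an entry to NMR-STAR text
#'
#' @param entry A valid [star_entry] (checked with [validate_star()]; an
#'   invalid entry is refused with the first violation).
#' @return Character scalar: the NMR-STAR document, LF line endings, ending
#'   with a newline.
#' @examples
#' e <- parse_star("data_X\nsave_A\n_T v\nsave_\n")
#' cat(format_star(e))
#' @export
format_star <- function(entry) {
  stopifnot(inherits(entry, "star_entry"))
  violations <- validate_star(entry)
  if (length(violations))
    stop("refusing to write invalid entry: ", violations[1L])
  out <- c(paste0("data_", entry$data, "\n\n"))
  body <- entry[-1L]
  for (k in names(body)) {
    v <- body[[k]]
    if (is_star_saveframe(v)) {
      out <- c(out, paste0("save_", k, "\n"),
               format_members(unclass(v)),
               "save_\n\n")
    } else {
      out <- c(out, format_members(setNames(list(v), k)))
    }
  }
  paste(out, collapse = "")
}

#' Write an entry to a file in NMR-STAR format
#'
#' @param entry A valid [star_entry].
#' @param path Output file path or a writable connection.
#' @return Invisibly, `path`.
#' @export
write_star <- function(entry, path) {
  txt <- format_star(entry)
  writeLines(txt, path, sep = "", useBytes = TRUE)
  invisible(path)
}
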