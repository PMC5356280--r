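#' @title Ordered data model for NMR-STAR entries
#'
#' @description
#' An NMR-STAR document is a hierarchical, *ordered* database: one data block
#' (`data_<id>`) holding named saveframes (`save_<name>` ... `save_`), each of
#' which contains free tag-value pairs and loops (tables of records).  The
#' model here mirrors that structure one-to-one with ordered named lists, so
#' that a parsed entry can be written back out (or converted to JSON) without
#' losing the original key order -- the property that makes the round trip
#' lossless.
#'
#' * `star_entry`: named list; the reserved key `"data"` holds the data-block
#'   identifier and precedes everything else.  Remaining members are
#'   saveframes (`star_saveframe`), or -- for tags and loops that legally
#'   appear at data-block level -- tag values (character scalars under keys
#'   beginning `"_"`), loops under `"loop_0"`, `"loop_1"`, ... and captured
#'   comments under `"comment_0"`, ...  The provenance of the entry (file
#'   path, archive member, URL) is kept in attribute `"source"` and never
#'   takes part in equality.
#' * `star_saveframe`: named list of tag values (character scalars), loops and
#'   comments, ordered as in the document.
#' * `star_loop`: `list(fields = <character>, records = <list>)`; `records`
#'   is an ordered list of named character vectors, one per row, whose names
#'   are exactly `fields` in order.
#'
#' All values are stored as strings verbatim (including the `.` and `?`
#' placeholders and `$framecode` references); no numeric coercion happens in
#' the model.
#'
#' @name star-model
NULL

#' Create an NMR-STAR entry object
#'
#' @param id Data-block identifier (the part after `data_`).
#' @param ... Named members in document order: `star_saveframe` objects,
#'   character tag values (names starting with `_`), `star_loop` objects
#'   (names `loop_0`, `loop_1`, ...).
#' @param source Provenance descriptor (path, URL, archive member, BMRB id).
#' @return An object of class `star_entry`.
#' @examples
#' e <- star_entry("18569", assembly = star_saveframe(`_Name` = "ubiquitin"))
#' @export
star_entry <- function(id, ..., source = "") {
  body <- list(...)
  x <- c(list(data = as.character(id)), body)
  attr(x, "source") <- source
  class(x) <- "star_entry"
  x
}

#' Create a saveframe
#'
#' @param ... Named members in document order: character tag values (names
#'   starting with `_`), `star_loop` objects (names `loop_N`) and captured
#'   comments (names `comment_N`).
#' @return An object of class `star_saveframe`.
#' @export
star_saveframe <- function(...) {
  x <- list(...)
  class(x) <- "star_saveframe"
  x
}

#' Create a loop (table of records)
#'
#' @param fields Character vector of loop field tags (each starting with `_`).
#' @param records Either a list of named character vectors (names equal to
#'   `fields`, in order) or a data.frame whose columns are `fields`.
#' @return An object of class `star_loop`.
#' @export
star_loop <- function(fields, records = list()) {
  fields <- as.character(fields)
  if (is.data.frame(records)) {
    df <- records
    records <- lapply(seq_len(nrow(df)), function(i) {
      r <- vapply(df[i, , drop = FALSE], as.character, character(1))
      names(r) <- names(df)
      r
    })
  }
  x <- list(fields = fields, records = records)
  class(x) <- "star_loop"
  x
}

is_star_loop <- function(x) inherits(x, "star_loop")
is_star_saveframe <- function(x) inherits(x, "star_saveframe")

#' Convert a loop to a data.frame
#'
#' @param x A `star_loop`.
#' @param ... Unused.
#' @return A data.frame with one character column per loop field.
#' @export
as.data.frame.star_loop <- function(x, ...) {
  if (length(x$records) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(x$fields)),
                                 x$fields),
                        check.names = FALSE)
    return(df)
  }
  mat <- do.call(rbind, lapply(x$records, function(r) unname(r)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- x$fields
  rownames(df) <- NULL
  df
}

# ---- validation -------------------------------------------------------------

validate_loop <- function(loop, path) {
  out <- character(0)
  if (!is.list(loop$records))
    return(paste0(path, ": records is not a list"))
  if (length(loop$fields) == 0L && length(loop$records) > 0L)
    out <- c(out, paste0(path, ": loop has records but no fields"))
  if (anyDuplicated(loop$fields))
    out <- c(out, paste0(path, ": duplicate loop field tags"))
  bad_tag <- loop$fields[!startsWith(loop$fields, "_")]
  if (length(bad_tag))
    out <- c(out, paste0(path, ": field '", bad_tag[1], "' does not start with '_'"))
  for (i in seq_along(loop$records)) {
    r <- loop$records[[i]]
    if (!identical(names(r), loop$fields))
      out <- c(out, paste0(path, "/record ", i,
                           ": record keys do not equal loop fields"))
  }
  out
}

validate_members <- function(members, path) {
  out <- character(0)
  keys <- names(members)
  if (is.null(keys) && length(members) > 0L)
    return(paste0(path, ": unnamed members"))
  loop_keys <- grep("^loop_[0-9]+$", keys, value = TRUE)
  expected <- if (length(loop_keys))
    paste0("loop_", seq_along(loop_keys) - 1L) else character(0)
  if (!identical(loop_keys, expected))
    out <- c(out, paste0(path, ": loop keys not consecutively numbered from 0 (",
                         paste(loop_keys, collapse = ", "), ")"))
  for (k in keys) {
    v <- members[[k]]
    full <- paste0(path, "/", k)
    if (grepl("^loop_[0-9]+$", k)) {
      if (!is_star_loop(v)) {
        out <- c(out, paste0(full, ": key looks like a loop but value is not a star_loop"))
      } else {
        out <- c(out, validate_loop(v, full))
      }
    } else if (grepl("^comment_[0-9]+$", k)) {
      if (!is.character(v) || length(v) != 1L)
        out <- c(out, paste0(full, ": comment is not a single string"))
    } else if (startsWith(k, "_")) {
      if (!is.character(v) || length(v) != 1L)
        out <- c(out, paste0(full, ": tag value is not a single string"))
    } else {
      out <- c(out, paste0(full, ": key is neither a tag ('_'), loop_N nor comment_N"))
    }
  }
  if (anyDuplicated(keys))
    out <- c(out, paste0(path, ": duplicate keys"))
  out
}

#' Validate an entry against the model invariants
#'
#' Checks the structural invariants of the ordered model: the reserved
#' `"data"` key is present and first; saveframe names are unique; loop keys
#' are numbered `loop_0`, `loop_1`, ... consecutively within each scope; every
#' loop record's key sequence equals the loop's field sequence; tag keys start
#' with `"_"`.
#'
#' @param entry A `star_entry`.
#' @return Character vector of violation descriptions (empty if valid), each
#'   naming the offending key path.
#' @export
validate_star <- function(entry) {
  out <- character(0)
  keys <- names(entry)
  if (length(entry) == 0L || is.null(keys) || keys[1] != "data")
    return("entry: reserved key 'data' missing or not first")
  if (!is.character(entry$data) || length(entry$data) != 1L)
    out <- c(out, "entry/data: identifier is not a single string")
  body <- entry[-1L]
  bkeys <- names(body)
  frame_keys <- bkeys[vapply(body, is_star_saveframe, logical(1))]
  if (anyDuplicated(frame_keys))
    out <- c(out, "entry: duplicate saveframe names")
  loose <- body[!vapply(body, is_star_saveframe, logical(1))]
  out <- c(out, validate_members(loose, "entry"))
  for (k in frame_keys) {
    out <- c(out, validate_members(unclass(body[[k]]), paste0("save_", k)))
  }
  out
}

# ---- structural equality ----------------------------------------------------

values_equal <- function(a, b) {
  if (is_star_loop(a) || is_star_loop(b)) {
    if (!(is_star_loop(a) && is_star_loop(b))) return(FALSE)
    if (!identical(a$fields, b$fields)) return(FALSE)
    if (length(a$records) != length(b$records)) return(FALSE)
    for (i in seq_along(a$records)) {
      if (!identical(names(a$records[[i]]), names(b$records[[i]]))) return(FALSE)
      if (!identical(unname(a$records[[i]]), unname(b$records[[i]]))) return(FALSE)
    }
    return(TRUE)
  }
  if (is_star_saveframe(a) || is_star_saveframe(b)) {
    if (!(is_star_saveframe(a) && is_star_saveframe(b))) return(FALSE)
    return(members_equal(unclass(a), unclass(b)))
  }
  identical(as.character(a), as.character(b))
}

members_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(names(a), names(b))) return(FALSE)
  for (i in seq_along(a)) {
    if (!values_equal(a[[i]], b[[i]])) return(FALSE)
  }
  TRUE
}

#' Order-sensitive structural equality of two entries
#'
#' Two entries are structurally equal iff they have identical key sequences at
#' every nesting level (saveframe order, tag order within saveframes, loop
#' field order, record order) and identical value strings.  The provenance
#' (`source` attribute) is excluded from the comparison.  This is the
#' round-trip contract: `parse(write(e))` must be structurally equal to `e`.
#'
#' @param a,b `star_entry` objects.
#' @return `TRUE` or `FALSE`.
#' @export
structurally_equal <- function(a, b) {
  stopifnot(inherits(a, "star_entry"), inherits(b, "star_entry"))
  members_equal(unclass(a), unclass(b))
}

# ---- printing ---------------------------------------------------------------

#' @export
print.star_loop <- function(x, ...) {
  cat("<star_loop> ", length(x$fields), " fields x ", length(x$records),
      " records\n", sep = "")
  cat("  fields: ", paste(x$fields, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.star_saveframe <- function(x, ...) {
  nl <- sum(grepl("^loop_[0-9]+$", names(x)))
  cat("<star_saveframe> ", length(x) - nl, " tags, ", nl, " loops\n", sep = "")
  invisible(x)
}

#' @export
print.star_entry <- function(x, ...) {
  frames <- names(x)[vapply(x, is_star_saveframe, logical(1))]
  cat("<star_entry> data_", x$data, "\n", sep = "")
  src <- attr(x, "source")
  if (!is.null(src) && nzchar(src)) cat("  source: ", src, "\n", sep = "")
  cat("  saveframes (", length(frames), "): ",
      paste(utils::head(frames, 8L), collapse = ", "),
      if (length(frames) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.star_entry <- function(object, ...) {
  cnt <- star_counts(object)
  cat("NMR-STAR entry data_", object$data, ": ", cnt$saveframes,
      " saveframes, ", cnt$loops, " loops, ", cnt$records, " records\n",
      sep = "")
  invisible(cnt)
}

#' Count structural components of an entry
#'
#' @param entry A `star_entry`.
#' @return List with counts: `saveframes`, `loops`, `records`, `values`
#'   (loop cells), `tags`, `comments`.
#' @export
star_counts <- function(entry) {
  n_frames <- 0L; n_loops <- 0L; n_records <- 0L
  n_values <- 0L; n_tags <- 0L; n_comments <- 0L
  count_members <- function(members) {
    for (k in names(members)) {
      v <- members[[k]]
      if (is_star_loop(v)) {
        n_loops <<- n_loops + 1L
        n_records <<- n_records + length(v$records)
        n_values <<- n_values + length(v$fields) * length(v$records)
      } else if (grepl("^comment_[0-9]+$", k)) {
        n_comments <<- n_comments + 1L
      } else if (startsWith(k, "_")) {
        n_tags <<- n_tags + 1L
      }
    }
  }
  body <- entry[-1L]
  frames <- vapply(body, is_star_saveframe, logical(1))
  n_frames <- sum(frames)
  count_members(body[!frames])
  for (f in body[frames]) count_members(unclass(f))
  list(saveframes = n_frames, loops = n_loops, records = n_records,
       values = n_values, tags = n_tags, comments = n_comments)
}

#' List every loop in an entry with its shape
#'
#' @param entry A `star_entry`.
#' @return List with one element per loop in document order:
#'   `list(path, n_fields, n_records)` where `path` is
#'   `"<saveframe>/loop_N"` (or `"loop_N"` at data-block level).
#' @export
star_loop_shapes <- function(entry) {
  out <- list()
  walk <- function(members, prefix) {
    for (k in names(members)) {
      v <- members[[k]]
      if (is_star_loop(v)) {
        out[[length(out) + 1L]] <<- list(
          path = paste0(prefix, k),
          n_fields = length(v$fields),
          n_records = length(v$records))
      }
    }
  }
  body <- entry[-1L]
  frames <- vapply(body, is_star_saveframe, logical(1))
  walk(body[!frames], "")
  for (k in names(body)[frames])
    walk(unclass(body[[k]]), paste0(k, "/"))
  out
}

#' Flattened key order of an entry
#'
#' Returns the document-order sequence of structural keys: for each body
#' member its key, and for saveframes additionally their member keys prefixed
#' with the saveframe name (`"frame/_Tag"`, `"frame/loop_0"`).  Used to check
#' insertion-order preservation against a generator manifest.
#'
#' @param entry A `star_entry`.
#' @return Character vector of key paths in document order.
#' @export
star_key_order <- function(entry) {
  out <- character(0)
  body <- entry[-1L]
  for (k in names(body)) {
    v <- body[[k]]
    if (is_star_saveframe(v)) {
      out <- c(out, k, paste0(k, "/", names(v)))
    } else {
      out <- c(out, k)
    }
  }
  out
}
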