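#' @title Lossless JSON conversion
#'
#' @description
#' An entry maps one-to-one onto nested JSON: the data-block identifier under
#' `"data"`, saveframes as objects in document order, each loop as a
#' two-element array `[fields, records]` (the model's pair of lists), and
#' every scalar as a JSON string.  Member order is significant in both
#' directions; the reader preserves object member order, which is what makes
#' JSONized NMR-STAR a faithful alternate encoding rather than a lossy
#' export.
#'
#' @name star-json
NULL

json_error <- function(msg, path = NULL) {
  at <- if (is.null(path)) "" else sprintf(" at %s", path)
  stop(errorCondition(sprintf("JSON conversion error%s: %s", at, msg),
                      class = c("nmrstar_json_error", "nmrstar_error")))
}

loop_to_json_obj <- function(loop) {
  records <- lapply(loop$records, function(r)
    lapply(as.list(r), jsonlite::unbox))
  # named empty list must still serialize as {}
  records <- lapply(records, function(r)
    if (length(r)) r else structure(list(), names = character(0)))
  list(lapply(as.list(loop$fields), jsonlite::unbox), records)
}

members_to_json_obj <- function(members) {
  out <- vector("list", length(members))
  names(out) <- names(members)
  for (i in seq_along(members)) {
    v <- members[[i]]
    out[[i]] <- if (is_star_loop(v)) loop_to_json_obj(v)
                else if (is_star_saveframe(v)) members_to_json_obj(unclass(v))
                else jsonlite::unbox(as.character(v))
  }
  if (!length(out)) out <- structure(list(), names = character(0))
  out
}

#' Convert an entry to JSONized NMR-STAR text
#'
#' @param entry A valid [star_entry].
#' @param pretty If `TRUE`, indent the output with 4 spaces; default is
#'   compact output (JSON is already more verbose than NMR-STAR).
#' @return Character scalar of JSON text (UTF-8, no BOM).
#' @examples
#' to_json_star(parse_star("data_X\nsave_A\n_T v\nsave_\n"))
#' @export
to_json_star <- function(entry, pretty = FALSE) {
  stopifnot(inherits(entry, "star_entry"))
  violations <- validate_star(entry)
  if (length(violations))
    stop("refusing to convert invalid entry: ", violations[1L])
  obj <- c(list(data = jsonlite::unbox(entry$data)),
           members_to_json_obj(entry[-1L]))
  as.character(jsonlite::toJSON(obj, auto_unbox = FALSE,
                                pretty = if (pretty) 4L else FALSE))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L

json_to_loop <- function(x, path) {
  if (!is.list(x) || length(x) != 2L)
    json_error("loop array must have exactly 2 elements (fields, records)",
               path)
  fields <- x[[1L]]
  if (!is.list(fields) || !all(vapply(fields, is_scalar_chr, logical(1))))
    json_error("loop field list must be an array of strings", path)
  fields <- unlist(fields, use.names = FALSE)
  if (is.null(fields)) fields <- character(0)
  records <- x[[2L]]
  if (!is.list(records))
    json_error("loop records must be an array of objects", path)
  recs <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (!is.list(r) || !identical(names(r), fields))
      json_error(sprintf("record %d keys do not equal the field list", i),
                 path)
    vals <- vapply(r, function(v) {
      if (!is_scalar_chr(v))
        json_error(sprintf("record %d holds a non-string value", i), path)
      v
    }, character(1))
    names(vals) <- fields
    recs[[i]] <- vals
  }
  star_loop(fields, recs)
}

json_to_members <- function(x, path) {
  keys <- names(x)
  if (length(x) && (is.null(keys) || any(!nzchar(keys))))
    json_error("object members must be named", path)
  out <- vector("list", length(x))
  names(out) <- keys
  for (i in seq_along(x)) {
    k <- keys[i]
    v <- x[[i]]
    kp <- paste0(path, "/", k)
    if (grepl("^loop_[0-9]+$", k)) {
      out[[i]] <- json_to_loop(v, kp)
    } else if (startsWith(k, "_") || grepl("^comment_[0-9]+$", k)) {
      if (!is_scalar_chr(v)) json_error("tag value must be a string", kp)
      out[[i]] <- v
    } else {
      json_error("key is neither a tag, loop_N nor comment_N", kp)
    }
  }
  out
}

#' Reconstruct an entry from JSONized NMR-STAR text
#'
#' @param text Character scalar of JSON text produced by [to_json_star()] (or
#'   following the same schema).
#' @param source Provenance string stamped on the entry.
#' @return A [star_entry] with key order equal to the JSON member order.
#' @export
from_json_star <- function(text, source = "") {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) json_error(paste("malformed JSON:",
                                         conditionMessage(e))))
  if (!is.list(obj)) json_error("top level is not an object")
  keys <- names(obj)
  if (is.null(keys) || !("data" %in% keys))
    json_error("top-level object lacks the reserved \"data\" key")
  if (keys[1L] != "data")
    json_error("reserved \"data\" key must come first")
  id <- obj[["data"]]
  if (!is_scalar_chr(id)) json_error("\"data\" must be a string", "entry/data")
  body <- obj[-1L]
  members <- vector("list", length(body))
  names(members) <- names(body)
  for (i in seq_along(body)) {
    k <- names(body)[i]
    v <- body[[i]]
    if (grepl("^loop_[0-9]+$", k)) {
      members[[i]] <- json_to_loop(v, paste0("entry/", k))
    } else if (startsWith(k, "_") || grepl("^comment_[0-9]+$", k)) {
      if (!is_scalar_chr(v))
        json_error("tag value must be a string", paste0("entry/", k))
      members[[i]] <- v
    } else {
      # a saveframe
      if (!is.list(v))
        json_error("saveframe must be an object", paste0("entry/", k))
      members[[i]] <- structure(json_to_members(v, paste0("save_", k)),
                                class = "star_saveframe")
    }
  }
  x <- c(list(data = id), members)
  attr(x, "source") <- source
  class(x) <- "star_entry"
  x
}

# ---- bulk conversion --------------------------------------------------------

swap_extension <- function(name, to_format) {
  ext <- tolower(tools::file_ext(name))
  new_ext <- if (to_format == "json") "json" else "str"
  if (ext %in% c("str", "json", "nmrstar", "txt")) {
    paste0(tools::file_path_sans_ext(name), ".", new_ext)
  } else {
    paste0(name, ".", new_ext)
  }
}

parse_any <- function(text, format, source = "") {
  if (format == "json") from_json_star(text, source = source)
  else parse_star(text, source = source)
}

render_any <- function(entry, format) {
  if (format == "json") paste0(to_json_star(entry), "\n")
  else format_star(entry)
}

archive_kind <- function(path) {
  lp <- tolower(path)
  if (endsWith(lp, ".zip")) "zip"
  else if (endsWith(lp, ".tar.gz") || endsWith(lp, ".tgz")) "tar.gz"
  else if (endsWith(lp, ".tar.bz2")) "tar.bz2"
  else if (endsWith(lp, ".tar")) "tar"
  else NA_character_
}

pack_archive <- function(dir, target, kind) {
  target <- normalizePath(target, mustWork = FALSE)
  files <- list.files(dir, recursive = TRUE)
  old <- setwd(dir); on.exit(setwd(old))
  if (kind == "zip") {
    if (nzchar(Sys.which("zip"))) {
      utils::zip(target, files, flags = "-q")
    } else if (nzchar(Sys.which("python")) || nzchar(Sys.which("python3"))) {
      py <- if (nzchar(Sys.which("python"))) "python" else "python3"
      script <- paste(
        "import sys, zipfile",
        "zf = zipfile.ZipFile(sys.argv[1], 'w', zipfile.ZIP_DEFLATED)",
        "for m in sys.argv[2:]:",
        "    zf.write(m, m)",
        "zf.close()",
        sep = "\n")
      status <- system2(py, c("-c", shQuote(script), shQuote(target),
                              shQuote(files)))
      if (status != 0L) stop("zip creation via python failed")
    } else {
      stop("cannot create zip archive: neither 'zip' nor 'python' found")
    }
  } else {
    compression <- switch(kind, tar.gz = "gzip", tar.bz2 = "bzip2", "none")
    utils::tar(target, files, compression = compression)
  }
  invisible(target)
}

#' Bulk conversion between NMR-STAR and JSONized NMR-STAR
#'
#' One-to-one mode (source resolves to a single document) writes a single
#' converted file.  Many-to-many mode (directory or archive source) mirrors
#' the source's member structure into a target directory, or into an archive
#' when `to_path` carries an archive extension (`.zip`, `.tar`, `.tar.gz`,
#' `.tar.bz2`).  Members that fail to parse are reported and skipped.
#'
#' @param from_path Source specification (file, directory, archive, URL or
#'   BMRB id; see [star_source()]).
#' @param to_path Target file, directory or archive path.
#' @param from_format,to_format `"nmrstar"` or `"json"`; must differ.
#' @param pretty Pretty-print JSON output.
#' @param verbose Print a per-file line for failures.
#' @return A conversion report: list with `n_total`, `n_success`, `n_failed`,
#'   `failures` (named character vector of messages) and `members` (output
#'   member names).
#' @examples
#' src <- tempfile(fileext = ".str")
#' writeLines("data_X\nsave_A\n_T v\nsave_", src)
#' out <- tempfile(fileext = ".json")
#' convert_star(src, out, from_format = "nmrstar", to_format = "json")
#' @export
convert_star <- function(from_path, to_path,
                         from_format = c("nmrstar", "json"),
                         to_format = c("json", "nmrstar"),
                         pretty = FALSE, verbose = FALSE) {
  from_format <- match.arg(from_format)
  to_format <- match.arg(to_format)
  if (from_format == to_format)
    stop("from_format and to_format must differ")
  spec <- star_source(from_path, format_hint = from_format)
  members <- resolve_source(spec)
  single <- spec$kind %in% c("LOCAL_FILE", "URL_FILE", "BMRB_ID") &&
    length(members) == 1L
  failures <- character(0)
  out_members <- character(0)
  if (single) {
    res <- tryCatch({
      entry <- parse_any(members[[1L]]$read(), from_format,
                         source = members[[1L]]$name)
      txt <- if (to_format == "json") paste0(to_json_star(entry, pretty), "\n")
             else format_star(entry)
      writeLines(txt, to_path, sep = "", useBytes = TRUE)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      failures[members[[1L]]$name] <- res
    } else {
      out_members <- to_path
    }
  } else {
    kind <- archive_kind(to_path)
    out_dir <- if (is.na(kind)) to_path else tempfile("convert_out_")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in members) {
      res <- tryCatch({
        entry <- parse_any(m$read(), from_format, source = m$name)
        out_name <- swap_extension(m$name, to_format)
        dest <- file.path(out_dir, out_name)
        dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
        writeLines(render_any(entry, to_format), dest, sep = "",
                   useBytes = TRUE)
        out_name
      }, error = function(e) structure(conditionMessage(e), failed = TRUE))
      if (!is.null(attr(res, "failed"))) {
        failures[m$name] <- as.character(res)
        if (verbose) message("failed: ", m$name, ": ", res)
      } else {
        out_members <- c(out_members, res)
      }
    }
    if (!is.na(kind)) {
      pack_archive(out_dir, to_path, kind)
      unlink(out_dir, recursive = TRUE)
    }
  }
  report <- list(n_total = length(members),
                 n_success = length(members) - length(failures),
                 n_failed = length(failures),
                 failures = failures,
                 members = out_members)
  class(report) <- "star_conversion_report"
  report
}

#' @export
print.star_conversion_report <- function(x, ...) {
  cat("converted ", x$n_success, "/", x$n_total, " files",
      if (x$n_failed) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  if (x$n_failed) {
    for (nm in names(x$failures))
      cat("  failed: ", nm, ": ", x$failures[[nm]], "\n", sep = "")
  }
  invisible(x)
}
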