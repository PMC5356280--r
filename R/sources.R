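#' @title Resolving heterogeneous input sources
#'
#' @description
#' Entries can come from a single local file, a directory, a zip/tar archive,
#' a URL (of a file or an archive), or a bare BMRB accession id.  The
#' resolver turns any of these into a lazy sequence of named document
#' readers, and [read_star_entries()] turns those into a one-at-a-time entry
#' stream, so that a corpus of thousands of files never needs more than one
#' document's text in memory at once.
#'
#' @name star-sources
NULL

text_extensions <- c("str", "json", "txt", "nmrstar", "star")

default_bmrb_templates <- list(
  `2.1` = "https://bmrb.io/ftp/pub/bmrb/entry_directories/bmr%s/bmr%s_21.str",
  `3.1` = "https://bmrb.io/ftp/pub/bmrb/entry_directories/bmr%s/bmr%s_3.str"
)

bmrb_template <- function(version = c("3.1", "2.1")) {
  version <- match.arg(version)
  opt <- getOption(paste0("nmrstar.bmrb_url_template_",
                          gsub(".", "_", version, fixed = TRUE)))
  if (!is.null(opt)) opt else default_bmrb_templates[[version]]
}

read_file_text <- function(path) {
  txt <- rawToChar(readBin(path, "raw", n = file.size(path)))
  if (!all(validUTF8(txt))) {
    warning(sprintf("%s: invalid UTF-8 bytes replaced", path))
    txt <- iconv(txt, from = "UTF-8", to = "UTF-8", sub = "�")
  } else {
    Encoding(txt) <- "UTF-8"
  }
  txt
}

fetch_url <- function(url) {
  if (grepl("^file://", url)) {
    path <- sub("^file://", "", url)
    return(path)
  }
  tmp <- tempfile("nmrstar_fetch_")
  utils::download.file(url, tmp, quiet = TRUE, mode = "wb")
  tmp
}

#' Describe an input source
#'
#' Infers what kind of source a string denotes, with deterministic
#' precedence: an existing local path (directory, archive by extension, or
#' plain file) wins over a URL scheme, which wins over an all-digits BMRB
#' accession id.
#'
#' @param raw What the user supplied: path, URL, or all-digits BMRB id.
#' @param format_hint `"nmrstar"`, `"json"` or `"auto"` (detect per
#'   document: leading `{` means JSON).
#' @param bmrb_version Which NMR-STAR version template to use for a BMRB id
#'   (`"3.1"` or `"2.1"`); the URL templates are configurable via
#'   `options(nmrstar.bmrb_url_template_3_1 = ...)` /
#'   `...template_2_1 = ...` and may be `file://` URLs.
#' @return A `star_source` spec: list with `raw`, `kind` (LOCAL_FILE,
#'   LOCAL_DIR, LOCAL_ARCHIVE, URL_FILE, URL_ARCHIVE or BMRB_ID),
#'   `format_hint` and `bmrb_version`.
#' @export
star_source <- function(raw, format_hint = c("auto", "nmrstar", "json"),
                        bmrb_version = c("3.1", "2.1")) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  format_hint <- match.arg(format_hint)
  bmrb_version <- match.arg(bmrb_version)
  kind <- if (dir.exists(raw)) {
    "LOCAL_DIR"
  } else if (file.exists(raw)) {
    if (!is.na(archive_kind(raw))) "LOCAL_ARCHIVE" else "LOCAL_FILE"
  } else if (grepl("^(https?|file)://", raw)) {
    if (!is.na(archive_kind(raw))) "URL_ARCHIVE" else "URL_FILE"
  } else if (grepl("^[0-9]+$", raw)) {
    "BMRB_ID"
  } else {
    stop("cannot resolve source '", raw,
         "': not an existing path, URL, or numeric BMRB id")
  }
  structure(list(raw = raw, kind = kind, format_hint = format_hint,
                 bmrb_version = bmrb_version),
            class = "star_source")
}

list_archive <- function(path, kind) {
  if (kind == "zip") {
    info <- utils::unzip(path, list = TRUE)
    info$Name[info$Length > 0L | !endsWith(info$Name, "/")]
  } else {
    members <- utils::untar(path, list = TRUE)
    members[!endsWith(members, "/")]
  }
}

archive_member_reader <- function(path, kind, member) {
  force(path); force(kind); force(member)
  function() {
    tmp <- tempfile("nmrstar_member_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    if (kind == "zip") {
      utils::unzip(path, files = member, exdir = tmp, junkpaths = FALSE)
    } else {
      utils::untar(path, files = member, exdir = tmp)
    }
    read_file_text(file.path(tmp, member))
  }
}

#' Resolve a source into a lazy sequence of documents
#'
#' @param spec A `star_source` (or a string, coerced with [star_source()]).
#' @param pattern Optional regular expression filtering directory members;
#'   when `NULL`, hidden files and files without a recognized text extension
#'   (`.str`, `.json`, `.txt`, `.nmrstar`, `.star`) are skipped.
#' @return List of members, each `list(name = <chr>, read = <function()>)`;
#'   the `read` thunks do no I/O until called.  Directory members come in
#'   lexicographic order; archive members in archive order.
#' @export
resolve_source <- function(spec, pattern = NULL) {
  if (is.character(spec)) spec <- star_source(spec)
  stopifnot(inherits(spec, "star_source"))
  raw <- spec$raw
  switch(spec$kind,
    LOCAL_FILE = {
      list(list(name = raw, read = function() read_file_text(raw)))
    },
    LOCAL_DIR = {
      files <- sort(list.files(raw, recursive = TRUE, full.names = FALSE))
      if (is.null(pattern)) {
        files <- files[tolower(tools::file_ext(files)) %in% text_extensions]
      } else {
        files <- grep(pattern, files, value = TRUE)
      }
      lapply(files, function(f) {
        full <- file.path(raw, f)
        list(name = f, read = function() read_file_text(full))
      })
    },
    LOCAL_ARCHIVE = {
      kind <- archive_kind(raw)
      members <- list_archive(raw, kind)
      lapply(members, function(m)
        list(name = m, read = archive_member_reader(raw, kind, m)))
    },
    URL_FILE = {
      list(list(name = raw, read = function() read_file_text(fetch_url(raw))))
    },
    URL_ARCHIVE = {
      local_path <- fetch_url(raw)
      resolve_source(structure(list(raw = local_path, kind = "LOCAL_ARCHIVE",
                                    format_hint = spec$format_hint,
                                    bmrb_version = spec$bmrb_version),
                               class = "star_source"))
    },
    BMRB_ID = {
      url <- gsub("%s", raw, bmrb_template(spec$bmrb_version), fixed = TRUE)
      list(list(name = paste0("bmrb:", raw),
                read = function() read_file_text(fetch_url(url))))
    },
    stop("unsupported source kind: ", spec$kind)
  )
}

detect_format <- function(text, hint) {
  if (hint != "auto") return(hint)
  if (grepl("^[ \t\r\n]*\\{", text)) "json" else "nmrstar"
}

#' Stream entries one at a time from any mix of sources
#'
#' Builds a pull-based stream over one or more sources.  Each call to
#' [next_entry()] reads (at most) one more document, parses it (format
#' auto-detected per document unless hinted), stamps its provenance, and
#' returns it -- so at any moment at most one document's text and one entry
#' are materialized.
#'
#' @param sources Character vector of source strings and/or a list of
#'   `star_source` specs.
#' @param format_hint,bmrb_version Passed to [star_source()] for string
#'   sources.
#' @param strict,capture_comments Passed to [parse_star()].
#' @param on_error `"stop"` (default) or `"skip"`: what to do when one
#'   document fails to parse.  Skipped failures are counted in the stream
#'   state.
#' @return A `star_entry_stream`; use [next_entry()] to pull entries and
#'   [collect_entries()] to drain it into a list.
#' @examples
#' f <- tempfile(fileext = ".str")
#' writeLines("data_X\nsave_A\n_T v\nsave_", f)
#' s <- read_star_entries(f)
#' e <- next_entry(s)
#' @export
read_star_entries <- function(sources, format_hint = "auto",
                              bmrb_version = "3.1",
                              strict = TRUE, capture_comments = FALSE,
                              on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (is.character(sources)) sources <- as.list(sources)
  if (inherits(sources, "star_source")) sources <- list(sources)
  specs <- lapply(sources, function(s) {
    if (inherits(s, "star_source")) s
    else star_source(s, format_hint = format_hint,
                     bmrb_version = bmrb_version)
  })
  state <- new.env(parent = emptyenv())
  state$specs <- specs
  state$spec_i <- 0L
  state$members <- list()
  state$member_i <- 0L
  state$docs_read <- 0L
  state$failed <- 0L
  structure(list(state = state, strict = strict,
                 capture_comments = capture_comments, on_error = on_error),
            class = "star_entry_stream")
}

#' Pull the next entry from a stream
#'
#' @param stream A `star_entry_stream` from [read_star_entries()].
#' @return The next [star_entry], or `NULL` when the stream is exhausted.
#' @export
next_entry <- function(stream) {
  stopifnot(inherits(stream, "star_entry_stream"))
  st <- stream$state
  repeat {
    while (st$member_i >= length(st$members)) {
      if (st$spec_i >= length(st$specs)) return(NULL)
      st$spec_i <- st$spec_i + 1L
      spec <- st$specs[[st$spec_i]]
      st$members <- resolve_source(spec)
      st$member_i <- 0L
      st$hint <- spec$format_hint
    }
    st$member_i <- st$member_i + 1L
    m <- st$members[[st$member_i]]
    res <- tryCatch({
      txt <- m$read()
      st$docs_read <- st$docs_read + 1L
      fmt <- detect_format(txt, st$hint)
      if (fmt == "json")
        from_json_star(txt, source = m$name)
      else
        parse_star(txt, strict = stream$strict,
                   capture_comments = stream$capture_comments,
                   source = m$name)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (stream$on_error == "stop") stop(res)
      st$failed <- st$failed + 1L
      warning(sprintf("skipping %s: %s", m$name, conditionMessage(res)))
      next
    }
    return(res)
  }
}

#' Drain a stream into a list of entries
#'
#' @param stream A `star_entry_stream`.
#' @param n Maximum number of entries to pull (default: all).
#' @return List of [star_entry] objects in source order.
#' @export
collect_entries <- function(stream, n = Inf) {
  out <- list()
  while (length(out) < n) {
    e <- next_entry(stream)
    if (is.null(e)) break
    out[[length(out) + 1L]] <- e
  }
  out
}

#' @export
print.star_entry_stream <- function(x, ...) {
  st <- x$state
  cat("<star_entry_stream> ", length(st$specs), " source(s); ",
      st$docs_read, " document(s) read so far\n", sep = "")
  invisible(x)
}
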