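#' @title Deterministic synthetic NMR-STAR fixtures
#'
#' @description
#' The generator emits synthetic NMR-STAR documents together with the exact
#' entry object a correct parser must produce from them, plus a manifest of
#' ground-truth counts.  Because the raw document text is written directly
#' (not through the package's writer), the generator can exercise surface
#' syntax a well-behaved writer never produces -- in particular the three
#' multiline constructions known to break regex-based NMR-STAR parsers:
#' a semicolon embedded inside multiline text, a multiline block whose
#' closing delimiter is not followed by a newline (end of file), and a
#' multiline block whose closing delimiter line is immediately followed by
#' `loop_`.  Random values draw from a pool that includes whitespace, `#`,
#' `$`, quotes, `.`/`?` placeholders and keyword lookalikes, so that the
#' writer's quoting policy is exercised on round trips.
#'
#' Same spec + same seed gives byte-identical output and manifest.
#'
#' @name star-fixtures
NULL

with_preserved_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  fn()
}

ri <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
pick <- function(x) x[[ri(1L, length(x))]]

edge_flag_names <- c("EMBEDDED_SEMICOLON", "MULTILINE_NO_TRAILING_NEWLINE",
                     "MULTILINE_THEN_LOOP", "QUOTES_IN_VALUES",
                     "EMPTY_LOOP", "COMMENTS", "V21_SHIFTS", "V31_SHIFTS")

#' The edge-case flags the fixture generator understands
#'
#' @return Character vector of the eight recognized edge flags.
#' @export
fixture_edge_flags <- function() edge_flag_names

bare_pool <- c("12.5", "-3.07", "0.001", "298", "7.4", "ALA", "GLY", "HIS",
               "H", "CA", "N15", "yes", "no", "x1y2", "uniprot:P0AG67",
               "1AKE", "monomer", "reduced")
quoted_pool <- c("a b", "two words here", "it's", "don't stop", "say \"hi\"",
                 "#not a comment", "_leading_underscore", "loop_", "stop_",
                 "save_frame", "data_99", ";starts with semicolon",
                 "trailing space ")
multiline_pool <- c("Helix is ;near the C-term",
                    "line one\nline two",
                    "alpha\nbeta ; gamma\ndelta",
                    "sequence:\nMKVL AHGI\nRRQW TTES",
                    "ends with a blank line\n")
framecode_pool <- c("$entry_information", "$sample_1", "$software_3")

random_value <- function() {
  r <- runif(1)
  if (r < 0.45) pick(bare_pool)
  else if (r < 0.55) pick(c(".", "?"))
  else if (r < 0.62) pick(framecode_pool)
  else if (r < 0.82) pick(quoted_pool)
  else if (r < 0.92) pick(multiline_pool)
  else ""
}

random_bareish_value <- function() {
  r <- runif(1)
  if (r < 0.7) pick(bare_pool) else pick(c(".", "?"))
}

#' Specify a synthetic fixture
#'
#' @param seed Integer seed; same spec + seed is byte-identical output.
#' @param n_saveframes Number of ordinary saveframes (shift saveframes from
#'   edge flags come in addition).
#' @param loops_per_saveframe,fields_per_loop,records_per_loop Length-2
#'   integer ranges sampled per saveframe/loop.
#' @param edge_flags Character subset of
#'   `EMBEDDED_SEMICOLON`, `MULTILINE_NO_TRAILING_NEWLINE`,
#'   `MULTILINE_THEN_LOOP`, `QUOTES_IN_VALUES`, `EMPTY_LOOP`, `COMMENTS`,
#'   `V21_SHIFTS`, `V31_SHIFTS`; each enabled flag is exercised at least
#'   once in the document.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_saveframes = 2L,
                         loops_per_saveframe = c(0L, 2L),
                         fields_per_loop = c(1L, 4L),
                         records_per_loop = c(0L, 4L),
                         edge_flags = character()) {
  stopifnot(all(edge_flags %in% edge_flag_names),
            n_saveframes >= 0L,
            length(loops_per_saveframe) == 2L,
            length(fields_per_loop) == 2L, fields_per_loop[1] >= 1L,
            length(records_per_loop) == 2L)
  structure(list(seed = as.integer(seed), n_saveframes = as.integer(n_saveframes),
                 loops_per_saveframe = as.integer(loops_per_saveframe),
                 fields_per_loop = as.integer(fields_per_loop),
                 records_per_loop = as.integer(records_per_loop),
                 edge_flags = edge_flags),
            class = "fixture_spec")
}

# ---- shift composition ------------------------------------------------------

residue_atom_pool <- list(
  ALA = c("H", "N", "CA", "CB", "HA"),
  GLY = c("H", "N", "CA", "HA"),
  GLU = c("H", "N", "CA", "CB", "CG"),
  THR = c("H", "N", "CA", "CB", "CG2"),
  SER = c("H", "N", "CA", "CB", "HB2"),
  LEU = c("H", "N", "CA", "CB", "CD1")
)

typical_shift <- function(atom) {
  base <- switch(substr(atom, 1L, 1L),
                 H = 6.5, N = 115, C = 35, 50)
  if (atom == "CA") base <- 55
  if (atom == "CB") base <- 32
  if (atom %in% c("CG", "CG2", "CD1")) base <- 22
  if (atom == "HA") base <- 4.2
  sprintf("%.2f", base + runif(1, -2, 2))
}

random_shift_composition <- function(label) {
  n_res <- ri(2L, 5L)
  residues <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    type <- pick(names(residue_atom_pool))
    pool <- residue_atom_pool[[type]]
    n_atoms <- ri(2L, length(pool))
    atoms_names <- pool[sort(sample.int(length(pool), n_atoms))]
    atoms <- lapply(atoms_names, function(a)
      list(atom = a, value = typical_shift(a)))
    residues[[i]] <- list(seq = i + 1L, type = type, atoms = atoms)
  }
  list(label = label, residues = residues)
}

shift_loop_from_composition <- function(comp, version) {
  if (version == "3.1") {
    fields <- c("_Atom_chem_shift.ID", "_Atom_chem_shift.Seq_ID",
                "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
                "_Atom_chem_shift.Atom_type", "_Atom_chem_shift.Val",
                "_Atom_chem_shift.Val_err", "_Atom_chem_shift.Ambiguity_code")
  } else {
    fields <- c("_Atom_shift_assign_ID", "_Residue_seq_code",
                "_Residue_label", "_Atom_name", "_Atom_type",
                "_Chem_shift_value", "_Chem_shift_value_error",
                "_Chem_shift_ambiguity_code")
  }
  records <- list()
  id <- 0L
  for (res in comp$residues) {
    for (at in res$atoms) {
      id <- id + 1L
      rec <- c(as.character(id), as.character(res$seq), res$type,
               at$atom, substr(at$atom, 1L, 1L), at$value, "0.02", "1")
      names(rec) <- fields
      records[[length(records) + 1L]] <- rec
    }
  }
  star_loop(fields, records)
}

shift_frame_from_composition <- function(comp, version) {
  loop <- shift_loop_from_composition(comp, version)
  if (version == "3.1") {
    star_saveframe(
      `_Assigned_chem_shift_list.Sf_category` = "assigned_chemical_shifts",
      `_Assigned_chem_shift_list.Sf_framecode` = comp$label,
      loop_0 = loop)
  } else {
    star_saveframe(
      `_Saveframe_category` = "assigned_chemical_shifts",
      `_Details` = ".",
      loop_0 = loop)
  }
}

# render members of a saveframe (or entry level) to raw document lines,
# using the package's quoting policy for ordinary values
emit_members <- function(members) {
  out <- character(0)
  for (k in names(members)) {
    v <- members[[k]]
    if (is_star_loop(v)) {
      out <- c(out, "loop_\n", paste0("   ", v$fields, "\n"))
      for (rec in v$records) {
        row <- "   "
        for (val in rec) {
          frag <- format_value(val)
          if (startsWith(frag, "\n;")) {
            out <- c(out, sub(" +$", "", row), frag)
            row <- "   "
          } else {
            row <- paste0(row, frag, " ")
          }
        }
        if (nzchar(trimws(row))) out <- c(out, sub(" $", "", row), "\n")
      }
      out <- c(out, "stop_\n")
    } else if (grepl("^comment_[0-9]+$", k)) {
      out <- c(out, paste0("# ", v, "\n"))
    } else {
      frag <- format_value(v)
      if (startsWith(frag, "\n;")) out <- c(out, k, frag)
      else out <- c(out, k, " ", frag, "\n")
    }
  }
  out
}

#' Generate one synthetic NMR-STAR document with ground truth
#'
#' @param spec A [fixture_spec()].
#' @return List with components:
#'   \describe{
#'     \item{text}{the raw NMR-STAR document,}
#'     \item{entry}{the exact [star_entry] a correct parse (without comment
#'       capture) must produce,}
#'     \item{manifest}{ground-truth record: `data_id`, `counts` (from
#'       [star_counts()]), `key_order` (from [star_key_order()]),
#'       `n_comments`, `edge_flags`, and `shifts` (the chain/residue/atom
#'       composition when shift flags are set).}
#'   }
#' @export
generate_star_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, function() generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  flags <- spec$edge_flags
  has <- function(f) f %in% flags
  id <- as.character(ri(10000L, 99999L))
  n_comments <- 0L

  doc <- paste0("data_", id, "\n\n")
  if (has("COMMENTS")) {
    doc <- c(doc, "# synthetic entry-level comment\n")
    n_comments <- n_comments + 1L
  }

  entry_members <- list()
  shifts <- list()

  make_loop <- function(forced_empty = FALSE) {
    nf <- ri(spec$fields_per_loop[1], spec$fields_per_loop[2])
    nr <- if (forced_empty) 0L
          else ri(spec$records_per_loop[1], spec$records_per_loop[2])
    fields <- paste0("_", pick(c("Atom", "Sample", "Cond", "Ref")),
                     "_f", seq_len(nf), "_", ri(1L, 99L))
    records <- lapply(seq_len(nr), function(i) {
      rec <- vapply(seq_len(nf), function(j) {
        # multiline values inside loops are legal but rarer
        if (runif(1) < 0.1) pick(multiline_pool) else random_bareish_value()
      }, character(1))
      names(rec) <- fields
      rec
    })
    star_loop(fields, records)
  }

  for (fi in seq_len(spec$n_saveframes)) {
    fname <- sprintf("frame_%d", fi)
    members <- list()
    n_tags <- ri(1L, 4L)
    for (ti in seq_len(n_tags)) {
      members[[sprintf("_Tag_%d_%d", fi, ti)]] <- random_value()
    }
    if (has("QUOTES_IN_VALUES") && fi == 1L) {
      members[["_Forced_quote"]] <- "don't stop"
      members[["_Forced_dquote"]] <- "he said 'go'"
    }
    if (has("EMBEDDED_SEMICOLON") && fi == 1L) {
      members[["_Embedded_semicolon"]] <- "Helix is ;near the C-term"
    }
    n_loops <- ri(spec$loops_per_saveframe[1], spec$loops_per_saveframe[2])
    loop_i <- 0L
    for (li in seq_len(n_loops)) {
      members[[paste0("loop_", loop_i)]] <- make_loop()
      loop_i <- loop_i + 1L
    }
    if (has("EMPTY_LOOP") && fi == 1L) {
      members[[paste0("loop_", loop_i)]] <- make_loop(forced_empty = TRUE)
      loop_i <- loop_i + 1L
    }
    mtl <- has("MULTILINE_THEN_LOOP") && fi == 1L
    if (mtl) {
      members[["_Multiline_then_loop"]] <- "multiline quoted text"
      members[[paste0("loop_", loop_i)]] <-
        star_loop("_Edge_field", list(c(`_Edge_field` = "edge_v1"),
                                      c(`_Edge_field` = "edge_v2")))
      loop_i <- loop_i + 1L
    }
    frame <- structure(members, class = "star_saveframe")
    entry_members[[fname]] <- frame

    # ---- raw text for this frame ----
    doc <- c(doc, paste0("save_", fname, "\n"))
    if (mtl) {
      # everything before the edge construction goes through the normal
      # emitter; the multiline-then-loop surface syntax is written raw
      pre <- members[seq_len(length(members) - 2L)]
      doc <- c(doc, emit_members(pre))
      doc <- c(doc, "_Multiline_then_loop\n;\nmultiline quoted text\n",
               ";loop_\n   _Edge_field\nedge_v1\nedge_v2\nstop_\n")
    } else {
      doc <- c(doc, emit_members(members))
    }
    if (has("COMMENTS") && fi == 1L) {
      doc <- c(doc, "# synthetic frame-level comment\n")
      n_comments <- n_comments + 1L
    }
    doc <- c(doc, "save_\n\n")
  }

  for (ver in c("2.1", "3.1")) {
    flag <- if (ver == "2.1") "V21_SHIFTS" else "V31_SHIFTS"
    if (!has(flag)) next
    label <- if (has("V21_SHIFTS") && has("V31_SHIFTS"))
      paste0("assigned_chem_shift_list_",
             if (ver == "2.1") "A" else "B")
    else "assigned_chem_shift_list_1"
    comp <- random_shift_composition(label)
    frame <- shift_frame_from_composition(comp, ver)
    entry_members[[label]] <- frame
    shifts[[length(shifts) + 1L]] <- c(comp, list(version = ver))
    doc <- c(doc, paste0("save_", label, "\n"),
             emit_members(unclass(frame)), "save_\n\n")
  }

  if (has("MULTILINE_NO_TRAILING_NEWLINE")) {
    entry_members[["_Closing_note"]] <- "final remark; unterminated line"
    doc <- c(doc, "_Closing_note\n;\nfinal remark; unterminated line\n;")
  }

  entry <- do.call(star_entry, c(list(id = id), entry_members))
  text <- paste(doc, collapse = "")
  manifest <- list(data_id = id,
                   counts = star_counts(entry),
                   key_order = as.list(star_key_order(entry)),
                   loops = star_loop_shapes(entry),
                   n_comments = n_comments,
                   edge_flags = as.list(flags),
                   shifts = shifts)
  list(text = text, entry = entry, manifest = manifest)
}

#' Generate an adversarial document for lexer verification
#'
#' Assembles a random token soup -- bare words, keyword lookalikes in mixed
#' case, tags, quoted strings with interior quote characters, comments,
#' `#`/`$`/`;` inside words, tab/space runs, CRLF line endings, and multiline
#' blocks with interior semicolons, blocks immediately followed by `loop_`,
#' and blocks at end-of-file without a trailing newline.  The result is
#' lexically valid but deliberately not a well-formed entry; its only
#' purpose is comparing [tokenize()] against [tokenize_reference()].
#'
#' @param seed Integer seed.
#' @return Character scalar document text.
#' @export
generate_lex_document <- function(seed) {
  with_preserved_seed(seed, function() {
    word_pool <- c(bare_pool, ".", "?", "$frame_ref", "_a_tag", "_Other.Tag",
                   "x#y", "a;b", ";midline", "DATA_91", "Save_block", "LOOP_",
                   "STOP_", "save_", "stop_", "ab'cd", "d\"e")
    quoted <- function() {
      q <- pick(c("'", "\""))
      inner <- pick(c("plain", "two words", "it's ok", "say \"hi\"",
                      "semi ; colon", "#hash", "", "tricky'quote"))
      if (q == "'" ) inner <- gsub("'(?=[ \t]|$)", "", inner, perl = TRUE)
      else inner <- gsub("\"(?=[ \t]|$)", "", inner, perl = TRUE)
      paste0(q, inner, q)
    }
    block <- function() {
      n <- ri(0L, 3L)
      lines <- vapply(seq_len(n), function(i)
        pick(c("text line", "has ; semicolon", "  indented", "q'uo\"te", "")),
        character(1))
      paste0(";", if (runif(1) < 0.3) " opening rest" else "",
             "\n", paste0(lines, "\n", collapse = ""), ";")
    }
    n_lines <- ri(3L, 15L)
    out <- character(0)
    for (i in seq_len(n_lines)) {
      r <- runif(1)
      if (r < 0.15) {
        out <- c(out, paste0("# comment ", ri(1L, 99L), "\n"))
      } else if (r < 0.35) {
        suffix <- if (runif(1) < 0.4) pick(c("loop_", " stop_", "_T v", ""))
                  else ""
        out <- c(out, block(), suffix, "\n")
      } else if (r < 0.4) {
        out <- c(out, "\n")
      } else {
        k <- ri(1L, 5L)
        toks <- vapply(seq_len(k), function(j)
          if (runif(1) < 0.25) quoted() else pick(word_pool), character(1))
        sep <- pick(c(" ", "  ", "\t"))
        soup <- paste(toks, collapse = sep)
        # a line-initial ";" would open a multiline block: keep the word form
        if (startsWith(soup, ";")) soup <- paste0(" ", soup)
        out <- c(out, soup, if (runif(1) < 0.1) "\r\n" else "\n")
      }
    }
    txt <- paste(out, collapse = "")
    if (runif(1) < 0.3) txt <- paste0(txt, block())   # EOF without newline
    txt
  })
}

#' Generate matched v2.1/v3.1 chemical-shift documents
#'
#' Emits two documents that encode one randomly drawn chain/residue/atom
#' composition in the version 2.1 and version 3.1 tag schemas respectively,
#' with identically named shift saveframes, so that their extracted
#' chemical-shift tables must be identical.
#'
#' @param seed Integer seed.
#' @return List with `v21` and `v31` (document texts), `composition` (the
#'   shared chain composition) and `entry_id`.
#' @export
generate_shift_pair <- function(seed) {
  with_preserved_seed(seed, function() {
    id <- as.character(ri(10000L, 99999L))
    comp <- random_shift_composition("assigned_chem_shift_list_1")
    texts <- lapply(c("2.1", "3.1"), function(ver) {
      frame <- shift_frame_from_composition(comp, ver)
      entry <- star_entry(id, assigned_chem_shift_list_1 = frame)
      format_star(entry)
    })
    list(v21 = texts[[1L]], v31 = texts[[2L]],
         composition = comp, entry_id = id)
  })
}

#' Generate a corpus of fixtures with a manifest index
#'
#' Writes `n` fixture files -- into a directory, or packed into a zip,
#' tar.gz or tar.bz2 archive when `out_path` carries that extension -- plus
#' a machine-readable JSON manifest index written next to the corpus as
#' `<out>.manifest.json`.  Edge flags are
#' assigned round-robin (fixture `i` always carries flag `(i-1) mod 8`) plus
#' random extras, so every flag is guaranteed to appear in at least
#' `floor(n/8)` fixtures.
#'
#' @param n Number of fixtures (>= 1).
#' @param seed Integer master seed; per-file seeds derive from it.
#' @param out_path Target directory or archive path.
#' @param format `"nmrstar"`, `"json"` (JSONized equivalents) or `"mixed"`
#'   (alternating).
#' @return Invisibly, the manifest index: list with `seed`, `n`, `format`
#'   and `files`, each file recording `name`, `seed`, `edge_flags`,
#'   `counts`, `key_order`, `n_comments`, `shifts` and `entry_json` (the
#'   expected entry, JSON-encoded, from which the expected object can be
#'   rebuilt with [from_json_star()]).
#' @export
generate_corpus <- function(n, seed, out_path,
                            format = c("nmrstar", "json", "mixed")) {
  stopifnot(n >= 1L)
  format <- match.arg(format)
  kind <- archive_kind(out_path)
  dir <- if (is.na(kind)) out_path else tempfile("corpus_build_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vector("list", n)
  extra <- with_preserved_seed(seed, function()
    matrix(runif(n * length(edge_flag_names)) < 0.15, nrow = n))
  for (i in seq_len(n)) {
    file_seed <- (as.integer(seed) + i * 7919L) %% 2147483647L
    flags <- edge_flag_names[unique(c((i - 1L) %% 8L + 1L,
                                         which(extra[i, ])))]
    fx <- generate_star_fixture(fixture_spec(file_seed, edge_flags = flags))
    fmt_i <- switch(format, nmrstar = "nmrstar", json = "json",
                    mixed = if (i %% 2L == 0L) "json" else "nmrstar")
    name <- sprintf("fixture_%04d.%s", i,
                    if (fmt_i == "json") "json" else "str")
    txt <- if (fmt_i == "json") paste0(to_json_star(fx$entry), "\n")
           else fx$text
    writeLines(txt, file.path(dir, name), sep = "", useBytes = TRUE)
    files[[i]] <- c(list(name = name, seed = file_seed, format = fmt_i,
                         entry_json = to_json_star(fx$entry)),
                    fx$manifest)
  }
  index <- list(seed = as.integer(seed), n = as.integer(n), format = format,
                files = files)
  index_path <- paste0(sub("/+$", "", out_path), ".manifest.json")
  if (!is.na(kind)) {
    pack_archive(dir, out_path, kind)
    unlink(dir, recursive = TRUE)
  }
  jsonlite::write_json(index, index_path, auto_unbox = TRUE, digits = NA)
  invisible(index)
}

#' Load a corpus manifest index written by [generate_corpus()]
#'
#' @param path Path to the manifest JSON.
#' @return The manifest index list (member order preserved).
#' @export
read_corpus_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
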