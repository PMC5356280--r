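#' @title Assigned chemical-shift extraction and visualization
#'
#' @description
#' BMRB entries store assigned chemical shifts (the resonance frequency
#' offset of each atom, in ppm) in a loop whose tag schema differs between
#' NMR-STAR versions: 3.1 uses `_Atom_chem_shift.Seq_ID` /
#' `.Comp_ID` / `.Atom_ID` / `.Val`, while 2.1 uses `_Residue_seq_code` /
#' `_Residue_label` / `_Atom_name` / `_Chem_shift_value`.  Discovery keys off
#' these loop field schemas rather than saveframe category tags, because
#' category tag names differ across versions and legacy files mislabel them.
#' Either version normalizes to the same per-residue table, and one entry
#' can carry several shift saveframes (e.g. one per molecular chain).
#'
#' @name star-chemshift
NULL

v31_shift_fields <- c("_Atom_chem_shift.Seq_ID", "_Atom_chem_shift.Comp_ID",
                      "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val")
v21_shift_fields <- c("_Residue_seq_code", "_Residue_label",
                      "_Atom_name", "_Chem_shift_value")

shift_loop_version <- function(loop) {
  if (all(v31_shift_fields %in% loop$fields)) return("3.1")
  if (all(v21_shift_fields %in% loop$fields)) return("2.1")
  NA_character_
}

shift_loop_to_rows <- function(loop, chain, version) {
  df <- as.data.frame(loop)
  cols <- if (version == "3.1") v31_shift_fields else v21_shift_fields
  out <- data.frame(chain = rep(chain, nrow(df)),
                    seq_id = suppressWarnings(as.integer(df[[cols[1L]]])),
                    comp_id = df[[cols[2L]]],
                    atom_id = df[[cols[3L]]],
                    value = df[[cols[4L]]],
                    stringsAsFactors = FALSE)
  bad <- suppressWarnings(is.na(as.numeric(out$value)))
  if (any(bad))
    warning(sprintf("%d shift value(s) do not parse as decimal numbers",
                    sum(bad)))
  out
}

#' Extract assigned chemical shifts from an entry
#'
#' Scans every saveframe's loops (and data-block-level loops) for the
#' version 3.1 or version 2.1 assigned-chemical-shift schema and normalizes
#' all matches into one table.  Each matching saveframe becomes one chain,
#' labeled with the saveframe name; residues within a chain are ordered by
#' sequence position (stable for equal positions); duplicate atom names
#' within a residue keep the first occurrence with a warning.
#'
#' @param entry A [star_entry].
#' @return A `chemshift_table`: data.frame with character columns `chain`,
#'   `comp_id`, `atom_id`, `value` and integer `seq_id`, plus attribute
#'   `entry_id`.  Shift values stay strings for display fidelity (numeric
#'   parseability is validated with a warning only).
#' @export
extract_shifts <- function(entry) {
  stopifnot(inherits(entry, "star_entry"))
  rows <- list()
  scan_members <- function(members, chain) {
    for (k in names(members)) {
      v <- members[[k]]
      if (is_star_loop(v)) {
        ver <- shift_loop_version(v)
        if (!is.na(ver))
          rows[[length(rows) + 1L]] <<- shift_loop_to_rows(v, chain, ver)
      }
    }
  }
  body <- entry[-1L]
  for (k in names(body)) {
    v <- body[[k]]
    if (is_star_saveframe(v)) scan_members(unclass(v), chain = k)
  }
  scan_members(body[!vapply(body, is_star_saveframe, logical(1))],
               chain = entry$data)
  if (!length(rows))
    stop("no assigned chemical shift loop found: searched all loops for ",
         "the version 3.1 schema (", paste(v31_shift_fields, collapse = ", "),
         ") and the version 2.1 schema (",
         paste(v21_shift_fields, collapse = ", "), ")")
  tab <- do.call(rbind, rows)
  # order residues by sequence position within each chain (stable)
  chain_order <- match(tab$chain, unique(tab$chain))
  tab <- tab[order(chain_order, tab$seq_id), , drop = FALSE]
  rownames(tab) <- NULL
  # atom names unique within a residue
  key <- paste(tab$chain, tab$seq_id, tab$atom_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate atom names within a residue: keeping first occurrence")
    tab <- tab[!duplicated(key), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, entry_id = entry$data,
            class = c("chemshift_table", "data.frame"))
}

#' Filter a chemical-shift table by residue type and atom name
#'
#' @param table A `chemshift_table`.
#' @param aminoacids Optional character vector of 3-letter residue codes to
#'   keep (e.g. `c("GLU", "THR")`); `NULL` or empty keeps all.
#' @param atoms Optional character vector of atom names to keep (e.g.
#'   `c("CA", "CB")`); `NULL` or empty keeps all.
#' @return The filtered `chemshift_table`, order preserved.  Filters that
#'   empty the table are legal.
#' @export
filter_shifts <- function(table, aminoacids = NULL, atoms = NULL) {
  stopifnot(inherits(table, "chemshift_table"))
  keep <- rep(TRUE, nrow(table))
  if (length(aminoacids)) keep <- keep & table$comp_id %in% aminoacids
  if (length(atoms)) keep <- keep & table$atom_id %in% atoms
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, entry_id = attr(table, "entry_id"),
            class = c("chemshift_table", "data.frame"))
}

#' @export
print.chemshift_table <- function(x, ...) {
  cat("<chemshift_table> entry ", attr(x, "entry_id"), ": ",
      length(unique(x$chain)), " chain(s), ",
      nrow(unique(data.frame(x$chain, x$seq_id))), " residue(s), ",
      nrow(x), " shift(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Render a chemical-shift table as a residue tree graph
#'
#' Emits a DOT-language tree: root = entry id, children = chains,
#' grandchildren = residue nodes labeled `<Type><Position>` (e.g. `GLU2`),
#' leaves = `<atom>: <value>` labels.  For image formats the external
#' Graphviz `dot` layout engine is invoked when present on the PATH;
#' otherwise the DOT text is written (with a `.dot` extension and a warning)
#' so no information is lost.
#'
#' @param table A non-empty `chemshift_table`.
#' @param out_path Output file path (extension not added for `dot` format).
#' @param image_format `"dot"` (default), `"png"`, `"pdf"` or `"svg"`.
#' @return Invisibly, the path actually written.
#' @export
render_graph <- function(table, out_path,
                         image_format = c("dot", "png", "pdf", "svg")) {
  stopifnot(inherits(table, "chemshift_table"))
  image_format <- match.arg(image_format)
  if (nrow(table) == 0L)
    stop("refusing to render an empty chemical-shift table ",
         "(no residues left after filtering?)")
  lines <- c("digraph chemshifts {",
             "  node [shape=box, fontname=\"Helvetica\"];",
             sprintf("  root [label=%s];", dot_quote(attr(table, "entry_id"))))
  edges <- character(0)
  chains <- unique(table$chain)
  atom_n <- 0L
  for (ci in seq_along(chains)) {
    cid <- sprintf("chain_%d", ci)
    lines <- c(lines, sprintf("  %s [label=%s];", cid, dot_quote(chains[ci])))
    edges <- c(edges, sprintf("  root -> %s;", cid))
    sub <- table[table$chain == chains[ci], , drop = FALSE]
    res_keys <- unique(sub$seq_id)
    for (ri in seq_along(res_keys)) {
      rsub <- sub[sub$seq_id == res_keys[ri], , drop = FALSE]
      rid <- sprintf("%s_res_%d", cid, ri)
      rlabel <- paste0(rsub$comp_id[1L], rsub$seq_id[1L])
      lines <- c(lines, sprintf("  %s [label=%s];", rid, dot_quote(rlabel)))
      edges <- c(edges, sprintf("  %s -> %s;", cid, rid))
      for (ai in seq_len(nrow(rsub))) {
        atom_n <- atom_n + 1L
        aid <- sprintf("atom_%d", atom_n)
        alabel <- paste0(rsub$atom_id[ai], ": ", rsub$value[ai])
        lines <- c(lines, sprintf("  %s [label=%s];", aid, dot_quote(alabel)))
        edges <- c(edges, sprintf("  %s -> %s;", rid, aid))
      }
    }
  }
  dot_text <- paste(c(lines, edges, "}", ""), collapse = "\n")
  if (image_format == "dot") {
    writeLines(dot_text, out_path, sep = "")
    return(invisible(out_path))
  }
  dot_bin <- Sys.which("dot")
  if (nzchar(dot_bin)) {
    tmp <- tempfile(fileext = ".dot")
    on.exit(unlink(tmp))
    writeLines(dot_text, tmp, sep = "")
    status <- system2(dot_bin, c(paste0("-T", image_format), tmp,
                                 "-o", shQuote(out_path)))
    if (status != 0L) stop("graphviz 'dot' failed with status ", status)
    return(invisible(out_path))
  }
  fallback <- paste0(tools::file_path_sans_ext(out_path), ".dot")
  warning("graphviz 'dot' not found on PATH: writing DOT text to ", fallback)
  writeLines(dot_text, fallback, sep = "")
  invisible(fallback)
}

#' Count the nodes in a DOT file produced by [render_graph()]
#'
#' Convenience for verification: every node definition line contains a
#' `[label=` attribute, so the node count is the number of such lines.
#' For a shift table the count obeys
#' `1 + n_chains + n_residues + n_atoms`.
#'
#' @param path Path to a `.dot` file.
#' @return Integer node count.
#' @export
dot_node_count <- function(path) {
  sum(grepl("\\[label=", readLines(path)))
}
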