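shift_fixture <- function(seed, flags = "V31_SHIFTS") {
  fx <- generate_star_fixture(fixture_spec(seed, edge_flags = flags))
  list(fx = fx, entry = fx$entry,
       comp = fx$manifest$shifts)
}

comp_n_residues <- function(comp) length(comp$residues)
comp_n_atoms <- function(comp) sum(lengths(lapply(comp$residues, `[[`, "atoms")))

test_that("v3.1 shift loops extract with manifest-predicted composition", {
  sf <- shift_fixture(801)
  tab <- extract_shifts(sf$entry)
  comp <- sf$comp[[1]]
  expect_s3_class(tab, "chemshift_table")
  expect_identical(attr(tab, "entry_id"), sf$fx$manifest$data_id)
  expect_identical(length(unique(tab$chain)), 1L)
  expect_identical(length(unique(tab$seq_id)), comp_n_residues(comp))
  expect_identical(nrow(tab), comp_n_atoms(comp))
  # every manifest atom appears with its value
  for (res in comp$residues) for (at in res$atoms) {
    row <- tab[tab$seq_id == res$seq & tab$atom_id == at$atom, ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$value, at$value)
    expect_identical(row$comp_id, res$type)
  }
})

test_that("v2.1 and v3.1 encodings of one composition extract identically", {
  for (s in c(811, 812, 813)) {
    pair <- generate_shift_pair(s)
    t21 <- extract_shifts(parse_star(pair$v21))
    t31 <- extract_shifts(parse_star(pair$v31))
    expect_identical(as.data.frame(t21), as.data.frame(t31))
    expect_identical(attr(t21, "entry_id"), attr(t31, "entry_id"))
  }
})

test_that("multiple shift saveframes become multiple chains", {
  sf <- shift_fixture(821, flags = c("V21_SHIFTS", "V31_SHIFTS"))
  tab <- extract_shifts(sf$entry)
  expect_identical(length(unique(tab$chain)), 2L)
  expect_identical(unique(tab$chain),
                   vapply(sf$comp, `[[`, character(1), "label"))
})

test_that("entries without shifts raise a descriptive error", {
  err <- tryCatch(extract_shifts(minimal_entry()), error = identity)
  expect_match(conditionMessage(err), "_Atom_chem_shift.Seq_ID")
  expect_match(conditionMessage(err), "_Residue_seq_code")
})

test_that("residues are ordered by sequence position within each chain", {
  loop <- star_loop(v31 <- c("_Atom_chem_shift.Seq_ID",
                             "_Atom_chem_shift.Comp_ID",
                             "_Atom_chem_shift.Atom_ID",
                             "_Atom_chem_shift.Val"),
                    list(setNames(c("3", "GLY", "CA", "45.1"), v31),
                         setNames(c("1", "ALA", "CA", "52.2"), v31),
                         setNames(c("2", "SER", "CA", "58.3"), v31)))
  e <- star_entry("5", shifts = star_saveframe(loop_0 = loop))
  tab <- extract_shifts(e)
  expect_identical(tab$seq_id, 1:3)
  expect_identical(tab$comp_id, c("ALA", "SER", "GLY"))
})

test_that("non-numeric shift values only warn", {
  loop <- star_loop(v31 <- c("_Atom_chem_shift.Seq_ID",
                             "_Atom_chem_shift.Comp_ID",
                             "_Atom_chem_shift.Atom_ID",
                             "_Atom_chem_shift.Val"),
                    list(setNames(c("1", "ALA", "CA", "not-a-number"), v31)))
  e <- star_entry("5", shifts = star_saveframe(loop_0 = loop))
  expect_warning(tab <- extract_shifts(e), "do not parse as decimal")
  expect_identical(tab$value, "not-a-number")
})

test_that("filtering keeps the requested residues and atoms, in order", {
  sf <- shift_fixture(831)
  tab <- extract_shifts(sf$entry)
  types <- unique(tab$comp_id)
  f1 <- filter_shifts(tab, aminoacids = types[1])
  expect_true(all(f1$comp_id == types[1]))
  f2 <- filter_shifts(tab, atoms = "CA")
  expect_true(all(f2$atom_id == "CA"))
  # no filters: identity
  expect_identical(as.data.frame(filter_shifts(tab)), as.data.frame(tab))
  # idempotence and commutation
  a <- filter_shifts(filter_shifts(tab, aminoacids = types[1]), atoms = "CA")
  b <- filter_shifts(filter_shifts(tab, atoms = "CA"), aminoacids = types[1])
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(as.data.frame(filter_shifts(a, aminoacids = types[1])),
                   as.data.frame(a))
  # emptying filters are legal
  expect_identical(nrow(filter_shifts(tab, aminoacids = "TRP")), 0L)
})

test_that("the documented residue/atom filter keeps exactly that set", {
  pair <- generate_shift_pair(841)
  tab <- extract_shifts(parse_star(pair$v31))
  f <- filter_shifts(tab, aminoacids = c("GLU", "THR"),
                     atoms = c("CA", "CB", "CG", "CG2"))
  expect_true(all(f$comp_id %in% c("GLU", "THR")))
  expect_true(all(f$atom_id %in% c("CA", "CB", "CG", "CG2")))
  manual <- tab[tab$comp_id %in% c("GLU", "THR") &
                tab$atom_id %in% c("CA", "CB", "CG", "CG2"), ]
  expect_identical(nrow(f), nrow(manual))
})

test_that("DOT output has 1 + chains + residues + atoms nodes", {
  for (s in c(851, 852)) {
    sf <- shift_fixture(s, flags = c("V21_SHIFTS", "V31_SHIFTS"))
    tab <- extract_shifts(sf$entry)
    path <- withr::local_tempfile(fileext = ".dot")
    render_graph(tab, path, image_format = "dot")
    n_chains <- length(sf$comp)
    n_res <- sum(vapply(sf$comp, comp_n_residues, integer(1)))
    n_atoms <- sum(vapply(sf$comp, comp_n_atoms, integer(1)))
    expect_identical(dot_node_count(path), 1L + n_chains + n_res + n_atoms)
    txt <- paste(readLines(path), collapse = "\n")
    expect_match(txt, "digraph")
    # residue labels are <Type><Position>
    r1 <- sf$comp[[1]]$residues[[1]]
    expect_match(txt, paste0('"', r1$type, r1$seq, '"'), fixed = TRUE)
  }
})

test_that("rendering an empty table is refused", {
  sf <- shift_fixture(861)
  empty <- filter_shifts(extract_shifts(sf$entry), aminoacids = "TRP")
  expect_error(render_graph(empty, tempfile()), "empty")
})

test_that("image formats render via graphviz or fall back to DOT", {
  sf <- shift_fixture(871)
  tab <- extract_shifts(sf$entry)
  out <- file.path(withr::local_tempdir(), "view.png")
  if (nzchar(Sys.which("dot"))) {
    written <- render_graph(tab, out, image_format = "png")
    expect_true(file.exists(written))
  } else {
    expect_warning(written <- render_graph(tab, out, image_format = "png"),
                   "not found")
    expect_match(written, "\\.dot$")
    expect_gt(dot_node_count(written), 0L)
  }
})
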