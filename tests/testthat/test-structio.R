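test_that("hand-written PDB text parses with coordinates and order intact", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA B   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_s3_class(s, "pepstruct")
  expect_equal(nrow(s), 3)
  expect_equal(s$name, c("N", "CA", "C"))
  expect_equal(s$chain, c("A", "A", "B"))          # both chains, in order
  expect_equal(s$x, c(0, 1.458, 2.009))
  expect_true(all(is.na(s$charge)))                # PDB leaves charge unset
})

test_that("mol2 charges are carried into the structure", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "m", "3 2 1", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "1 N  0.0 0.0 0.0 N.4 1 ALA1 -0.3",
    "2 CA 1.5 0.0 0.0 C.3 1 ALA1 0.1",
    "3 C  2.0 1.4 0.0 C.2 1 ALA1 0.2",
    "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 1"), path)
  s <- read_structure(path)
  expect_equal(s$charge, c(-0.3, 0.1, 0.2))
  expect_equal(s$element, c("N", "C", "C"))
})

test_that("write/read round trip preserves coordinates and atom order", {
  pep <- build_peptide(c("ALA", "ARG", "SER"))
  for (fmt in c("pdb", "mol2")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(pep, path)
    back <- read_structure(path)
    expect_equal(back$name, pep$name)
    expect_equal(seedgrow:::coords(back), seedgrow:::coords(pep),
                 tolerance = 2e-3)   # PDB precision: 3 decimals
  }
})

test_that("target preparation keeps the first protein chain only and is idempotent", {
  a <- build_peptide(c("ALA", "SER", "LYS"), chain = "A")
  b <- build_peptide(c("GLY", "THR"), chain = "B")
  b <- seedgrow:::set_coords(b, seedgrow:::coords(b) + 30)
  hoh <- data.frame(serial = 1L, name = "O", element = "O", resid = "HOH",
                    chain = "A", resno = 99L, x = 50, y = 50, z = 50,
                    charge = NA_real_, radius = NA_real_, eps = NA_real_,
                    is_h = FALSE)
  s <- seedgrow:::new_pepstruct(rbind(as.data.frame(a), as.data.frame(b),
                                      hoh))
  prep <- prepare_target(s)
  expect_setequal(unique(prep$chain), "A")
  expect_false("HOH" %in% prep$resid)
  expect_false(anyNA(prep$charge))
  expect_false(anyNA(prep$radius))
  # polar hydrogens present (backbone amide H on residues 2-3, SER HG, LYS HZ)
  expect_true("HN" %in% prep$name)
  expect_true("HG" %in% prep$name)
  expect_true(all(c("HZ1", "HZ2", "HZ3") %in% prep$name))
  # idempotent
  prep2 <- prepare_target(prep)
  expect_equal(as.data.frame(prep2), as.data.frame(prep), tolerance = 1e-12)
  # water-only input is a typed failure
  expect_error(prepare_target(seedgrow:::new_pepstruct(hoh)),
               class = "seedgrow_no_protein_error")
})

test_that("parameter assignment covers capped fragments and standard residues", {
  seq <- peptide_sequence("ARTKQTARKSTGGKA")
  frag <- enumerate_dipeptides(seq)[[1]]
  s <- build_fragment(frag)                      # AR, free N-terminus
  expect_false(anyNA(s$charge))
  expect_false(anyNA(s$radius))
  expect_true(all(s$radius > 0))
  expect_true(all(s$eps >= 0))
  expect_equal(sum(s$charge), 1, tolerance = 0.01)   # Arg carries the +1
  # neutral capped dipeptide sums to ~0
  sq <- build_fragment(enumerate_dipeptides(peptide_sequence("ASTG"),
                                            2)[[2]])   # ST, double-capped
  expect_equal(sum(sq$charge), 0, tolerance = 0.01)
  # backbone carbonyl O parameters come from the shipped oxygen row
  o <- s[s$name == "O", ][1, ]
  expect_equal(o$radius, 1.60)
  expect_equal(o$eps, 0.20)
  # unknown residues are typed errors
  bad <- s
  bad$resid[1] <- "XXX"
  bad$charge <- NA_real_
  expect_error(assign_parameters(bad), class = "seedgrow_typing_error")
})

test_that("mol2 input charges take precedence over the template", {
  pep <- assign_parameters(build_peptide(c("ALA", "ALA")))
  pep$charge <- seq_len(nrow(pep)) / 100   # marker charges
  path <- withr::local_tempfile(fileext = ".mol2")
  write_structure(pep, path)
  back <- assign_parameters(read_structure(path))
  expect_equal(back$charge, pep$charge, tolerance = 1e-6)
})
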