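test_that("a hand-written PDB file parses to exact atom records", {
  p <- write_three_atom_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_s3_class(s, "ribs_structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$resno, c(41L, 127L, 911L))
  expect_equal(s$atoms$chain, rep("A", 3))
  expect_equal(s$atoms$x, c(10.0, 11.5, -5.25), tolerance = 1e-3)
  expect_equal(s$atoms$y, c(20.0, 21.5, 0.125), tolerance = 1e-3)
  expect_equal(s$atoms$z, c(30.0, 31.5, 7.375), tolerance = 1e-3)
})

test_that("reading a missing or undetectable file errors", {
  expect_error(read_structure("does-not-exist.pdb"), "not found")
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", p)
  expect_error(read_structure(p), "format")
})

test_that("an equivalent mmCIF file parses to the same atoms as PDB", {
  pdb <- write_three_atom_pdb(withr::local_tempfile(fileext = ".pdb"))
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_TEST", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- c(
    "ATOM 1 P P . G A 1 41 ? 10.000 20.000 30.000 1.00 10.00 ? 41 G A P 1",
    "ATOM 2 P P . C A 1 127 ? 11.500 21.500 31.500 1.00 10.00 ? 127 C A P 1",
    "ATOM 3 P P . U A 1 911 ? -5.250 0.125 7.375 1.00 10.00 ? 911 U A P 1")
  writeLines(c(hdr, rows), cif)
  a <- read_structure(pdb)$atoms
  b <- read_structure(cif)$atoms
  expect_equal(b[, c("chain", "resno", "elety")], a[, c("chain", "resno", "elety")])
  expect_equal(atom_coords(b), atom_coords(a), tolerance = 1e-6)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P  A  C A 127      11.500  21.500  31.500  0.60 10.00           P",
    "ATOM      2  P  B  C A 127      99.000  99.000  99.000  0.40 10.00           P",
    "ATOM      3  P     G A  41      10.000  20.000  30.000  1.00 10.00           P",
    "END"), p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 2)
  kept <- s$atoms[s$atoms$resno == 127, ]
  expect_equal(kept$alt, "A")
  expect_equal(kept$x, 11.5)
})

test_that("altloc occupancy ties break to the lexicographically first id", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P  B  C A 127      99.000  99.000  99.000  0.50 10.00           P",
    "ATOM      2  P  A  C A 127      11.500  21.500  31.500  0.50 10.00           P",
    "ATOM      3  P     G A  41      10.000  20.000  30.000  1.00 10.00           P",
    "END"), p)
  s <- read_structure(p)
  expect_equal(s$atoms$alt[s$atoms$resno == 127], "A")
})

test_that("write/read round-trip preserves keys exactly and positions at PDB precision", {
  gen <- generate_pseudo_ribosome(synthetic_truth(phi = 4, theta = 2, psi = 6,
                                                  seed = 11))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(gen$model, p)
  back <- read_structure(p)
  expect_equal(nrow(back$atoms), nrow(gen$model$atoms))
  key <- function(a) paste(a$chain, a$resno, a$insert, a$elety)
  expect_identical(key(back$atoms), key(gen$model$atoms))
  expect_lt(max(abs(atom_coords(back$atoms) - atom_coords(gen$model$atoms))),
            1e-3 + 1e-12)
})

test_that("write_structure rejects unrepresentable structures", {
  s <- read_structure(write_three_atom_pdb(withr::local_tempfile(fileext = ".pdb")))
  empty <- s
  empty$atoms <- s$atoms[0, ]
  out <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(empty, out), "empty")
  expect_false(file.exists(out))
  big <- s
  big$atoms$resno[1] <- 10000L
  expect_error(write_structure(big, out), "residue numbers")
  wide <- s
  wide$atoms$chain[1] <- "AB"
  expect_error(write_structure(wide, out), "chain ids")
})

test_that("written coordinates follow the fixed three-decimal rounding rule", {
  s <- read_structure(write_three_atom_pdb(withr::local_tempfile(fileext = ".pdb")))
  s$atoms <- s$atoms[1, ]
  s$atoms$x <- 1.2345; s$atoms$y <- 0; s$atoms$z <- 0
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, p)
  line <- grep("^ATOM", readLines(p), value = TRUE)[1]
  field <- trimws(substr(line, 31, 38))
  expect_true(field %in% c("1.234", "1.235"))
  expect_identical(field, trimws(sprintf("%8.3f", 1.2345)))
})

test_that("select_atoms counts residue-range P atoms and orders results", {
  n <- 1500L
  at <- data.frame(model = 1L, chain = "B", resno = n:1, insert = "",
                   resid = "G", elety = "P", elesy = "P",
                   x = rnorm(n), y = rnorm(n), z = rnorm(n), o = 1, alt = "",
                   stringsAsFactors = FALSE)
  s <- headswivel:::new_structure("X", at, "pdb")
  got <- select_atoms(s, selection("B", list(c(930, 1380)), "P"))
  expect_equal(nrow(got), 451)       # 1380 - 930 + 1
  expect_false(is.unsorted(got$resno))
  # residue 1000 without a P atom drops from the count
  s2 <- s
  s2$atoms <- s2$atoms[s2$atoms$resno != 1000, ]
  expect_equal(nrow(select_atoms(s2, selection("B", list(c(930, 1380)), "P"))),
               450)
})

test_that("selecting an absent chain warns and returns an empty list", {
  s <- read_structure(write_three_atom_pdb(withr::local_tempfile(fileext = ".pdb")))
  expect_warning(got <- select_atoms(s, selection("Z", list(c(1, 999)), "P")),
                 "no atoms")
  expect_equal(nrow(got), 0)
})

test_that("select_atoms agrees with a brute-force filter on random selections", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 5))
  s <- gen$classical
  withr::local_seed(99)
  for (i in 1:100) {
    ch <- sample(c("A", "B", "Z"), 1)
    lo <- sample(1:1300, 1)
    hi <- lo + sample(0:300, 1)
    sel <- selection(ch, list(c(lo, hi)), "P")
    got <- suppressWarnings(select_atoms(s, sel))
    brute <- sum(s$atoms$chain == ch & s$atoms$resno >= lo &
                 s$atoms$resno <= hi & s$atoms$elety == "P")
    expect_equal(nrow(got), brute)
  }
})

test_that("pair_atoms aligns intersections, warns on loss, errors when sparse", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 8, n_head = 100))
  a <- select_atoms(gen$classical, selection("B", list(c(930, 1380)), "P"))
  b <- a
  pr <- pair_atoms(a, b, min_pairs = 50)
  expect_equal(nrow(pr$a), 100)
  expect_identical(pr$a$resno, pr$b$resno)
  # one residue missing from b
  b1 <- b[-7, ]
  expect_warning(pr <- pair_atoms(a, b1, min_pairs = 50), "99")
  expect_equal(nrow(pr$a), 99)
  expect_identical(pr$a$resno, pr$b$resno)
  # disjoint ranges
  c1 <- a; c1$resno <- c1$resno + 5000L
  expect_error(pair_atoms(a, c1, min_pairs = 1), "0 atom pairs")
})

test_that("pair_atoms is symmetric in its inputs", {
  gen <- generate_pseudo_ribosome(synthetic_truth(seed = 8, n_head = 100))
  a <- select_atoms(gen$classical, selection("B", list(c(930, 1380)), "P"))
  b <- select_atoms(gen$swiveled, selection("B", list(c(930, 1300)), "P"))
  p1 <- suppressWarnings(pair_atoms(a, b, min_pairs = 10))
  p2 <- suppressWarnings(pair_atoms(b, a, min_pairs = 10))
  expect_identical(p1$a, p2$b)
  expect_identical(p1$b, p2$a)
})

test_that("domain definitions enforce marker and core containment", {
  expect_error(domain_definition("head", "16S", list(c(930, 1380)),
                                 markers = c(984, 940, 2000)),
               "marker")
  expect_error(domain_definition("head", "16S", list(c(930, 1380)),
                                 markers = c(984, 940, 1106),
                                 core = c(935, 10)),
               "core")
  d <- domain_definition("head", "16S", list(c(930, 1380)),
                         markers = c(984, 940, 1106),
                         chain_map = c(`6NWY` = "a", default = "B"))
  expect_equal(chain_for(d, "6NWY"), "a")
  expect_equal(chain_for(d, "OTHER"), "B")
  expect_equal(chain_for(d, "OTHER", override = "Q"), "Q")
})
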