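test_that("loop-location parsing handles hairpins, internal loops and odd chains", {
  loc <- parse_loop_location("1U9S_A:136-139_161-162")
  expect_equal(loc$pdb_id, "1U9S")
  expect_equal(loc$chain, "A")
  expect_equal(loc$segments$start, c(136L, 161L))
  expect_equal(loc$segments$end, c(139L, 162L))

  loc2 <- parse_loop_location("1S72_0:1971-1974_2008-2010")
  expect_equal(loc2$chain, "0")
  expect_equal(nrow(loc2$segments), 2L)

  hp <- parse_loop_location("XXXX_A:10-15")
  expect_equal(nrow(hp$segments), 1L)
  expect_equal(loop_location_length(hp), 6L)
})

test_that("malformed locations fail naming the offending token", {
  expect_error(parse_loop_location("1U9S:136-139"), "malformed")
  expect_error(parse_loop_location("1U9S_A:139-136"), "139-136")
  expect_error(parse_loop_location("1U9S_A:13x-139"), "13x")
  expect_error(parse_loop_location("1U9S_A:136"), "136")
})

test_that("parse/format round-trips on generated well-formed strings", {
  set.seed(7)
  for (r in 1:25) {
    nseg <- sample(1:3, 1)
    starts <- sort(sample(1:500, nseg))
    lens <- sample(0:8, nseg, replace = TRUE)
    segs <- paste0(starts, "-", starts + lens, collapse = "_")
    txt <- paste0("1ABC_", sample(c("A", "B", "0", "9"), 1), ":", segs)
    expect_identical(format_loop_location(parse_loop_location(txt)), txt)
  }
  # insertion codes are carried opaquely
  withins <- "2XYZ_A:10^A-15_20-25^B"
  expect_identical(format_loop_location(parse_loop_location(withins)), withins)
})

test_that("loop files round-trip every field", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tmp)
  expect_length(read_loop_file(tmp), 0L)

  hp <- toy_loop(rand_centers(4), bases = c("G", "A", "A", "G"),
                 bp = data.frame(i = 1L, j = 4L, lw = "cWW"),
                 loc = "XXXX_A:10-13")
  write_loop_file(list(hp), tmp)
  back <- read_loop_file(tmp)
  expect_length(back, 1L)
  expect_equal(nrow(back[[1]]$base_pairs), 1L)
  expect_equal(back[[1]]$base_pairs$lw, "cWW")

  ds <- generate_dataset(builtin_templates()[c("SR", "GL")], 5L,
                         noise_spec(), seed = 3L)
  write_loop_file(ds$loops, tmp)
  back <- read_loop_file(tmp)
  # serialized forms are field-identical (coordinates live in the
  # coordinate file, not the loop file)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_loop_file(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  for (k in seq_along(back)) {
    expect_identical(loop_id(back[[k]]), loop_id(ds$loops[[k]]))
    expect_identical(back[[k]]$family, ds$loops[[k]]$family)
    expect_identical(loop_sequences(back[[k]]), loop_sequences(ds$loops[[k]]))
    expect_equal(sort(paste(back[[k]]$base_pairs$i, back[[k]]$base_pairs$j,
                            back[[k]]$base_pairs$lw)),
                 sort(paste(ds$loops[[k]]$base_pairs$i, ds$loops[[k]]$base_pairs$j,
                            ds$loops[[k]]$base_pairs$lw)))
  }
})

test_that("unknown annotation tokens are rejected with context", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">XXXX_A:1-3", "SEQ\tGAG", "BP\t0\t2\tcXW"), tmp)
  expect_error(read_loop_file(tmp), "cXW")
  writeLines(c(">XXXX_A:1-3", "SEQ\tGAG", "STK\t0\t1\tsideways"), tmp)
  expect_error(read_loop_file(tmp), "sideways")
})

test_that("attach_coordinates fills atoms from a flat table and flags misses", {
  lp <- toy_loop(rand_centers(6), loc = "XXXX_A:1-6", full = TRUE)
  coords <- loops_to_coordinates(list(lp))
  expect_equal(nrow(coords), 36L)  # 6 nt x 6 atoms

  lf <- withr::local_tempfile(fileext = ".tsv")
  write_loop_file(list(lp), lf)
  bare <- read_loop_file(lf)[[1]]
  got <- attach_coordinates(list(bare), coords)
  expect_equal(nrow(attr(got, "missing")), 0L)
  expect_true(all(vapply(got[[1]]$nucleotides,
                         function(nt) nrow(nt$coords) == 6L, logical(1))))

  # partial backbone: drop the P atom of nucleotide 2 -> 5 atoms, still usable
  partial <- coords[!(coords$nt_index == 1L & coords$atom_name == "P"), ]
  got <- attach_coordinates(list(bare), partial)
  expect_equal(nrow(got[[1]]$nucleotides[[2]]$coords), 5L)
  expect_length(nucleotide_center(got[[1]]$nucleotides[[2]]), 3L)

  # residue absent entirely -> flagged, not fatal; encoder then rejects
  absent <- coords[coords$nt_index != 3L, ]
  got <- attach_coordinates(list(bare), absent)
  expect_equal(attr(got, "missing")$nt_index, 3L)
  expect_error(encode_loop(got[[1]]), "no backbone atoms")
})

test_that("attach_coordinates reads PDB-format structures and checks chains", {
  skip_if_not_installed("bio3d")
  # minimal hand-written PDB: chain A residues 1-2, three backbone atoms each
  pdb_lines <- c(
    "ATOM      1  P     G A   1       1.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C4'   G A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O3'   G A   1       3.000   0.000   0.000  1.00  0.00           O",
    "ATOM      4  P     A A   2       1.000   4.000   0.000  1.00  0.00           P",
    "ATOM      5  C4'   A A   2       2.000   4.000   0.000  1.00  0.00           C",
    "ATOM      6  O3'   A A   2       3.000   4.000   0.000  1.00  0.00           O",
    "END")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, tmp)
  lp <- rna_loop("XXXX_A:1-2", list(nucleotide(1, "G"), nucleotide(2, "A")))
  got <- attach_coordinates(list(lp), tmp)
  expect_equal(unname(nucleotide_center(got[[1]]$nucleotides[[1]])), c(2, 0, 0))
  expect_equal(unname(nucleotide_center(got[[1]]$nucleotides[[2]])), c(2, 4, 0))
  lpB <- rna_loop("XXXX_B:1-2", list(nucleotide(1, "G"), nucleotide(2, "A")))
  expect_error(attach_coordinates(list(lpB), tmp), "chain")
})

test_that("nucleotide list order follows segment order with ascending residues", {
  ds <- generate_dataset(builtin_templates()["KT"], 3L, noise_spec(), seed = 2L)
  for (lp in ds$loops) {
    seg <- lp$location$segments
    res <- vapply(lp$nucleotides, `[[`, integer(1), "residue_number")
    expected <- unlist(lapply(seq_len(nrow(seg)),
                              function(k) seq.int(seg$start[k], seg$end[k])))
    expect_identical(res, as.integer(expected))
  }
})
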