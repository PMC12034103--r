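test_that("nucleotide centers are backbone-atom means", {
  nt1 <- nucleotide(1, "A", coords = matrix(c(1, 2, 3), 1, 3,
                                            dimnames = list("P", NULL)))
  expect_equal(unname(nucleotide_center(nt1)), c(1, 2, 3))
  nt2 <- nucleotide(2, "G", coords = matrix(c(0, 0, 0, 2, 0, 0), 2, 3,
                                            byrow = TRUE,
                                            dimnames = list(c("P", "C4'"), NULL)))
  expect_equal(unname(nucleotide_center(nt2)), c(1, 0, 0))
  # full six-atom set against a hand sum
  set.seed(4)
  xyz <- matrix(rnorm(18), 6, 3, dimnames = list(BACKBONE_ATOMS, NULL))
  nt3 <- nucleotide(3, "C", coords = xyz)
  expect_equal(nucleotide_center(nt3), colSums(xyz) / 6)
  expect_error(nucleotide_center(nucleotide(4, "U")), "4")
})

test_that("kabsch_rmsd is zero under rigid motion and matches a rotation-search oracle", {
  P <- rand_centers(6, seed = 9)
  expect_equal(kabsch_rmsd(P, P), 0)
  expect_lt(kabsch_rmsd(P, rigid_transform(P)), 1e-8)
  for (seed in 1:3) {
    A <- rand_centers(6, seed = seed)
    B <- rand_centers(6, seed = seed + 100)
    expect_equal(kabsch_rmsd(A, B), rmsd_rotation_search(A, B), tolerance = 1e-3)
  }
  expect_error(kabsch_rmsd(P, P[1:3, ]), "equal k")
})

test_that("pairwise distances agree with a per-pair oracle in both modes", {
  lp <- toy_loop(matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE))
  D <- pairwise_distances(lp)
  expect_equal(D[1, 2], 5)
  lp4 <- toy_loop(rand_centers(4, seed = 3), full = TRUE)
  for (mode in c("center_euclidean", "kabsch_backbone")) {
    D <- pairwise_distances(lp4, mode)
    expect_equal(unname(diag(D)), rep(0, 4))
    expect_equal(D, t(D), ignore_attr = TRUE)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      expected <- if (mode == "center_euclidean") {
        sqrt(sum((nucleotide_center(lp4$nucleotides[[i]]) -
                  nucleotide_center(lp4$nucleotides[[j]]))^2))
      } else {
        kabsch_rmsd(lp4$nucleotides[[i]]$coords, lp4$nucleotides[[j]]$coords)
      }
      expect_equal(D[i, j], expected)
    }
  }
})

test_that("encoding yields the complete directed graph with 23-element edges", {
  lp <- toy_loop(rand_centers(6, seed = 5),
                 bp = data.frame(i = 1L, j = 6L, lw = "cWW"))
  g <- encode_loop(lp)
  expect_equal(nrow(g$edges), 6 * 5)
  expect_equal(ncol(g$edge_features), 23L)
  expect_equal(length(LW_CLASSES), 18L)
  # distance channel symmetric and matches the adjacency matrix
  for (r in seq_len(nrow(g$edges))) {
    u <- g$edges[r, 1]; v <- g$edges[r, 2]
    expect_equal(unname(g$edge_features[r, 1]), unname(g$adjacency[u, v]))
  }
  # zero-annotation loop: bits all zero, distances set
  g0 <- encode_loop(toy_loop(rand_centers(3)))
  expect_equal(sum(g0$edge_features[, -1]), 0)
  expect_true(all(g0$edge_features[, 1] > 0))
})

test_that("pair and stacking bits are directional with transposed reverse edges", {
  lp <- toy_loop(rand_centers(4, seed = 2),
                 bp = data.frame(i = 1L, j = 2L, lw = "tHS"),
                 stk = data.frame(i = 2L, j = 3L, direction = "upward"))
  g <- encode_loop(lp)
  erow <- function(u, v) which(g$edges[, 1] == u & g$edges[, 2] == v)
  expect_equal(unname(g$edge_features[erow(1, 2), 1 + match("tHS", LW_CLASSES)]), 1)
  expect_equal(unname(g$edge_features[erow(2, 1), 1 + match("tSH", LW_CLASSES)]), 1)
  expect_equal(unname(g$edge_features[erow(2, 3), 19 + match("upward", STACK_CLASSES)]), 1)
  expect_equal(unname(g$edge_features[erow(3, 2), 19 + match("downward", STACK_CLASSES)]), 1)
  # at most one pair bit and one stacking bit per edge; encoding is
  # invariant to annotation order
  expect_true(all(rowSums(g$edge_features[, 2:19]) <= 1))
  expect_true(all(rowSums(g$edge_features[, 20:23]) <= 1))
  lp2 <- lp; lp2$base_pairs <- lp$base_pairs[rev(seq_len(nrow(lp$base_pairs))), ]
  expect_equal(encode_loop(lp2)$edge_features, g$edge_features)
})

test_that("LW and stacking reversal tables are involutions", {
  expect_identical(lw_transpose(lw_transpose(LW_CLASSES)), LW_CLASSES)
  expect_identical(stack_transpose(stack_transpose(STACK_CLASSES)), STACK_CLASSES)
  expect_identical(lw_transpose("cWH"), "cHW")
  expect_identical(stack_transpose(c("inward", "outward")), c("inward", "outward"))
})

test_that("node one-hots sum to 1 for standard bases and 0 for others", {
  lp <- toy_loop(rand_centers(5), bases = c("A", "C", "G", "U", "X"))
  g <- encode_loop(lp)
  expect_equal(unname(rowSums(g$node_features)), c(1, 1, 1, 1, 0))
  expect_equal(unname(g$node_features[3, ]), c(0, 0, 1, 0))
})

test_that("graph JSON-lines serialization round-trips", {
  ds <- generate_dataset(builtin_templates()[c("TS", "GL")], 3L,
                         noise_spec(), seed = 5L)
  graphs <- lapply(ds$loops, encode_loop)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_graphs_jsonl(graphs, tmp)
  back <- read_graphs_jsonl(tmp)
  expect_length(back, length(graphs))
  for (k in seq_along(graphs)) {
    expect_identical(back[[k]]$loop_id, graphs[[k]]$loop_id)
    expect_identical(back[[k]]$label, graphs[[k]]$label)
    expect_equal(back[[k]]$node_features, graphs[[k]]$node_features)
    expect_equal(back[[k]]$edge_features, graphs[[k]]$edge_features,
                 ignore_attr = TRUE)
    expect_equal(back[[k]]$adjacency, graphs[[k]]$adjacency, ignore_attr = TRUE)
  }
})

test_that("out-of-range annotation indices are rejected", {
  expect_error(rna_loop("XXXX_A:1-3",
                        list(nucleotide(1, "A"), nucleotide(2, "C"),
                             nucleotide(3, "G")),
                        base_pairs = data.frame(i = 1L, j = 9L, lw = "cWW")),
               "out of range")
})
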