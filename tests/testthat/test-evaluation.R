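mk_assign <- function(subs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("L", seq_along(subs))
  data.frame(loop_id = ids, cluster = 1L, subcluster = subs,
             stringsAsFactors = FALSE)
}

test_that("majority mapping applies the strict >60% rule over labelled members", {
  truth <- setNames(c("SR", "SR", "SR", "KT", "KT"), paste0("L", 1:5))
  pure <- mk_assign(rep("1.1", 3), paste0("L", 1:3))
  fa <- map_clusters_to_labels(pure, truth)
  expect_equal(fa$mapping$family, "SR")
  expect_equal(fa$mapping$majority_fraction, 1)
  # 3:2 split gives fraction 0.6, which is NOT > 0.6
  fa2 <- map_clusters_to_labels(mk_assign(rep("1.1", 5)), truth)
  expect_equal(fa2$mapping$family, "unassigned")
  # 4:1 passes
  truth2 <- setNames(c(rep("SR", 4), "KT"), paste0("L", 1:5))
  fa3 <- map_clusters_to_labels(mk_assign(rep("1.1", 5)), truth2)
  expect_equal(fa3$mapping$family, "SR")
  # exclusions are honored: dropping the KT member makes it pure
  fa4 <- map_clusters_to_labels(mk_assign(rep("1.1", 5)), truth,
                                exclude = paste0("L", 4:5))
  expect_equal(fa4$mapping$family, "SR")
})

test_that("Hungarian mapping equals exhaustive assignment search", {
  # 4 subclusters x 3 families with a deliberately tricky count matrix
  counts <- matrix(c(5, 4, 0,
                     4, 5, 0,
                     0, 3, 3,
                     1, 0, 4), 4, 3, byrow = TRUE)
  best <- -Inf; best_perm <- NULL
  rows <- 1:4
  for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))) {
    # assign family p[k] to subcluster k for every 3-subset of rows
    for (drop in rows) {
      sel <- setdiff(rows, drop)
      tot <- sum(counts[cbind(sel, p)])
      if (tot > best) { best <- tot; best_perm <- list(sel = sel, p = p) }
    }
  }
  sol <- rnaloopclust:::hungarian_max(counts)
  got <- sum(counts[cbind(which(!is.na(sol)), sol[!is.na(sol)])])
  expect_equal(got, best)

  # end-to-end: hungarian mode maps one-to-one
  truth <- setNames(rep(c("A", "B", "C"), times = c(9, 12, 7)), paste0("L", 1:28))
  subs <- rep(c("1.1", "1.2", "2.1", "2.2"), times = c(9, 9, 6, 4))
  fa <- map_clusters_to_labels(mk_assign(subs, paste0("L", 1:28)), truth,
                               mode = "hungarian")
  assigned <- fa$mapping$family[fa$mapping$family != "unassigned"]
  expect_equal(anyDuplicated(assigned), 0L)
})

test_that("classification report matches closed forms on a hand confusion", {
  # binary case: TP=8, FN=2, FP=1, TN=9 for class 'pos'
  truth <- setNames(c(rep("pos", 10), rep("neg", 10)), paste0("L", 1:20))
  subs <- c(rep("1.1", 8), rep("2.1", 2),   # 8 pos right, 2 pos as neg
            rep("1.1", 1), rep("2.1", 9))   # 1 neg as pos, 9 neg right
  assign <- mk_assign(subs, paste0("L", 1:20))
  fa <- structure(list(mapping = data.frame(subcluster = c("1.1", "2.1"),
                                            family = c("pos", "neg"),
                                            majority_fraction = c(8/9, 9/11),
                                            n_labelled = c(9L, 11L)),
                       threshold = 0.6, mode = "majority"),
                  class = "family_assignment")
  rep <- classification_report(assign, truth, fa)
  pos <- rep$per_family[rep$per_family$family == "pos", ]
  expect_equal(pos$precision, 8 / 9)
  expect_equal(pos$recall, 0.8)
  expect_equal(pos$f1, 2 * (8/9) * 0.8 / (8/9 + 0.8))
  expect_equal(rep$accuracy, 17 / 20)
  expect_equal(sum(diag(rep$confusion[c("pos", "neg"), c("pos", "neg")])) / 20,
               rep$accuracy)
  # perfect mapping: everything 1
  perfect <- classification_report(mk_assign(c("1.1", "1.1", "2.1"),
                                             paste0("L", 1:3)),
                                   setNames(c("A", "A", "B"), paste0("L", 1:3)))
  expect_equal(unname(perfect$weighted), c(1, 1, 1))
  expect_equal(perfect$accuracy, 1)
})

test_that("unassigned subclusters count against their true classes", {
  truth <- setNames(c(rep("A", 3), rep("B", 3)), paste0("L", 1:6))
  subs <- c(rep("1.1", 3), rep("9.9", 3))
  fa <- map_clusters_to_labels(mk_assign(subs, names(truth)), truth)
  # subcluster 9.9 is pure B so it maps; force it unassigned to test
  fa$mapping$family[fa$mapping$subcluster == "9.9"] <- "unassigned"
  rep <- classification_report(mk_assign(subs, names(truth)), truth, fa)
  expect_equal(rep$accuracy, 0.5)
  b <- rep$per_family[rep$per_family$family == "B", ]
  expect_equal(b$recall, 0)
  expect_true(b$flagged)
})

test_that("MCA is the fraction of known motifs landing in their family's subclusters", {
  # 290 known motifs of one family, 286 in family-assigned subclusters
  ids <- paste0("G", 1:290)
  truth <- setNames(rep("GL", 290), ids)
  subs <- c(rep("1.1", 286), rep("7.7", 4))
  assign <- mk_assign(subs, ids)
  fa <- structure(list(mapping = data.frame(subcluster = c("1.1", "7.7"),
                                            family = c("GL", "unassigned"),
                                            majority_fraction = c(1, 1),
                                            n_labelled = c(286L, 4L)),
                       threshold = 0.6, mode = "majority"),
                  class = "family_assignment")
  expect_equal(mca("GL", fa, assign, truth), 286 / 290)
  expect_equal(round(100 * mca("GL", fa, assign, truth), 2), 98.62)
  # all in -> 1; none in -> 0; unknown family errors
  fa$mapping$family <- c("GL", "GL")
  expect_equal(mca("GL", fa, assign, truth), 1)
  fa$mapping$family <- c("unassigned", "unassigned")
  expect_equal(mca("GL", fa, assign, truth), 0)
  expect_error(mca("ZZ", fa, assign, truth), "ZZ")
})

test_that("two-SD bounds and purity behave per definition", {
  expect_equal(two_sd_upper(c(1, 1, 1)), 1)
  v <- c(0.5, 1.0, 2.5, 3.1)
  expect_equal(two_sd_upper(v), mean(v) + 2 * sd(v))
  # all-identical members -> avg RMSD 0 -> fraction 1
  lp <- toy_loop(rand_centers(5, seed = 13))
  subs <- list(s1 = list(lp, lp), s2 = list(lp, lp, lp),
               lone = list(lp))  # singleton excluded
  pa <- purity_analysis(subs, threshold = 0.5)
  expect_equal(pa$fraction, 1)
  expect_equal(nrow(pa$per_subcluster), 2L)
  # purity is monotone in the threshold
  far <- toy_loop(rand_centers(5, seed = 14) * 3)
  subs2 <- list(a = list(lp, far), b = list(lp, lp))
  f_small <- purity_analysis(subs2, threshold = 1e-6)$fraction
  f_big <- purity_analysis(subs2, threshold = 1e6)$fraction
  expect_lte(f_small, f_big)
  expect_error(purity_analysis(list(x = list(lp)), 1), "multi-member")
})
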