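mk_summaries <- function(trip_list, meds) {
  do.call(rbind, lapply(seq_along(trip_list), function(i) {
    tr <- trip_list[[i]]
    data.frame(clade_quartet = paste(c(tr, "O"), collapse = ""),
               c1 = tr[1], c2 = tr[2], c3 = tr[3],
               m1 = meds[[i]][1], m2 = meds[[i]][2], m3 = meds[[i]][3],
               n_retained = 5L, n_total = 5L, empty = FALSE)
  }))
}

test_that("rooted tree enumeration counts follow the double factorial", {
  dd <- function(n) prod(seq(2 * n - 3, 1, by = -2))
  for (n in 2:7) {
    trees <- enumerate_rooted_clade_trees(LETTERS[1:n])
    expect_equal(length(trees), dd(n))
    expect_false(anyDuplicated(names(trees)) > 0)
    # every tree carries exactly the requested leaves
    expect_true(all(vapply(trees, function(t)
      setequal(quartetpol:::tree_leaves(t), LETTERS[1:n]), logical(1))))
  }
  expect_equal(length(enumerate_rooted_clade_trees(c("A", "B"))), 1L)
  expect_equal(length(enumerate_rooted_clade_trees(c("A", "B", "C"))), 3L)
  expect_equal(length(enumerate_rooted_clade_trees(LETTERS[1:5])), 105L)
  expect_error(enumerate_rooted_clade_trees(LETTERS[1:9]), "2 to 8")
})

test_that("induced triplet topologies follow the tree structure", {
  t1 <- "(S,(T,(E,(K,R))))"
  # {E,K,R}: K and R are grouped
  expect_equal(induced_quartet_topology(t1, c("E", "K", "R")), "x3")
  # {E,K,T}: E and K are grouped against T
  expect_equal(induced_quartet_topology(t1, c("E", "K", "T")), "x1")
  # {S,T,E}: T,E group against S
  expect_equal(induced_quartet_topology(t1, c("E", "S", "T")), "x2")
  # cherry plus outlier always returns the cherry
  t2 <- "((A,B),C)"
  expect_equal(induced_quartet_topology(t2, c("A", "B", "C")), "x1")
  expect_error(induced_quartet_topology(t2, c("A", "B", "Z")), "Z")
})

test_that("total support sums induced-topology medians", {
  trips <- combn(c("E", "K", "R", "S", "T"), 3, simplify = FALSE)
  truth <- "(S,(T,(E,(K,R))))"
  meds <- lapply(trips, function(tr) {
    topo <- induced_quartet_topology(truth, tr)
    m <- c(0, 0, 0); m[match(topo, c("x1", "x2", "x3"))] <- 1
    m
  })
  summ <- mk_summaries(trips, meds)
  rk <- rank_trees(summ)
  expect_equal(rk$ranking$support[1L], 10)
  expect_equal(rk$best, quartetpol:::canonical_label(
    quartetpol:::parse_clade_newick(truth)))
  expect_equal(rk$ranking$dist_to_best[1L], 0)
  expect_equal(nrow(rk$ranking), 105L)

  # uniform summaries: all trees tie
  meds_u <- rep(list(rep(1 / 3, 3)), length(trips))
  rk_u <- rank_trees(mk_summaries(trips, meds_u))
  expect_equal(diff(range(rk_u$ranking$support)), 0)
  expect_true(all(rk_u$ranking$tie[-1L]))
})

test_that("two independent scorers agree on random summaries", {
  # independent scorer: restrict each candidate tree with ape and read the
  # cherry off the 3-leaf subtree
  ape_score <- function(newick, summ) {
    ph <- ape::read.tree(text = paste0(newick, ";"))
    tot <- 0
    for (i in seq_len(nrow(summ))) {
      trip <- c(summ$c1[i], summ$c2[i], summ$c3[i])
      sub <- ape::keep.tip(ph, trip)
      # the cherry is the pair whose MRCA is not the subtree root
      pairs <- list(trip[1:2], trip[c(1, 3)], trip[2:3])
      root <- length(sub$tip.label) + 1L
      k <- which(vapply(pairs, function(pr)
        ape::getMRCA(sub, pr) != root, logical(1)))
      tot <- tot + summ[[paste0("m", k)]][i]
    }
    tot
  }
  set.seed(19)
  trips <- combn(c("E", "K", "R", "S", "T"), 3, simplify = FALSE)
  for (rep in 1:3) {
    meds <- lapply(trips, function(tr) runif(3))
    summ <- mk_summaries(trips, meds)
    trees <- enumerate_rooted_clade_trees(c("E", "K", "R", "S", "T"))
    pick <- sample(seq_along(trees), 12)
    for (j in pick) {
      mine <- total_tree_support(trees[[j]], summ)
      ind <- ape_score(names(trees)[j], summ)
      expect_equal(mine, ind, tolerance = 1e-12)
    }
  }
})

test_that("scoring is invariant under consistent clade relabeling", {
  set.seed(23)
  labs <- c("E", "K", "R", "S", "T")
  perm <- setNames(sample(labs), labs)
  trips <- combn(labs, 3, simplify = FALSE)
  meds <- lapply(trips, function(tr) runif(3))
  summ <- mk_summaries(trips, meds)
  # permuted summaries: relabel clades and re-sort triplets canonically
  summ_p <- summ
  for (i in seq_len(nrow(summ_p))) {
    tr_new <- unname(perm[c(summ$c1[i], summ$c2[i], summ$c3[i])])
    ord <- order(tr_new)
    m <- c(summ$m1[i], summ$m2[i], summ$m3[i])
    # reorder topology supports to the sorted new labels: topology k
    # groups the pair excluding the k-th... map via pair identity
    pairs_old <- list(c(1, 2), c(1, 3), c(2, 3))
    sorted_new <- sort(tr_new)
    m_new <- numeric(3)
    for (k in 1:3) {
      pr <- sort(tr_new[pairs_old[[k]]])
      kk <- which(vapply(pairs_old, function(p)
        identical(sorted_new[p], pr), logical(1)))
      m_new[kk] <- m[k]
    }
    summ_p$c1[i] <- sorted_new[1]; summ_p$c2[i] <- sorted_new[2]
    summ_p$c3[i] <- sorted_new[3]
    summ_p$m1[i] <- m_new[1]; summ_p$m2[i] <- m_new[2]
    summ_p$m3[i] <- m_new[3]
  }
  rk <- rank_trees(summ)
  rk_p <- rank_trees(summ_p)
  relabel <- function(nw) {
    for (l in labs) nw <- gsub(l, tolower(perm[[l]]), nw)
    toupper(nw)
  }
  best_mapped <- quartetpol:::canonical_label(
    quartetpol:::parse_clade_newick(relabel(rk$best)))
  expect_equal(rk_p$best, best_mapped)
  expect_equal(sort(rk_p$ranking$support), sort(rk$ranking$support),
               tolerance = 1e-12)
})

test_that("aggregation uses medians without re-normalization", {
  sc <- data.frame(clade_quartet = "EKOR", clade_a = "E", clade_b = "K",
                   clade_c = "R",
                   s1 = c(0.8, 0.4, 0.45), s2 = c(0.1, 0.5, 0.1),
                   s3 = c(0.1, 0.1, 0.45), status = "retained")
  ag <- aggregate_clade_quartet(sc)
  expect_equal(ag$m1, 0.45)
  expect_equal(ag$m2, 0.1)
  expect_equal(ag$m3, 0.1)
  expect_false(abs(ag$m1 + ag$m2 + ag$m3 - 1) < 1e-12)

  single <- sc[1, ]
  ag1 <- aggregate_clade_quartet(single)
  expect_equal(c(ag1$m1, ag1$m2, ag1$m3), c(0.8, 0.1, 0.1))

  none <- sc; none$status <- "rejected_risk"
  expect_warning(ag0 <- aggregate_clade_quartet(none), "no retained")
  expect_true(ag0$empty)
})

test_that("empty clade-quartets drop out of rankings equivalently", {
  set.seed(31)
  trips <- combn(c("E", "K", "R", "S", "T"), 3, simplify = FALSE)
  meds <- lapply(trips, function(tr) runif(3))
  summ <- mk_summaries(trips, meds)
  summ2 <- summ
  summ2$empty[4L] <- TRUE
  rk_marked <- rank_trees(summ2)
  rk_dropped <- rank_trees(summ2[-4L, ])
  expect_equal(rk_marked$ranking, rk_dropped$ranking)
})

test_that("topology comparison reports shared and conflicting clades", {
  t1 <- "(S,(T,(E,(K,R))))"
  cmp_self <- compare_topologies(t1, t1)
  expect_true(cmp_self$same)
  expect_equal(length(cmp_self$only_t1), 0L)
  # nearest-neighbor swap: all but one internal clade shared
  t2 <- "(S,(T,(K,(E,R))))"
  cmp <- compare_topologies(t1, t2)
  expect_false(cmp$same)
  expect_equal(length(cmp$only_t1), 1L)
  expect_equal(length(cmp$only_t2), 1L)
  expect_error(compare_topologies(t1, "((A,B),C)"), "leaf sets")
})

test_that("external trees are scored within the exhaustive ranking", {
  set.seed(37)
  trips <- combn(c("E", "K", "R", "S", "T"), 3, simplify = FALSE)
  meds <- lapply(trips, function(tr) runif(3))
  summ <- mk_summaries(trips, meds)
  rk <- rank_trees(summ)
  ext <- score_external_tree("(O,(S,(T,(E,(K,R)))));", rk, summ,
                             outgroup = "O")
  expect_true(ext$rank >= 1 && ext$rank <= 105)
  expect_equal(ext$support,
               rk$ranking$support[rk$ranking$newick == ext$newick])
  expect_equal(ext$dist_to_best,
               rk$ranking$support[1L] - ext$support)
})
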