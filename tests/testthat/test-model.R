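random_model <- function() {
  bf <- runif(4, 0.1, 0.4); bf <- bf / sum(bf)
  subst_model(rates = c(runif(5, 0.2, 4), 1), bf = bf,
              shape = runif(1, 0.3, 2), pinv = runif(1, 0, 0.4))
}

random_blen <- function() {
  c(a = runif(1, 0.02, 0.5), b = runif(1, 0.02, 0.5),
    c = runif(1, 0.02, 0.5), o = runif(1, 0.05, 0.8),
    int = runif(1, 0, 0.2))
}

test_that("pattern probabilities form a proper distribution", {
  set.seed(101)
  for (i in 1:5) {
    m <- random_model(); bl <- random_blen()
    for (tp in c("x1", "x2", "x3")) {
      p <- quartet_pattern_probs(m, bl, tp)
      expect_equal(sum(p), 1, tolerance = 1e-8)
      expect_true(all(p >= 0))
    }
  }
})

test_that("pruning probabilities match hand-expanded state summation", {
  set.seed(7)
  m <- random_model(); bl <- random_blen()
  p <- quartet_pattern_probs(m, bl, "x2")
  tab <- quartetpol:::quartet_pattern_table()
  idx <- sample.int(256, 12)
  for (i in idx) {
    oracle <- oracle_pattern_prob(m, bl, "x2",
                                  c(tab$a[i], tab$b[i], tab$c[i], tab$o[i]))
    expect_equal(p[i], oracle, tolerance = 1e-10)
  }
})

test_that("the C++ kernel reproduces the R engine to machine precision", {
  set.seed(55)
  for (i in 1:3) {
    m <- random_model(); bl <- random_blen()
    for (tp in 1:3) {
      pR <- quartet_pattern_probs(m, bl, c("x1", "x2", "x3")[tp])
      pC <- quartetpol:::.quartet_pattern_probs_cpp(
        m$rates, m$bf, m$shape, m$pinv, 4L, bl, tp)
      expect_lt(max(abs(pR - as.numeric(pC))), 1e-12)
    }
  }
})

test_that("degenerate branch lengths behave as expected", {
  m <- subst_model(shape = 1, pinv = 0)
  bl0 <- c(a = 0, b = 0, c = 0, o = 0, int = 0)
  p <- quartet_pattern_probs(m, bl0, "x1")
  tab <- quartetpol:::quartet_pattern_table()
  expect_equal(sum(p[tab$class > 0]), 0)
  const <- tab$a == tab$b & tab$b == tab$c & tab$c == tab$o
  expect_equal(sum(p[const]), 1)

  # star tree, symmetric model: the three class probabilities coincide
  bl_star <- c(a = 0.3, b = 0.3, c = 0.3, o = 0.3, int = 0)
  ps <- quartet_pattern_probs(subst_model(), bl_star, "x1")
  cp <- vapply(1:3, function(k) sum(ps[tab$class == k]), numeric(1))
  expect_lt(max(cp) - min(cp), 1e-10)
})

test_that("class probabilities match Monte-Carlo pattern frequencies", {
  set.seed(13)
  tab <- quartetpol:::quartet_pattern_table()
  for (rep in 1:3) {
    m <- random_model(); bl <- random_blen()
    p <- quartet_pattern_probs(m, bl, "x1")
    cp <- vapply(1:3, function(k) sum(p[tab$class == k]), numeric(1))
    tr <- ape::read.tree(text = sprintf(
      "((a:%g,b:%g):%g,c:%g,o:%g);", bl["a"], bl["b"], bl["int"],
      bl["c"], bl["o"]))
    n <- 30000L
    cls <- quartetpol:::rate_classes(m)
    draw <- sample.int(length(cls$rate), n, TRUE, prob = cls$weight)
    sub <- matrix("A", 4, n, dimnames = list(c("a", "b", "c", "o"), NULL))
    for (k in unique(draw)) {
      idx <- which(draw == k)
      if (cls$rate[k] == 0) {
        st <- sample(c("A", "C", "G", "T"), length(idx), TRUE, prob = m$bf)
        sub[, idx] <- matrix(st, 4, length(idx), byrow = TRUE)
      } else {
        sim <- phangorn::simSeq(tr, l = length(idx), Q = m$rates, bf = m$bf,
                                rate = cls$rate[k], type = "DNA")
        ch <- toupper(as.character(sim))
        sub[rownames(ch), idx] <- ch
      }
    }
    pc <- count_polarized_patterns(sub)
    for (k in 1:3) {
      se <- sqrt(cp[k] * (1 - cp[k]) * n)
      expect_lt(abs(pc$Na[k] - n * cp[k]), 3 * se + 1e-9)
    }
  }
})

test_that("simulated parameters are recovered by the quartet fit", {
  set.seed(77)
  true <- subst_model(rates = c(2, 4, 0.8, 1.2, 3, 1),
                      bf = c(0.3, 0.2, 0.2, 0.3), shape = 0.6, pinv = 0.3)
  bl <- c(a = 0.15, b = 0.2, c = 0.1, o = 0.4, int = 0.08)
  tr <- ape::read.tree(text = sprintf(
    "((a:%g,b:%g):%g,c:%g,o:%g);", bl["a"], bl["b"], bl["int"],
    bl["c"], bl["o"]))
  cls <- quartetpol:::rate_classes(true)
  n <- 100000L
  draw <- sample.int(length(cls$rate), n, TRUE, prob = cls$weight)
  sub <- matrix("A", 4, n, dimnames = list(c("a", "b", "c", "o"), NULL))
  for (k in unique(draw)) {
    idx <- which(draw == k)
    if (cls$rate[k] == 0) {
      st <- sample(c("A", "C", "G", "T"), length(idx), TRUE, prob = true$bf)
      sub[, idx] <- matrix(st, 4, length(idx), byrow = TRUE)
    } else {
      sim <- phangorn::simSeq(tr, l = length(idx), Q = true$rates,
                              bf = true$bf, rate = cls$rate[k], type = "DNA")
      ch <- toupper(as.character(sim))
      sub[rownames(ch), idx] <- ch
    }
  }
  fit <- fit_gtr_gamma_i(sub, "x1", control = list(maxit = 400L,
                                                   factr = 1e7,
                                                   restarts = 2L))
  expect_gte(fit$logLik, fit$logLik0)
  expect_lt(abs(fit$model$shape - true$shape) / true$shape, 0.15)
  expect_lt(abs(fit$model$pinv - true$pinv) / true$pinv, 0.15)
  expect_lt(max(abs(fit$blen - bl)), 0.05)
})

test_that("Jukes-Cantor data yields near-equal rates and frequencies", {
  set.seed(9)
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,c:0.2,o:0.3);")
  sim <- phangorn::simSeq(tr, l = 50000L, type = "DNA")
  sub <- toupper(as.character(sim))[c("a", "b", "c", "o"), ]
  fit <- fit_gtr_gamma_i(sub, "x1", control = list(maxit = 300L,
                                                   factr = 1e8,
                                                   restarts = 1L))
  expect_lt(max(abs(fit$model$bf - 0.25)), 0.02)
  expect_lt(max(fit$model$rates) / min(fit$model$rates), 1.35)
})

test_that("all-constant subalignments are refused with guidance", {
  sub <- matrix("G", 4, 50, dimnames = list(c("a", "b", "c", "o"), NULL))
  expect_error(fit_gtr_gamma_i(sub, "x1"), "uninformative")
})

test_that("expected convergent counts behave qualitatively", {
  m <- subst_model(shape = 1, pinv = 0)
  mk_fit <- function(topology, bl)
    structure(list(topology = topology, model = m, blen = bl),
              class = "quartet_fit")
  # zero internal branches, long terminals: homoplasy expectation positive
  bl_lba <- c(a = 0.8, b = 0.2, c = 0.8, o = 0.6, int = 0)
  fits <- list(x1 = mk_fit("x1", bl_lba), x2 = mk_fit("x2", bl_lba),
               x3 = mk_fit("x3", bl_lba))
  nc <- expected_convergent_count(fits, "x1", n_usable = 1000L)
  expect_gt(nc, 0)
  # no substitutions at all: zero expectation for every topology
  bl0 <- c(a = 0, b = 0, c = 0, o = 0, int = 0)
  fits0 <- list(x1 = mk_fit("x1", bl0), x2 = mk_fit("x2", bl0),
                x3 = mk_fit("x3", bl0))
  for (x in c("x1", "x2", "x3"))
    expect_equal(expected_convergent_count(fits0, x, 1000L), 0)
  # missing rival fit errors
  expect_error(expected_convergent_count(fits[1:2], "x1", 100L), "x3")
  # max mode is never below mean mode
  expect_gte(expected_convergent_count(fits, "x2", 1000L, mode = "max"),
             expected_convergent_count(fits, "x2", 1000L, mode = "mean"))
})

test_that("convergent expectation shrinks with terminal branch lengths", {
  m <- subst_model(shape = 1, pinv = 0)
  grid <- c(0.8, 0.4, 0.2, 0.1, 0.05)
  nc <- vapply(grid, function(t) {
    bl <- c(a = t, b = t, c = t, o = t, int = 0.02)
    fits <- lapply(c("x1", "x2", "x3"), function(tp)
      structure(list(topology = tp, model = m, blen = bl),
                class = "quartet_fit"))
    names(fits) <- c("x1", "x2", "x3")
    expected_convergent_count(fits, "x1", 1000L)
  }, numeric(1))
  expect_true(all(diff(nc) < 0))
})
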