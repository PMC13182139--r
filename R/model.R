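#' Construct a GTR+Gamma+I substitution model
#'
#' General time-reversible model with discrete-gamma among-site rate
#' variation (4 categories by default, mean-of-category discretization, the
#' same scheme used by standard likelihood implementations) and a proportion
#' of invariable sites.  Rates follow the conventional order AC, AG, AT, CG,
#' CT, GT with GT fixed to 1.
#'
#' @param rates 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param bf 4 base frequencies (A, C, G, T), summing to 1.
#' @param shape gamma shape alpha (> 0).
#' @param pinv proportion of invariable sites in [0, 1).
#' @param k number of gamma categories.
#' @return object of class \code{"subst_model"}.
#' @export
subst_model <- function(rates = rep(1, 6), bf = rep(0.25, 4),
                        shape = 1, pinv = 0, k = 4L) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(bf) == 4L, abs(sum(bf) - 1) < 1e-9, all(bf > 0),
            shape > 0, pinv >= 0, pinv < 1, k >= 1L)
  structure(list(rates = rates / rates[6L], bf = bf, shape = shape,
                 pinv = pinv, k = as.integer(k)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR+G+I: rates", paste(signif(x$rates, 3), collapse = "/"),
      "| bf", paste(signif(x$bf, 3), collapse = "/"),
      sprintf("| alpha %.3g | pinv %.3g | %d categories\n",
              x$shape, x$pinv, x$k))
  invisible(x)
}

# Normalized GTR rate matrix: Q[i,j] = r_ij * pi_j, scaled so the expected
# substitution rate at stationarity is 1.
gtr_rate_matrix <- function(rates, bf) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- rates  # column-major lower tri is AC,AG,AT,CG,CT,GT
  Q <- Q + t(Q)
  Q <- Q * rep(bf, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * bf)
}

# Eigendecomposition of Q via the symmetrized form; returns components to
# build P(t) = B %*% diag(exp(lambda t)) %*% Binv cheaply for many t.
gtr_eigen <- function(Q, bf) {
  s <- sqrt(bf)
  S <- Q * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(lambda = e$values,
       B = e$vectors / s,          # rows scaled by 1/sqrt(bf)
       Binv = t(e$vectors * s))    # columns scaled by sqrt(bf)
}

# Transition probability matrix for branch length t (expected substitutions
# per site at relative rate 1).
gtr_pmat <- function(eig, t) {
  P <- eig$B %*% (exp(eig$lambda * t) * eig$Binv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Relative rates and weights of the gamma + invariant mixture.  Gamma
# category rates are rescaled by 1/(1 - pinv) so the overall mean rate is 1
# (the convention of phangorn and most ML programs).
rate_classes <- function(model) {
  if (model$pinv > 0) {
    g <- phangorn::discrete.gamma(model$shape, model$k) / (1 - model$pinv)
    list(rate = c(0, g),
         weight = c(model$pinv, rep((1 - model$pinv) / model$k, model$k)))
  } else {
    list(rate = phangorn::discrete.gamma(model$shape, model$k),
         weight = rep(1 / model$k, model$k))
  }
}

#' Exact site-pattern probabilities on a quartet tree
#'
#' Computes, by the pruning algorithm run over every one of the 256
#' nucleotide site patterns, the probability of each pattern on the unrooted
#' quartet tree in which ingroup taxa \code{pair} are sisters, under a
#' GTR+Gamma+I model.  Pattern order is the canonical encoding
#' \code{idx = a + 4(b-1) + 16(c-1) + 64(o-1)} over states A,C,G,T = 1..4
#' for taxa (a, b, c, o).
#'
#' @param model a \code{\link{subst_model}}.
#' @param blen named numeric of 5 branch lengths: \code{a}, \code{b},
#'   \code{c}, \code{o} (terminal) and \code{int} (internal), in expected
#'   substitutions per site.
#' @param topology \code{"x1"} (a,b sisters), \code{"x2"} (a,c) or
#'   \code{"x3"} (b,c).
#' @return numeric vector of length 256 summing to 1.
#' @export
quartet_pattern_probs <- function(model, blen, topology = "x1") {
  stopifnot(all(c("a", "b", "c", "o", "int") %in% names(blen)),
            all(blen >= 0))
  # permute taxa so the tree is always ((p1,p2),(p3,o)) with p1,p2 the pair
  perm <- switch(topology,
                 x1 = c("a", "b", "c"), x2 = c("a", "c", "b"),
                 x3 = c("b", "c", "a"), stop("unknown topology ", topology))
  Q <- gtr_rate_matrix(model$rates, model$bf)
  eig <- gtr_eigen(Q, model$bf)
  rc <- rate_classes(model)
  # state index of each taxon in each of the 256 patterns
  st <- list(a = rep_len(rep(1:4, each = 1), 256),
             b = rep_len(rep(1:4, each = 4), 256),
             c = rep_len(rep(1:4, each = 16), 256),
             o = rep(1:4, each = 64))
  s1 <- st[[perm[1L]]]; s2 <- st[[perm[2L]]]; s3 <- st[[perm[3L]]]; so <- st$o
  probs <- numeric(256)
  for (m in seq_along(rc$rate)) {
    r <- rc$rate[m]
    if (r == 0) {
      const <- s1 == s2 & s2 == s3 & s3 == so
      probs[const] <- probs[const] + rc$weight[m] * model$bf[s1[const]]
      next
    }
    P1 <- gtr_pmat(eig, r * blen[[perm[1L]]])
    P2 <- gtr_pmat(eig, r * blen[[perm[2L]]])
    P3 <- gtr_pmat(eig, r * blen[[perm[3L]]])
    Po <- gtr_pmat(eig, r * blen[["o"]])
    Pi <- gtr_pmat(eig, r * blen[["int"]])
    # L1[x, pat]: partial likelihood of the cherry node; L2[y, pat]: of the
    # node joining p3 and the outgroup.
    L1 <- P1[, s1, drop = FALSE] * P2[, s2, drop = FALSE]
    L2 <- P3[, s3, drop = FALSE] * Po[, so, drop = FALSE]
    probs <- probs + rc$weight[m] * colSums(model$bf * L1 * (Pi %*% L2))
  }
  probs
}

# Tabulate usable columns of a quartet subalignment into the 256-pattern
# count vector (canonical encoding, rows a,b,c,o).
pattern_counts_256 <- function(sub, usable = rep(TRUE, ncol(sub))) {
  u <- sub[, usable, drop = FALSE]
  code <- match(u, DNA_BASES)
  dim(code) <- dim(u)
  idx <- code[1L, ] + 4L * (code[2L, ] - 1L) + 16L * (code[3L, ] - 1L) +
    64L * (code[4L, ] - 1L)
  tabulate(idx, nbins = 256L)
}

quartet_loglik <- function(counts256, model, blen, topology) {
  p <- quartet_pattern_probs(model, blen, topology)
  obs <- counts256 > 0
  p <- pmax(p[obs], 1e-300)
  sum(counts256[obs] * log(p))
}

#' Fit GTR+Gamma+I to a quartet subalignment under a fixed topology
#'
#' Maximum-likelihood optimization of the 5 branch lengths, 5 free
#' exchangeabilities, 3 free base frequencies, gamma shape and invariable
#' proportion, starting from the conventional initial values (alpha = 1,
#' pinv = 0.3, empirical base frequencies, equal exchangeabilities, branch
#' lengths from observed pairwise differences).  Optimization is bounded
#' quasi-Newton (L-BFGS-B) on log/logit-transformed parameters with jittered
#' restarts on non-convergence.
#'
#' @param sub 4 x n character matrix (rows a, b, c, o) or a length-256
#'   pattern count vector.
#' @param topology \code{"x1"}, \code{"x2"} or \code{"x3"}.
#' @param usable logical column mask (matrix input only).
#' @param init optional \code{\link{subst_model}} giving starting values.
#' @param control list: \code{maxit} (default 200), \code{factr} (default
#'   1e9), \code{restarts} on non-convergence (default 2).
#' @return object of class \code{"quartet_fit"}: \code{topology},
#'   \code{model}, \code{blen}, \code{logLik}, \code{n_usable},
#'   \code{convergence}.
#' @export
fit_gtr_gamma_i <- function(sub, topology = "x1",
                            usable = if (is.matrix(sub)) rep(TRUE, ncol(sub)),
                            init = NULL, control = list()) {
  counts <- if (is.matrix(sub)) pattern_counts_256(sub, usable) else sub
  stopifnot(length(counts) == 256L)
  n <- sum(counts)
  if (n == 0L) stop("no usable columns in quartet subalignment")
  tab <- quartet_pattern_table()
  variable <- !(tab$a == tab$b & tab$b == tab$c & tab$c == tab$o)
  if (sum(counts[variable]) == 0L)
    stop("all-constant quartet subalignment: mark quartet uninformative")
  ctl <- utils::modifyList(list(maxit = 200L, factr = 1e9, restarts = 2L),
                           control)
  # empirical base frequencies with a pseudocount
  freq <- vapply(1:4, function(s) {
    sum(counts * ((tab$a == s) + (tab$b == s) + (tab$c == s) + (tab$o == s)))
  }, numeric(1))
  bf0 <- (freq + 1) / (sum(freq) + 4)
  # p-distance-based starting branch lengths
  pd <- function(i, j) {
    d <- sum(counts[tab[[i]] != tab[[j]]]) / n
    max(min(d, 0.70), 0.01)
  }
  perm <- switch(topology, x1 = c("a", "b", "c"), x2 = c("a", "c", "b"),
                 x3 = c("b", "c", "a"))
  t12 <- pd(perm[1L], perm[2L])
  t3o <- pd(perm[3L], "o")
  bl0 <- c(a = t12 / 2, b = t12 / 2, c = t3o / 2, o = t3o / 2, int = 0.05)
  bl0[perm[1L]] <- t12 / 2; bl0[perm[2L]] <- t12 / 2; bl0[perm[3L]] <- t3o / 2
  if (!is.null(init)) {
    par0 <- encode_par(init, bl0)
  } else {
    par0 <- encode_par(subst_model(bf = bf0, shape = 1, pinv = 0.3), bl0)
  }
  topo_int <- match(topology, c("x1", "x2", "x3"))
  nll <- function(par) .quartet_nll_cpp(par, counts, topo_int, 4L)
  run <- function(p0) {
    stats::optim(p0, nll, method = "L-BFGS-B",
                 lower = rep(-9, length(p0)), upper = rep(9, length(p0)),
                 control = list(maxit = ctl$maxit, factr = ctl$factr))
  }
  fit <- run(par0)
  tries <- 0L
  while (fit$convergence != 0L && tries < ctl$restarts) {
    tries <- tries + 1L
    cand <- run(par0 + stats::rnorm(length(par0), sd = 0.3))
    if (cand$value < fit$value) fit <- cand
  }
  if (fit$convergence != 0L)
    warning("quartet model optimizer did not fully converge; ",
            "best-found parameters returned")
  dec <- decode_par(fit$par)
  structure(list(topology = topology, model = dec$model, blen = dec$blen,
                 logLik = -fit$value, logLik0 = -nll(par0),
                 n_usable = n, counts = counts,
                 convergence = fit$convergence),
            class = "quartet_fit")
}

# Parameter transform: log branch lengths (5), log exchangeabilities vs GT
# (5), log base-frequency ratios vs T (3), log shape, logit pinv.
encode_par <- function(model, blen) {
  c(log(pmax(blen, 1e-6)),
    log(model$rates[1:5]),
    log(model$bf[1:3] / model$bf[4L]),
    log(model$shape),
    stats::qlogis(max(model$pinv, 1e-4)))
}

decode_par <- function(par) {
  blen <- exp(par[1:5])
  names(blen) <- c("a", "b", "c", "o", "int")
  bf <- c(exp(par[11:13]), 1)
  bf <- bf / sum(bf)
  list(model = subst_model(rates = c(exp(par[6:10]), 1), bf = bf,
                           shape = exp(par[14L]),
                           pinv = stats::plogis(par[15L])),
       blen = blen)
}

#' @export
print.quartet_fit <- function(x, ...) {
  cat(sprintf("quartet fit [%s]: logLik %.3f over %d usable sites\n",
              x$topology, x$logLik, x$n_usable))
  print(x$model)
  cat("branch lengths:",
      paste(names(x$blen), signif(x$blen, 3), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.quartet_fit <- function(object, ...) {
  structure(object$logLik, df = 15L, class = "logLik")
}

#' Probability of a polarized topology-support pattern class
#'
#' Sums the exact pattern probabilities of the 12 site patterns that
#' constitute strict synapomorphic support for a topology (the grouped pair
#' sharing one of 3 derived states against any of 4 plesiomorphic outgroup
#' states), under a fitted quartet model.
#'
#' @param fit a \code{\link{fit_gtr_gamma_i}} result.
#' @param class \code{"x1"}, \code{"x2"} or \code{"x3"}: the support class.
#' @return probability in [0, 1].
#' @export
pattern_class_probability <- function(fit, class = c("x1", "x2", "x3")) {
  class <- match.arg(class)
  p <- quartet_pattern_probs(fit$model, fit$blen, fit$topology)
  tab <- quartet_pattern_table()
  sum(p[tab$class == match(class, c("x1", "x2", "x3"))])
}

#' Expected convergent site count Nc(x)
#'
#' The convergent (homoplastic) signal for topology \code{x}: the number of
#' x-supporting polarized site patterns expected to arise when \code{x} is
#' false, i.e. under the models fitted to the two rival topologies.  The
#' default averages the expectation over both rivals; \code{mode = "max"}
#' takes the more pessimistic rival.
#'
#' @param fits named list of three \code{\link{fit_gtr_gamma_i}} results
#'   (names \code{x1}, \code{x2}, \code{x3}).
#' @param x topology whose convergent expectation is wanted.
#' @param n_usable number of usable columns to scale the class probability.
#' @param mode \code{"mean"} (default) or \code{"max"} over the two rivals.
#' @return nonnegative expected count.
#' @export
expected_convergent_count <- function(fits, x = c("x1", "x2", "x3"),
                                      n_usable, mode = c("mean", "max")) {
  x <- match.arg(x); mode <- match.arg(mode)
  rivals <- setdiff(c("x1", "x2", "x3"), x)
  if (!all(rivals %in% names(fits)))
    stop("missing fit(s) for rival topologies: ",
         paste(setdiff(rivals, names(fits)), collapse = ", "))
  p <- vapply(rivals, function(y) pattern_class_probability(fits[[y]], x),
              numeric(1))
  n_usable * if (mode == "mean") mean(p) else max(p)
}
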