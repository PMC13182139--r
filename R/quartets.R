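#' Enumerate clade-quartets
#'
#' A clade-quartet is the outgroup clade together with one of the
#' \eqn{\binom{k}{3}} triplets of the \eqn{k} ingroup clades.  The three
#' ingroup clades are ordered alphabetically and the quartet id is the
#' sorted concatenation of all four clade labels (so with ingroups E,K,R and
#' outgroup O the id is \code{"EKOR"}).
#'
#' @param ca a \code{\link{clade_assignment}}.
#' @return data.frame with columns \code{id}, \code{c1}, \code{c2},
#'   \code{c3} (ingroup clades, sorted) and \code{outgroup}.
#' @export
enumerate_clade_quartets <- function(ca) {
  ing <- sort(ca$ingroup_clades)
  trip <- utils::combn(ing, 3L)
  ids <- apply(trip, 2L, function(cl)
    paste(sort(c(cl, ca$outgroup_clade)), collapse = ""))
  out <- data.frame(id = ids, c1 = trip[1L, ], c2 = trip[2L, ],
                    c3 = trip[3L, ], outgroup = ca$outgroup_clade)
  out[order(out$id), , drop = FALSE]
}

#' Enumerate species-quartets of one clade-quartet
#'
#' The cartesian product of the member species of the three ingroup clades
#' and of the outgroup clade, in canonical (sorted species label) order.
#' Ingroup position \code{a} always carries clade \code{c1}, \code{b} clade
#' \code{c2} and \code{c} clade \code{c3}; the three rooted topologies are
#' labelled \code{x1} = (a,b) grouped, \code{x2} = (a,c), \code{x3} = (b,c).
#'
#' @param cq one row of \code{\link{enumerate_clade_quartets}} output (or a
#'   list with \code{id}, \code{c1}, \code{c2}, \code{c3}, \code{outgroup}).
#' @param ca a \code{\link{clade_assignment}}.
#' @return data.frame with columns \code{quartet_id}, \code{clade_quartet},
#'   \code{a}, \code{b}, \code{c}, \code{o}.
#' @export
enumerate_species_quartets <- function(cq, ca) {
  mem <- lapply(c(cq$c1, cq$c2, cq$c3, cq$outgroup), clade_members, ca = ca)
  if (any(!lengths(mem)))
    stop("empty clade in clade-quartet ", cq$id)
  g <- expand.grid(a = mem[[1L]], b = mem[[2L]], c = mem[[3L]],
                   o = mem[[4L]], KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[order(g$a, g$b, g$c, g$o), , drop = FALSE]
  data.frame(quartet_id = paste(g$a, g$b, g$c, g$o, sep = "|"),
             clade_quartet = cq$id, g, row.names = NULL)
}

#' Enumerate every species-quartet of an assignment
#'
#' @param ca a \code{\link{clade_assignment}}.
#' @return data.frame as \code{\link{enumerate_species_quartets}}, stacked
#'   over all clade-quartets in canonical order.
#' @export
enumerate_all_species_quartets <- function(ca) {
  cqs <- enumerate_clade_quartets(ca)
  do.call(rbind, lapply(seq_len(nrow(cqs)), function(i)
    enumerate_species_quartets(cqs[i, ], ca)))
}

#' Extract the polarized subalignment of one species-quartet
#'
#' Rows are ordered a, b, c (ingroup) then o (outgroup).  A column is usable
#' when all four characters are unambiguous nucleotides; gaps and IUPAC
#' ambiguity codes exclude the column (ambiguity is treated as missing
#' rather than as partial information).
#'
#' @param m a \code{\link{supermatrix}}.
#' @param q one row of \code{\link{enumerate_species_quartets}} output.
#' @return list with \code{sub} (4 x n character matrix) and \code{usable}
#'   (logical mask over columns).
#' @export
extract_quartet_subalignment <- function(m, q) {
  sp <- c(q$a, q$b, q$c, q$o)
  absent <- setdiff(sp, m$taxa)
  if (length(absent))
    stop("species absent from alignment: ", paste(absent, collapse = ", "))
  sub <- m$seq[sp, , drop = FALSE]
  usable <- colSums(matrix(sub %in% DNA_BASES, nrow = 4L)) == 4L
  list(sub = sub, usable = usable)
}

# Classify polarized quartet site patterns.  Inputs are parallel character
# vectors of unambiguous nucleotide states for ingroup taxa a, b, c and
# outgroup o.  Returns integer: 1 if the pattern is a strict synapomorphy
# for topology x1 (a,b grouped: a==b, c==o, a!=o), 2 for x2 (a,c), 3 for x3
# (b,c), 0 otherwise.  The outgroup state is taken as plesiomorphic; the
# third ingroup taxon must retain it, so the three classes are mutually
# exclusive.
classify_polarized_pattern <- function(a, b, c, o) {
  cls <- integer(length(a))
  cls[a == b & c == o & a != o] <- 1L
  cls[a == c & b == o & a != o] <- 2L
  cls[b == c & a == o & b != o] <- 3L
  cls
}

#' Count synapomorphic site patterns per rooted quartet topology
#'
#' Over the usable columns of a quartet subalignment, counts for each rooted
#' topology the columns in which the grouped ingroup pair shares a state
#' derived relative to the outgroup while the remaining ingroup taxon
#' retains the outgroup (plesiomorphic) state.  These are the apomorphic
#' signals Na(x1), Na(x2), Na(x3); the classes are mutually exclusive.
#'
#' @param sub 4 x n character matrix (rows a, b, c, o).
#' @param usable logical mask of usable columns (see
#'   \code{\link{extract_quartet_subalignment}}).
#' @return list of class \code{"pattern_counts"}: \code{Na} (named numeric,
#'   x1/x2/x3), \code{n_usable}, \code{n_informative}.
#' @export
count_polarized_patterns <- function(sub, usable = rep(TRUE, ncol(sub))) {
  u <- sub[, usable, drop = FALSE]
  cls <- classify_polarized_pattern(u[1L, ], u[2L, ], u[3L, ], u[4L, ])
  Na <- vapply(1:3, function(k) sum(cls == k), numeric(1))
  names(Na) <- c("x1", "x2", "x3")
  structure(list(Na = Na, n_usable = ncol(u), n_informative = sum(cls > 0L)),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("usable: %d | informative: %d | Na: x1=%d x2=%d x3=%d\n",
              x$n_usable, x$n_informative, x$Na[1L], x$Na[2L], x$Na[3L]))
  invisible(x)
}

#' Minimum informative-column check
#'
#' Quartets whose subalignment carries fewer informative columns than
#' \code{min_cols} are excluded before model fitting and scoring; the bound
#' is inclusive (exactly \code{min_cols} passes).
#'
#' @param pc a \code{\link{count_polarized_patterns}} result.
#' @param min_cols minimum number of informative columns (default 20).
#' @return logical: \code{TRUE} if the quartet passes.
#' @export
check_min_informative <- function(pc, min_cols = 20L) {
  pc$n_informative >= min_cols
}

# All 256 nucleotide patterns for taxa (a, b, c, o) with their topology
# class.  Pattern index encodes states base 4, a fastest-varying... fixed
# order used by the likelihood engine: idx = sa + 4*(sb-1) + 16*(sc-1) +
# 64*(so-1), states A=1, C=2, G=3, T=4.
quartet_pattern_table <- function() {
  g <- expand.grid(a = 1:4, b = 1:4, c = 1:4, o = 1:4)
  g$class <- classify_polarized_pattern(g$a, g$b, g$c, g$o)
  g
}
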