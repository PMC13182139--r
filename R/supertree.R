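# Rooted binary clade trees are represented as nested lists: a leaf is its
# clade label (character), an internal node a list of its two children.
# Identity and ordering use the canonical newick string (children sorted
# lexicographically at every node).

canonical_label <- function(tree) {
  if (is.character(tree)) return(tree)
  kids <- sort(vapply(tree, canonical_label, character(1)))
  paste0("(", paste(kids, collapse = ","), ")")
}

tree_leaves <- function(tree) {
  if (is.character(tree)) return(tree)
  unlist(lapply(tree, tree_leaves), use.names = FALSE)
}

# every way to attach `leaf` along an edge of `tree` (including the root
# edge): a tree with m leaves yields 2m - 1 placements
insert_leaf <- function(tree, leaf) {
  out <- list(list(tree, leaf))  # new root above the old one
  if (!is.character(tree)) {
    for (i in 1:2) {
      for (sub in insert_leaf(tree[[i]], leaf)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

#' Enumerate all rooted binary trees on a set of clade labels
#'
#' Exhaustive, non-heuristic enumeration by recursive leaf insertion; the
#' number of trees on n labels is the double factorial (2n-3)!!.  Results
#' are deduplicated by canonical form and returned sorted by canonical
#' newick string, so the order is reproducible.
#'
#' @param clades character vector of 2 to 8 clade labels.
#' @return named list of trees (nested-list form); names are canonical
#'   newick strings without branch lengths or trailing semicolon.
#' @export
enumerate_rooted_clade_trees <- function(clades) {
  clades <- sort(unique(clades))
  n <- length(clades)
  if (n < 2L || n > 8L)
    stop("rooted clade-tree enumeration supports 2 to 8 clades, got ", n)
  trees <- list(clades[1L])
  for (k in 2:n)
    trees <- unlist(lapply(trees, insert_leaf, leaf = clades[k]),
                    recursive = FALSE)
  names(trees) <- vapply(trees, canonical_label, character(1))
  if (anyDuplicated(names(trees)))
    trees <- trees[!duplicated(names(trees))]
  trees[order(names(trees))]
}

#' Rooted triplet topology a clade tree induces on three clades
#'
#' Every rooted binary tree groups exactly one pair of the three clades
#' (the pair whose most recent common ancestor excludes the third); with
#' the outgroup on the root side this is the rooted quartet topology the
#' tree implies.  Topology labels follow the quartet convention for the
#' alphabetically sorted triplet (c1, c2, c3): \code{"x1"} groups (c1,c2),
#' \code{"x2"} groups (c1,c3), \code{"x3"} groups (c2,c3).
#'
#' @param tree nested-list clade tree (see
#'   \code{\link{enumerate_rooted_clade_trees}}) or newick string.
#' @param triplet character vector of three clade labels.
#' @return \code{"x1"}, \code{"x2"} or \code{"x3"}.
#' @export
induced_quartet_topology <- function(tree, triplet) {
  if (is.character(tree) && length(tree) == 1L && grepl("(", tree, fixed = TRUE))
    tree <- parse_clade_newick(tree)
  trip <- sort(triplet)
  stopifnot(length(trip) == 3L)
  if (!all(trip %in% tree_leaves(tree)))
    stop("clade(s) missing from tree: ",
         paste(setdiff(trip, tree_leaves(tree)), collapse = ", "))
  node <- tree
  repeat {
    inL <- intersect(tree_leaves(node[[1L]]), trip)
    inR <- intersect(tree_leaves(node[[2L]]), trip)
    if (length(inL) == 3L) { node <- node[[1L]]; next }
    if (length(inR) == 3L) { node <- node[[2L]]; next }
    pair <- if (length(inL) == 2L) inL else inR
    break
  }
  pair <- sort(pair)
  if (identical(pair, trip[1:2])) return("x1")
  if (identical(pair, trip[c(1L, 3L)])) return("x2")
  "x3"
}

#' Total compatible-quartet support of a candidate clade tree
#'
#' Sums, over all non-empty clade-quartet summaries, the median normalized
#' support of the topology the candidate tree induces on that clade
#' triplet.  With k summaries and supports in [0, 1] the total lies in
#' [0, k].
#'
#' @param tree nested-list clade tree or newick string.
#' @param summaries data.frame from \code{\link{summarize_clade_quartets}}.
#' @return numeric total support.
#' @export
total_tree_support <- function(tree, summaries) {
  if (is.character(tree)) tree <- parse_clade_newick(tree)
  use <- summaries[!summaries$empty, , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(use))) {
    topo <- induced_quartet_topology(tree, c(use$c1[i], use$c2[i], use$c3[i]))
    tot <- tot + use[[paste0("m", match(topo, c("x1", "x2", "x3")))]][i]
  }
  tot
}

#' Aggregate retained quartet scores of one clade-quartet
#'
#' Per-topology medians of the normalized supports over the retained
#' species-quartets (an even count takes the mean of the middle two).
#' Medians are deliberately not re-normalized across topologies.  An empty
#' retained set flags the summary empty; such clade-quartets are excluded
#' from every candidate tree's total equally.
#'
#' @param scores filtered scores of one clade-quartet.
#' @return one-row data.frame: \code{clade_quartet}, \code{c1..c3},
#'   \code{m1..m3} (medians), \code{n_retained}, \code{n_total},
#'   \code{empty}.
#' @export
aggregate_clade_quartet <- function(scores) {
  ret <- scores[scores$status == "retained", , drop = FALSE]
  cq <- scores$clade_quartet[1L]
  cl <- sort(unique(unlist(strsplit(cq, ""))))
  # clade letters of the three ingroup positions come from the species rows
  out <- data.frame(clade_quartet = cq,
                    c1 = NA_character_, c2 = NA_character_,
                    c3 = NA_character_,
                    m1 = NA_real_, m2 = NA_real_, m3 = NA_real_,
                    n_retained = nrow(ret), n_total = nrow(scores),
                    empty = nrow(ret) == 0L)
  if (all(c("clade_a", "clade_b", "clade_c") %in% names(scores))) {
    out$c1 <- scores$clade_a[1L]; out$c2 <- scores$clade_b[1L]
    out$c3 <- scores$clade_c[1L]
  }
  if (nrow(ret)) {
    out$m1 <- stats::median(ret$s1)
    out$m2 <- stats::median(ret$s2)
    out$m3 <- stats::median(ret$s3)
  } else {
    warning("clade-quartet ", cq,
            " has no retained quartets; excluded from tree scoring")
  }
  out
}

#' Aggregate all clade-quartets of a filtered score table
#'
#' @param scores filtered scores (rows carry \code{clade_quartet},
#'   \code{clade_a}, \code{clade_b}, \code{clade_c}).
#' @return data.frame with one row per clade-quartet (see
#'   \code{\link{aggregate_clade_quartet}}).
#' @export
summarize_clade_quartets <- function(scores) {
  do.call(rbind, lapply(split(scores, scores$clade_quartet),
                        aggregate_clade_quartet))
}

#' Exhaustively rank all rooted clade trees
#'
#' Enumerates every rooted binary tree on the ingroup clades, scores each by
#' its total compatible-quartet support and sorts in non-increasing order.
#' Exact support ties are broken by canonical newick order and flagged.
#' Support distances are measured from the best tree.
#'
#' @param summaries data.frame from \code{\link{summarize_clade_quartets}}.
#' @param clades optional explicit clade set; defaults to the clades
#'   appearing in \code{summaries}.
#' @return object of class \code{"clade_tree_ranking"}: a data.frame
#'   \code{ranking} (\code{rank}, \code{newick}, \code{support},
#'   \code{dist_to_best}, \code{tie}), plus \code{trees}, \code{best},
#'   \code{second}.
#' @export
rank_trees <- function(summaries, clades = NULL) {
  use <- summaries[!summaries$empty, , drop = FALSE]
  if (!nrow(use)) stop("no non-empty clade-quartet summaries to rank on")
  if (is.null(clades))
    clades <- sort(unique(c(use$c1, use$c2, use$c3)))
  trees <- enumerate_rooted_clade_trees(clades)
  supp <- vapply(trees, total_tree_support, numeric(1), summaries = use)
  ord <- order(-supp, names(trees))
  supp <- supp[ord]; trees <- trees[ord]
  rk <- data.frame(rank = seq_along(trees), newick = names(trees),
                   support = supp, dist_to_best = supp[1L] - supp,
                   row.names = NULL)
  rk$tie <- c(FALSE, abs(diff(supp)) < 1e-12)
  structure(list(ranking = rk, trees = trees,
                 best = names(trees)[1L],
                 second = if (length(trees) > 1L) names(trees)[2L]),
            class = "clade_tree_ranking")
}

#' @export
print.clade_tree_ranking <- function(x, n = 5L, ...) {
  cat("rooted clade-tree ranking over", nrow(x$ranking), "trees\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  if (nrow(x$ranking) > n) cat("...\n")
  invisible(x)
}

#' Compare two rooted clade trees
#'
#' Canonical-form equality plus a breakdown of the rooted clades (internal
#' leaf sets of two or more clades) shared by and conflicting between the
#' two trees.
#'
#' @param t1,t2 nested-list clade trees or newick strings; leaf sets must
#'   match.
#' @return list: \code{same}, \code{shared}, \code{only_t1}, \code{only_t2}
#'   (character vectors of sorted comma-joined leaf sets).
#' @export
compare_topologies <- function(t1, t2) {
  if (is.character(t1)) t1 <- parse_clade_newick(t1)
  if (is.character(t2)) t2 <- parse_clade_newick(t2)
  if (!setequal(tree_leaves(t1), tree_leaves(t2)))
    stop("trees have different leaf sets")
  cl <- function(tree) {
    acc <- character(0)
    walk <- function(node) {
      if (is.character(node)) return(node)
      lv <- sort(c(walk(node[[1L]]), walk(node[[2L]])))
      acc[[length(acc) + 1L]] <<- paste(lv, collapse = ",")
      lv
    }
    walk(tree)
    acc
  }
  c1 <- cl(t1); c2 <- cl(t2)
  list(same = identical(canonical_label(t1), canonical_label(t2)),
       shared = sort(intersect(c1, c2)),
       only_t1 = sort(setdiff(c1, c2)),
       only_t2 = sort(setdiff(c2, c1)))
}

#' Score an externally supplied clade tree within a ranking
#'
#' Parses a rooted newick tree on the ingroup clades (the outgroup leaf, if
#' present, is removed first), computes its total compatible-quartet
#' support, and reports the rank it attains among all exhaustively
#' enumerated trees.
#'
#' @param newick newick string (clade labels as tips; branch lengths
#'   ignored).
#' @param ranking a \code{\link{rank_trees}} result.
#' @param outgroup optional outgroup tip label to drop before scoring.
#' @param summaries the summaries used to build \code{ranking}.
#' @return list: \code{newick} (canonical), \code{support}, \code{rank},
#'   \code{dist_to_best}.
#' @export
score_external_tree <- function(newick, ranking, summaries, outgroup = NULL) {
  tr <- parse_clade_newick(newick, drop = outgroup)
  key <- canonical_label(tr)
  supp <- total_tree_support(tr, summaries[!summaries$empty, , drop = FALSE])
  pos <- match(key, ranking$ranking$newick)
  list(newick = key, support = supp,
       rank = if (!is.na(pos)) ranking$ranking$rank[pos] else NA_integer_,
       dist_to_best = ranking$ranking$support[1L] - supp)
}

# parse a newick string into the nested-list clade-tree form via ape;
# polytomies are rejected (clade trees are binary by construction)
parse_clade_newick <- function(newick, drop = NULL) {
  txt <- if (grepl(";\\s*$", newick)) newick else paste0(newick, ";")
  ph <- ape::read.tree(text = txt)
  if (is.null(ph)) stop("malformed newick: ", newick)
  if (!is.null(drop) && drop %in% ph$tip.label)
    ph <- ape::drop.tip(ph, drop)
  phylo_to_nested(ph)
}

phylo_to_nested <- function(ph) {
  n <- length(ph$tip.label)
  kids <- split(ph$edge[, 2L], ph$edge[, 1L])
  build <- function(node) {
    if (node <= n) return(ph$tip.label[node])
    ch <- kids[[as.character(node)]]
    if (length(ch) != 2L)
      stop("clade trees must be binary (node with ", length(ch), " children)")
    lapply(ch, build)
  }
  build(n + 1L)
}

#' Convert a clade tree to newick text
#'
#' @param tree nested-list clade tree.
#' @param outgroup optional outgroup label grafted as sister to the whole
#'   ingroup, making the root explicit.
#' @return newick string with trailing semicolon.
#' @export
clade_tree_newick <- function(tree, outgroup = NULL) {
  core <- canonical_label(tree)
  if (!is.null(outgroup)) core <- paste0("(", outgroup, ",", core, ")")
  paste0(core, ";")
}
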