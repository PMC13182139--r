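#' Polarized quartet support analysis
#'
#' The main fitting function.  Runs the full analysis on a supermatrix and
#' clade assignment: enumerates every species-quartet of every
#' clade-quartet, counts synapomorphic site patterns per rooted topology,
#' fits GTR+Gamma+I to each quartet subalignment under each topology to
#' obtain the expected convergent counts, converts the Na/Nc contrast into
#' normalized topology supports, optimizes and applies the DIST and RISK
#' filters per clade-quartet, aggregates retained supports to clade-quartet
#' medians, and exhaustively ranks all rooted clade trees by total
#' compatible-quartet support.
#'
#' @param m a \code{\link{supermatrix}}.
#' @param clades a \code{\link{clade_assignment}} covering the alignment.
#' @param min_cols minimum informative columns per quartet (inclusive).
#' @param risk_mode how the convergent expectation aggregates over the two
#'   rival topologies: \code{"mean"} (default) or \code{"max"}.
#' @param thresholds optional fixed filter thresholds: data.frame with
#'   \code{L_DIST}, \code{L_RISK} (and optionally \code{clade_quartet});
#'   when \code{NULL} thresholds are optimized per clade-quartet.
#' @param fit_control optimizer control passed to
#'   \code{\link{fit_gtr_gamma_i}}.
#' @param seed seed for the optimizer restarts (the analysis itself is
#'   deterministic given data and seed).
#' @param verbose print per-quartet progress.
#' @return object of class \code{"quartet_support"} with components
#'   \code{scores}, \code{thresholds}, \code{summaries}, \code{ranking},
#'   \code{rejections}, \code{alignment}, \code{clades}, \code{settings}.
#' @export
quartet_support <- function(m, clades, min_cols = 20L,
                            risk_mode = c("mean", "max"), thresholds = NULL,
                            fit_control = list(maxit = 60L, factr = 1e10,
                                               restarts = 1L),
                            seed = 1L, verbose = FALSE) {
  risk_mode <- match.arg(risk_mode)
  validate_assignment(m, clades)
  set.seed(seed)
  quartets <- enumerate_all_species_quartets(clades)
  quartets$clade_a <- unname(clades$clade_of[quartets$a])
  quartets$clade_b <- unname(clades$clade_of[quartets$b])
  quartets$clade_c <- unname(clades$clade_of[quartets$c])
  rows <- vector("list", nrow(quartets))
  for (i in seq_len(nrow(quartets))) {
    q <- quartets[i, ]
    ex <- extract_quartet_subalignment(m, q)
    pc <- count_polarized_patterns(ex$sub, ex$usable)
    if (!check_min_informative(pc, min_cols)) {
      if (verbose)
        message(q$quartet_id, ": only ", pc$n_informative,
                " informative columns (< ", min_cols, "), excluded")
      rows[[i]] <- data.frame(
        Na1 = pc$Na[1L], Na2 = pc$Na[2L], Na3 = pc$Na[3L],
        Nc1 = NA_real_, Nc2 = NA_real_, Nc3 = NA_real_,
        s1 = NA_real_, s2 = NA_real_, s3 = NA_real_,
        best = NA_character_, second = NA_character_,
        sd12 = NA_real_, risk = NA_real_, tie = FALSE,
        status = "uninformative",
        n_usable = pc$n_usable, n_informative = pc$n_informative)
      next
    }
    counts <- pattern_counts_256(ex$sub, ex$usable)
    nc <- quartet_convergent_counts(counts, pc$n_usable, risk_mode,
                                    fit_control)
    sc <- score_quartet(pc, nc)
    sc$n_usable <- pc$n_usable
    sc$n_informative <- pc$n_informative
    rows[[i]] <- sc
    if (verbose)
      message(q$quartet_id, ": best ", sc$best,
              " sd12 ", signif(sc$sd12, 3), " risk ", signif(sc$risk, 3))
  }
  scores <- cbind(quartets, do.call(rbind, rows))
  rownames(scores) <- NULL
  if (is.null(thresholds)) {
    thresholds <- do.call(rbind, lapply(
      split(scores, scores$clade_quartet), optimize_thresholds))
    thresholds <- cbind(clade_quartet = rownames(thresholds), thresholds)
    rownames(thresholds) <- NULL
  } else if (!"provenance" %in% names(thresholds)) {
    thresholds$provenance <- "user"
  }
  scores <- apply_filters(scores, thresholds)
  summaries <- summarize_clade_quartets(scores)
  ranking <- rank_trees(summaries)
  structure(list(
    scores = scores, thresholds = thresholds, summaries = summaries,
    ranking = ranking,
    rejections = rejection_summary(scores),
    alignment = summarize_alignment(m),
    clades = clades,
    settings = list(min_cols = min_cols, risk_mode = risk_mode,
                    fit_control = fit_control, seed = seed)),
    class = "quartet_support")
}

# fit the three rooted topologies to one quartet pattern-count vector and
# return the expected convergent counts Nc(x1), Nc(x2), Nc(x3)
quartet_convergent_counts <- function(counts, n_usable, risk_mode,
                                      fit_control) {
  topo <- c("x1", "x2", "x3")
  fits <- vector("list", 3L); names(fits) <- topo
  fits$x1 <- fit_gtr_gamma_i(counts, "x1", control = fit_control)
  # warm-start the rival topologies from the first fit's model
  fits$x2 <- fit_gtr_gamma_i(counts, "x2", init = fits$x1$model,
                             control = fit_control)
  fits$x3 <- fit_gtr_gamma_i(counts, "x3", init = fits$x1$model,
                             control = fit_control)
  tab <- quartet_pattern_table()
  # class probability matrix: classprob[y, x] = P(pattern class x | fit y)
  classprob <- t(vapply(topo, function(y) {
    p <- quartet_pattern_probs(fits[[y]]$model, fits[[y]]$blen, y)
    vapply(1:3, function(x) sum(p[tab$class == x]), numeric(1))
  }, numeric(3)))
  nc <- vapply(1:3, function(x) {
    rival <- setdiff(1:3, x)
    n_usable * if (risk_mode == "mean") mean(classprob[rival, x])
               else max(classprob[rival, x])
  }, numeric(1))
  names(nc) <- topo
  nc
}

#' @export
print.quartet_support <- function(x, ...) {
  st <- table(factor(x$scores$status,
                     c("retained", "rejected_dist", "rejected_risk",
                       "uninformative")))
  cat("polarized quartet support analysis\n")
  print(x$alignment)
  cat(sprintf("%d species-quartets in %d clade-quartets: %d retained, %d rejected (DIST), %d rejected (RISK), %d uninformative\n",
              nrow(x$scores), nrow(x$summaries), st[1L], st[2L], st[3L],
              st[4L]))
  cat("best rooted clade tree:",
      clade_tree_newick(x$ranking$trees[[1L]],
                        outgroup = x$clades$outgroup_clade), "\n")
  invisible(x)
}

#' @export
summary.quartet_support <- function(object, ...) {
  structure(list(fit = object), class = "summary.quartet_support")
}

#' @export
print.summary.quartet_support <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nper clade-quartet (medians over retained quartets):\n")
  s <- merge(f$summaries, f$thresholds, by = "clade_quartet")
  print(s[, c("clade_quartet", "n_retained", "n_total",
              "m1", "m2", "m3", "L_DIST", "L_RISK")],
        row.names = FALSE, digits = 3)
  cat("\ntop-ranked rooted clade trees:\n")
  print(utils::head(f$ranking$ranking, 5L), row.names = FALSE, digits = 4)
  top <- utils::head(f$rejections, 5L)
  if (nrow(top) && any(top$pct_rejected > 0)) {
    cat("\nmost-rejected species:\n")
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.quartet_support <- function(object, ...) {
  stats::setNames(
    object$thresholds[, c("clade_quartet", "L_DIST", "L_RISK")],
    c("clade_quartet", "L_DIST", "L_RISK"))
}

#' Ternary (barycentric) coordinates of quartet supports
#'
#' Embeds each informative quartet's normalized topology supports
#' (s1, s2, s3) in the unit triangle with corners x1 = (0,0), x2 = (1,0),
#' x3 = (0.5, sqrt(3)/2).  A quartet at a corner fully supports that
#' topology; the centroid is three-way conflict; edge midpoints are
#' two-topology conflict.
#'
#' @param scores a \code{quartet_support} object or its \code{scores}
#'   data.frame.
#' @return data.frame: \code{quartet_id}, \code{clade_quartet}, \code{x},
#'   \code{y}, \code{status}.
#' @export
ternary_coordinates <- function(scores) {
  if (inherits(scores, "quartet_support")) scores <- scores$scores
  inf <- scores[!is.na(scores$s1), , drop = FALSE]
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  w <- as.matrix(inf[, c("s1", "s2", "s3")])
  xy <- w %*% corners
  data.frame(quartet_id = inf$quartet_id,
             clade_quartet = inf$clade_quartet,
             x = xy[, 1L], y = xy[, 2L], status = inf$status,
             row.names = NULL)
}

#' @export
plot.quartet_support <- function(x, ...) {
  tc <- ternary_coordinates(x)
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.1, sqrt(3) / 2 + 0.05),
       asp = 1, axes = FALSE, xlab = "", ylab = "",
       main = "quartet topology support", ...)
  polygon(corners[, 1L], corners[, 2L])
  text(corners[, 1L], corners[, 2L] + c(-0.05, -0.05, 0.04),
       c("x1", "x2", "x3"))
  pch <- ifelse(tc$status == "retained", 19L, 1L)
  col <- ifelse(tc$status == "retained", "#c2407f", "#4060c2")
  points(tc$x, tc$y, pch = pch, col = col, cex = 0.7)
  invisible(x)
}

#' Read and write newick trees
#'
#' Thin wrappers over ape with hard errors on malformed input; polytomies
#' are allowed on read.
#'
#' @param path file path (or, for \code{read_newick}, a literal newick
#'   string when \code{text = TRUE}).
#' @param text treat \code{path} as newick text.
#' @return \code{read_newick}: an \code{ape::phylo}.
#' @export
read_newick <- function(path, text = FALSE) {
  tr <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick input")
  tr
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo} or nested-list clade tree.
#' @param outgroup optional outgroup label for clade trees.
#' @export
write_newick <- function(tree, path, outgroup = NULL) {
  if (!inherits(tree, "phylo"))
    tree <- read_newick(clade_tree_newick(tree, outgroup), text = TRUE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root-to-tip distances
#'
#' Sum of branch lengths from the root to every leaf; long root-to-tip
#' distances mark fast-evolving (long-branch) lineages, which is the
#' diagnostic joined against the per-species rejection summary.
#'
#' @param tree an \code{ape::phylo} with branch lengths, or newick text.
#' @param outgroup optional tip label used to root an unrooted input.
#' @return data.frame with \code{species} and \code{distance}, sorted
#'   decreasing.
#' @export
root_to_tip_distances <- function(tree, outgroup = NULL) {
  if (is.character(tree)) tree <- read_newick(tree, text = TRUE)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("unrooted tree: supply an outgroup tip to root on")
    tree <- ape::root(tree, outgroup, resolve.root = TRUE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  out <- data.frame(species = tree$tip.label, distance = d)
  out[order(-out$distance, out$species), , drop = FALSE]
}

#' Run the full pipeline and write a report directory
#'
#' Either analyzes a supplied supermatrix + clade table or simulates one of
#' the preset scenarios first, then writes all result tables (scores,
#' thresholds, clade-quartet summaries, tree ranking, rejection summary,
#' ternary coordinates) as TSV/JSON plus a provenance log.  Reruns with the
#' same inputs and seed produce identical outputs.
#'
#' @param output_dir directory to create.
#' @param m,clades a \code{\link{supermatrix}} and
#'   \code{\link{clade_assignment}} (mutually exclusive with
#'   \code{preset}).
#' @param preset a \code{\link{preset_scenarios}} name.
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{quartet_support}}.
#' @return the \code{quartet_support} object, invisibly.
#' @export
run_pipeline <- function(output_dir, m = NULL, clades = NULL, preset = NULL,
                         seed = 1L, ...) {
  if (is.null(preset) == is.null(m))
    stop("supply exactly one of 'preset' or 'm' + 'clades'")
  if (!is.null(preset)) {
    ds <- simulate_dataset(preset, seed = seed)
    m <- ds$supermatrix
    clades <- scenario_clades(preset_scenarios(preset, seed = seed))
  }
  if (is.null(clades)) stop("'clades' is required with 'm'")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- quartet_support(m, clades, seed = seed, ...)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(fit$scores, "scores.tsv")
  wtsv(fit$thresholds, "thresholds.tsv")
  wtsv(fit$summaries, "summaries.tsv")
  wtsv(fit$ranking$ranking, "ranking.tsv")
  wtsv(fit$rejections, "rejections.tsv")
  wtsv(ternary_coordinates(fit), "ternary.tsv")
  jsonlite::write_json(
    list(best = fit$ranking$best, second = fit$ranking$second,
         ranking = fit$ranking$ranking),
    file.path(output_dir, "ranking.json"), auto_unbox = TRUE, digits = NA)
  writeLines(clade_tree_newick(fit$ranking$trees[[1L]],
                               outgroup = clades$outgroup_clade),
             file.path(output_dir, "best_tree.nwk"))
  cfg <- list(seed = seed, preset = preset, settings = fit$settings,
              package_version = as.character(utils::packageVersion("quartetpol")),
              r_version = as.character(getRversion()))
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  writeLines(c(paste("run completed:", nrow(fit$scores), "quartets"),
               paste("config md5:", unname(tools::md5sum(cfg_path))),
               paste("best tree:", fit$ranking$best)),
             file.path(output_dir, "log.txt"))
  invisible(fit)
}
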