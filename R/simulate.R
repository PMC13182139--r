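#' Specify a simulation scenario
#'
#' A scenario fixes a rooted clade tree with internode lengths in coalescent
#' units (the control on incomplete lineage sorting), the number of species
#' per clade, per-clade substitution-rate scalars applied to terminal
#' branches (the control on long-branch effects), the locus structure and
#' the substitution model.  One haploid individual is sampled per species;
#' within a clade the species hang off a shallow caterpillar, since
#' within-clade phylogeny is not analyzed.
#'
#' @param clade_tree newick string on clade labels, rooted, with branch
#'   lengths in coalescent units; the outgroup clade must be the basal tip.
#' @param outgroup label of the outgroup clade in \code{clade_tree}.
#' @param species_counts named integer vector: species per clade.
#' @param rate_scalars named numeric: terminal-branch rate multiplier per
#'   clade (default 1 for unnamed clades).
#' @param n_loci number of independently coalescing loci.
#' @param locus_length alignment columns per locus.
#' @param model a \code{\link{subst_model}} for sequence evolution.
#' @param mu substitutions per site per coalescent unit at rate scalar 1.
#' @param within_clade_internode coalescent-unit spacing of the within-clade
#'   caterpillar.
#' @param seed mandatory integer random seed.
#' @return object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(clade_tree, outgroup, species_counts,
                          rate_scalars = NULL, n_loci = 100L,
                          locus_length = 500L,
                          model = subst_model(shape = 1, pinv = 0.3),
                          mu = 0.02, within_clade_internode = 0.5,
                          seed) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  stopifnot(all(species_counts >= 1L), n_loci >= 1L, locus_length >= 1L,
            mu >= 0)
  ph <- ape::read.tree(text = clade_tree)
  stopifnot(!is.null(ph), !is.null(ph$edge.length),
            outgroup %in% ph$tip.label,
            setequal(ph$tip.label, names(species_counts)))
  if (any(ph$edge.length < 0)) stop("negative internode length")
  rs <- stats::setNames(rep(1, length(ph$tip.label)), ph$tip.label)
  if (!is.null(rate_scalars)) rs[names(rate_scalars)] <- rate_scalars
  structure(list(clade_tree = clade_tree, clade_phylo = ph,
                 outgroup = outgroup,
                 species_counts = species_counts, rate_scalars = rs,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 model = model, mu = mu,
                 within_clade_internode = within_clade_internode,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario:", sum(x$species_counts), "species in",
      length(x$species_counts), "clades |", x$n_loci, "loci x",
      x$locus_length, "bp | seed", x$seed, "\n")
  cat("clade tree:", x$clade_tree, "\n")
  invisible(x)
}

# Expand the clade tree into a species tree (ape phylo, coalescent units):
# each clade tip is replaced by a caterpillar of its species.  Species are
# labelled <clade>_sp<i> unless the clade has a single species, which keeps
# the clade label with suffix _sp1 for uniformity.
species_tree_from_spec <- function(spec) {
  # caterpillar newick for one clade, outermost node carrying no length so
  # the clade tree's stem length attaches to it on substitution
  sub_newick <- function(clade) {
    n <- spec$species_counts[[clade]]
    d <- spec$within_clade_internode
    sp <- paste0(clade, "_sp", seq_len(n))
    if (n == 1L) return(sp)
    s <- paste0("(", sp[1L], ":", d, ",", sp[2L], ":", d, ")")
    if (n > 2L) for (i in 3:n)
      s <- paste0("(", s, ":", d, ",", sp[i], ":", d * (i - 1), ")")
    s
  }
  nw <- spec$clade_tree
  for (clade in names(spec$species_counts)) {
    nw <- sub(paste0("(?<![A-Za-z_])", clade, "(?![A-Za-z_0-9])"),
              sub_newick(clade), nw, perl = TRUE)
  }
  ape::read.tree(text = nw)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Standard MSC sampling on the scenario's species tree: within each
#' species-tree branch, k lineages coalesce at rate k(k-1)/2 per coalescent
#' unit; lineages that fail to coalesce are passed rootward, and all
#' remaining lineages coalesce above the root.  Deterministic given the
#' scenario seed.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n_trees number of gene trees (default \code{spec$n_loci}).
#' @return list of \code{ape::phylo} gene trees with branch lengths in
#'   coalescent units.
#' @export
simulate_gene_trees <- function(spec, n_trees = spec$n_loci) {
  sp_tree <- species_tree_from_spec(spec)
  set.seed(spec$seed)
  lapply(seq_len(n_trees), function(i) msc_one_tree(sp_tree))
}

# One MSC draw on an ape species tree.  Lineages are tracked as newick
# fragments with an "open" pendant length that grows as we move rootward.
msc_one_tree <- function(sp) {
  ntip <- length(sp$tip.label)
  root <- ntip + 1L
  # children and branch length lookup
  kids <- split(seq_len(nrow(sp$edge)), sp$edge[, 1L])
  # node heights (time before present measured from each tip... we only
  # need branch durations, taken from sp$edge.length)
  lineages_at <- vector("list", max(sp$edge))
  for (i in seq_len(ntip))
    lineages_at[[i]] <- list(list(txt = sp$tip.label[i], len = 0))
  # each lineage carries txt (newick fragment) and len, its accumulated
  # pendant branch length since the last coalescence
  run_branch <- function(lin, duration) {
    t <- 0
    repeat {
      k <- length(lin)
      if (k < 2L) break
      wait <- stats::rexp(1L, rate = k * (k - 1) / 2)
      if (is.finite(duration) && t + wait > duration) break
      t <- t + wait
      pair <- sort(sample.int(k, 2L))
      a <- lin[[pair[1L]]]; b <- lin[[pair[2L]]]
      merged <- list(txt = paste0("(", a$txt, ":", a$len + wait,
                                  ",", b$txt, ":", b$len + wait, ")"),
                     len = 0)
      lin[[pair[2L]]] <- NULL; lin[[pair[1L]]] <- NULL
      # grow the untouched lineages by the waiting time
      lin <- lapply(lin, function(l) { l$len <- l$len + wait; l })
      lin <- c(lin, list(merged))
    }
    if (is.finite(duration))
      lin <- lapply(lin, function(l) { l$len <- l$len + (duration - t); l })
    lin
  }
  # post-order over species-tree nodes
  visit <- function(node) {
    if (node <= ntip) return(lineages_at[[node]])
    ch <- kids[[as.character(node)]]
    lin <- list()
    for (e in ch) {
      child <- sp$edge[e, 2L]
      lin_c <- visit(child)
      lin <- c(lin, run_branch(lin_c, sp$edge.length[e]))
    }
    lin
  }
  lin <- visit(root)
  lin <- run_branch(lin, Inf)
  ape::read.tree(text = paste0(lin[[1L]]$txt, ";"))
}

#' Simulate a supermatrix along gene trees
#'
#' Each locus evolves under the scenario's GTR+Gamma+I model along its gene
#' tree; gene-tree branch lengths in coalescent units are converted to
#' substitutions per site by the scenario's \code{mu} and the per-clade
#' terminal rate scalars (terminal branches only; internal gene-tree
#' branches evolve at the base rate).  Among-site rate variation draws each
#' site's rate class (invariant or one of the discrete-gamma categories)
#' independently.  Loci are concatenated with recorded boundaries.
#'
#' @param gene_trees list of \code{ape::phylo} (coalescent units).
#' @param spec the generating \code{\link{scenario_spec}}.
#' @return list of class \code{"simulated_dataset"}: \code{supermatrix},
#'   \code{true_clade_tree} (newick), \code{species_tree}
#'   (\code{ape::phylo}), \code{gene_trees}, \code{provenance}.
#' @export
simulate_alignment <- function(gene_trees, spec) {
  set.seed(spec$seed + 1L)
  model <- spec$model
  rc <- rate_classes(model)
  loci <- vector("list", length(gene_trees))
  for (i in seq_along(gene_trees)) {
    tr <- gene_trees[[i]]
    tr$edge.length <- tr$edge.length * spec$mu
    term <- tr$edge[, 2L] <= length(tr$tip.label)
    cl <- sub("_sp[0-9]+$", "", tr$tip.label[tr$edge[term, 2L]])
    tr$edge.length[term] <- tr$edge.length[term] * spec$rate_scalars[cl]
    loci[[i]] <- sim_locus(tr, spec$locus_length, model, rc)
  }
  names(loci) <- sprintf("locus%04d", seq_along(loci))
  sm <- concatenate_loci(loci)
  structure(list(
    supermatrix = sm,
    true_clade_tree = spec$clade_tree,
    species_tree = species_tree_from_spec(spec),
    gene_trees = gene_trees,
    provenance = list(seed = spec$seed, n_loci = spec$n_loci,
                      locus_length = spec$locus_length, mu = spec$mu,
                      clade_tree = spec$clade_tree,
                      rate_scalars = as.list(spec$rate_scalars))),
    class = "simulated_dataset")
}

# simulate one locus: site rate classes drawn i.i.d., sites of each class
# evolved in one phangorn::simSeq call, columns then shuffled
sim_locus <- function(tr, len, model, rc) {
  cls <- sample.int(length(rc$rate), len, replace = TRUE, prob = rc$weight)
  mat <- matrix("A", length(tr$tip.label), len,
                dimnames = list(tr$tip.label, NULL))
  for (k in unique(cls)) {
    idx <- which(cls == k)
    if (rc$rate[k] == 0) {
      states <- sample(DNA_BASES, length(idx), replace = TRUE,
                       prob = model$bf)
      mat[, idx] <- matrix(states, length(tr$tip.label), length(idx),
                           byrow = TRUE)
    } else {
      sim <- phangorn::simSeq(tr, l = length(idx), Q = model$rates,
                              bf = model$bf, rate = rc$rate[k],
                              type = "DNA")
      ch <- toupper(as.character(sim))
      mat[rownames(ch), idx] <- ch
    }
  }
  supermatrix(mat[, sample.int(len), drop = FALSE])
}

#' @export
print.simulated_dataset <- function(x, ...) {
  print(x$supermatrix)
  cat("true clade tree:", x$true_clade_tree, "\n")
  cat("seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Three named scenarios with the packaged 6-clade structure (ingroup sizes
#' E=2, K=4, R=2, S=1, T=5; single-species outgroup O) on the tinamou-first
#' truth tree (O,(S,(T,(E,(K,R))))):
#' \describe{
#'   \item{strong_signal}{internodes of 2 coalescent units: little
#'     discordance, clean synapomorphic signal.}
#'   \item{lba}{internodes of 0.1 units plus 5x terminal rate scalars on
#'     the outgroup, tinamou and rhea clades: heavy discordance with
#'     long-branch attraction pressure.}
#'   \item{polytomy}{internodes of 0.01 units: a hard polytomy regime where
#'     the three topologies are nearly equally supported.}
#' }
#'
#' @param name preset name; omit to get the list of all presets.
#' @param seed integer seed for the returned spec.
#' @param n_loci,locus_length overrides of the locus structure.
#' @return a \code{\link{scenario_spec}} (or a named list of them).
#' @export
preset_scenarios <- function(name = NULL, seed = 1L, n_loci = 100L,
                             locus_length = 500L) {
  counts <- c(E = 2L, K = 4L, R = 2L, S = 1L, T = 5L, O = 1L)
  tmpl <- function(i, stem, scal = NULL)
    scenario_spec(
      clade_tree = sprintf(
        "(O:%g,(S:%g,(T:%g,(E:%g,(K:%g,R:%g):%g):%g):%g):%g);",
        stem["O"], stem["S"], stem["T"], stem["E"], stem["K"], stem["R"],
        i, i, i, i),
      outgroup = "O", species_counts = counts, rate_scalars = scal,
      n_loci = n_loci, locus_length = locus_length, seed = seed)
  base <- c(O = 12, S = 6, T = 6, E = 4, K = 3, R = 3)
  presets <- list(
    strong_signal = tmpl(2, base),
    lba = tmpl(0.1, base, scal = c(O = 5, T = 5, R = 5)),
    polytomy = tmpl(0.01, base))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Simulate a complete dataset from a preset or spec
#'
#' @param scenario preset name (see \code{\link{preset_scenarios}}) or a
#'   \code{\link{scenario_spec}}.
#' @param seed seed override (required for presets).
#' @param ... preset overrides passed to \code{\link{preset_scenarios}}.
#' @return a \code{simulated_dataset}.
#' @export
simulate_dataset <- function(scenario, seed = NULL, ...) {
  if (is.character(scenario))
    scenario <- preset_scenarios(scenario, seed = seed, ...)
  else if (!is.null(seed))
    scenario$seed <- as.integer(seed)
  gt <- simulate_gene_trees(scenario)
  simulate_alignment(gt, scenario)
}

#' Species tree of a scenario in substitution units
#'
#' The expanded species tree with branch lengths converted from coalescent
#' units to expected substitutions per site (terminal branches additionally
#' scaled by their clade's rate scalar), matching the expectation of the
#' sequence simulator.  Useful for root-to-tip diagnostics on simulated
#' data.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return an \code{ape::phylo}.
#' @export
scenario_substitution_tree <- function(spec) {
  tr <- species_tree_from_spec(spec)
  tr$edge.length <- tr$edge.length * spec$mu
  term <- tr$edge[, 2L] <= length(tr$tip.label)
  cl <- sub("_sp[0-9]+$", "", tr$tip.label[tr$edge[term, 2L]])
  tr$edge.length[term] <- tr$edge.length[term] * spec$rate_scalars[cl]
  tr
}

#' Clade assignment implied by a scenario
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return a \code{\link{clade_assignment}} covering the simulated species.
#' @export
scenario_clades <- function(spec) {
  sp <- unlist(lapply(names(spec$species_counts), function(cl)
    paste0(cl, "_sp", seq_len(spec$species_counts[[cl]]))))
  clade_assignment(sp, sub("_sp[0-9]+$", "", sp), spec$outgroup)
}
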