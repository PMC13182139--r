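#' Construct a clade assignment
#'
#' Maps each species to exactly one clade and designates one clade as the
#' outgroup.  At least three ingroup clades are required, since rooted
#' quartets compare three ingroup clades against the outgroup.
#'
#' @param species character vector of species labels.
#' @param clade character vector of clade labels, parallel to \code{species}.
#' @param outgroup the clade label designated as outgroup.
#' @return an object of class \code{"clade_assignment"} with components
#'   \code{clade_of} (named character), \code{outgroup_clade},
#'   \code{ingroup_clades} (sorted).
#' @export
clade_assignment <- function(species, clade, outgroup) {
  stopifnot(length(species) == length(clade), length(outgroup) == 1L)
  dup <- species[duplicated(species)]
  if (length(dup))
    stop("species assigned more than once: ", paste(unique(dup), collapse = ", "))
  clades <- unique(clade)
  if (!outgroup %in% clades)
    stop("outgroup clade '", outgroup, "' has no species")
  ingroup <- sort(setdiff(clades, outgroup))
  if (length(ingroup) < 3L)
    stop("need at least 3 ingroup clades, got ", length(ingroup))
  clade_of <- stats::setNames(clade, species)
  structure(list(clade_of = clade_of, outgroup_clade = outgroup,
                 ingroup_clades = ingroup),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  sizes <- table(x$clade_of)
  cat("clade assignment:", length(x$clade_of), "species,",
      length(x$ingroup_clades), "ingroup clades + outgroup",
      sprintf("'%s'\n", x$outgroup_clade))
  for (cl in c(x$ingroup_clades, x$outgroup_clade))
    cat(sprintf("  %s: %d species\n", cl, sizes[[cl]]))
  invisible(x)
}

#' Species belonging to one clade, in canonical (sorted) order
#' @param ca a \code{\link{clade_assignment}}.
#' @param clade a clade label.
#' @export
clade_members <- function(ca, clade) {
  sort(names(ca$clade_of)[ca$clade_of == clade])
}

#' Load a clade assignment from a two-column TSV
#'
#' Format: an initial comment line \code{#outgroup=<label>} naming the
#' outgroup clade, then tab-separated \code{species<TAB>clade} rows.
#'
#' @param path file path.
#' @return a \code{\link{clade_assignment}}.
#' @export
load_clade_assignment <- function(path) {
  lines <- readLines(path)
  og_line <- grep("^#\\s*outgroup\\s*=", lines, value = TRUE)
  if (!length(og_line))
    stop("clade table ", path, " lacks a '#outgroup=<label>' header line")
  outgroup <- trimws(sub("^#\\s*outgroup\\s*=", "", og_line[1L]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "\t")
  if (any(lengths(parts) < 2L)) stop("malformed row in clade table ", path)
  clade_assignment(vapply(parts, `[[`, "", 1L),
                   vapply(parts, `[[`, "", 2L), outgroup)
}

#' Packaged palaeognath clade assignment
#'
#' The 15-species assignment used throughout the examples: emu/cassowary (E,
#' 2 species), kiwi (K, 4), rhea (R, 2), ostrich (S, 1), tinamou incl. moa
#' (T, 5), and chicken as the sole outgroup clade (O).
#'
#' @return a \code{\link{clade_assignment}}.
#' @export
palaeognath_clades <- function() {
  load_clade_assignment(system.file("extdata", "palaeognath_clades.tsv",
                                    package = "quartetpol", mustWork = TRUE))
}

#' Check that a clade assignment covers a supermatrix
#'
#' @param m a \code{\link{supermatrix}}.
#' @param ca a \code{\link{clade_assignment}}.
#' @return invisibly \code{TRUE}; errors if any aligned taxon is unassigned.
#' @export
validate_assignment <- function(m, ca) {
  missing <- setdiff(m$taxa, names(ca$clade_of))
  if (length(missing))
    stop("taxa in alignment but not assigned to a clade: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
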