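#' Construct a supermatrix object
#'
#' A supermatrix is a concatenated multiple-sequence alignment stored as a
#' taxon-by-site character matrix over the DNA alphabet (A, C, G, T), the gap
#' character \code{"-"} and IUPAC ambiguity codes.  Optional locus boundaries
#' record which column ranges came from which input alignment.
#'
#' @param seq character matrix (taxa in rows, aligned sites in columns) with
#'   row names giving unique taxon labels.
#' @param loci optional data.frame with columns \code{name}, \code{start},
#'   \code{end} giving 0-based half-open column ranges, in order,
#'   non-overlapping.
#' @return an object of class \code{"supermatrix"}.
#' @export
supermatrix <- function(seq, loci = NULL) {
  stopifnot(is.matrix(seq), is.character(seq))
  taxa <- rownames(seq)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("sequence matrix must have taxon row names")
  dup <- taxa[duplicated(taxa)]
  if (length(dup))
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  seq <- toupper(seq)
  names(seq) <- NULL
  dimnames(seq) <- list(taxa, NULL)
  known <- c(DNA_BASES, "-", IUPAC_AMBIG)
  bad <- !(seq %in% known)
  if (any(bad)) {
    warning(sum(bad), " unknown character(s) mapped to fully-ambiguous 'N'")
    seq[bad] <- "N"
  }
  if (!is.null(loci)) {
    stopifnot(all(c("name", "start", "end") %in% names(loci)))
    loci <- loci[order(loci$start), , drop = FALSE]
    if (any(loci$start < 0) || any(loci$end > ncol(seq)) ||
        any(loci$end <= loci$start))
      stop("invalid locus ranges")
    if (nrow(loci) > 1L && any(loci$start[-1L] < loci$end[-nrow(loci)]))
      stop("overlapping locus ranges")
    rownames(loci) <- NULL
  }
  structure(list(taxa = taxa, seq = seq, loci = loci),
            class = "supermatrix")
}

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "?")

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$taxa), "taxa x", ncol(x$seq), "sites")
  if (!is.null(x$loci)) cat(",", nrow(x$loci), "loci")
  cat("\n")
  invisible(x)
}

#' @export
dim.supermatrix <- function(x) dim(x$seq)

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' Characters are uppercased; anything outside the DNA alphabet, gap and
#' IUPAC ambiguity codes is mapped to \code{"N"} with a warning.  Duplicate
#' taxon labels and unequal sequence lengths are hard errors.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed dialect:
#'   whitespace-delimited names of any length, sequential).
#' @return a \code{\link{supermatrix}}.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    # seqinr preserves characters verbatim, so the unknown-character
    # contract (map to N with a warning) can be enforced here
    dna <- seqinr::read.fasta(path, seqtype = "DNA",
                              forceDNAtolower = FALSE)
    labs <- names(dna)
    dup <- labs[duplicated(labs)]
    if (length(dup))
      stop("duplicate taxon label(s) in ", path, ": ",
           paste(unique(dup), collapse = ", "))
    lens <- lengths(dna)
    if (length(unique(lens)) > 1L) {
      off <- labs[lens != lens[1L]][1L]
      stop("unequal sequence lengths in ", path, " (e.g. taxon '", off, "')")
    }
    seq <- toupper(do.call(rbind, lapply(dna, as.character)))
    rownames(seq) <- labs
  } else {
    seq <- read_relaxed_phylip(path)
  }
  supermatrix(seq)
}

# Relaxed PHYLIP: header "ntax nsite"; then one record per taxon, name and
# sequence whitespace-separated, sequence possibly wrapped over lines.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) < 2L || anyNA(hdr))
    stop("malformed PHYLIP header in ", path)
  ntax <- hdr[1L]; nsite <- hdr[2L]
  toks <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- character(ntax); seqs <- character(ntax)
  i <- 0L
  for (tk in toks) {
    if (i < ntax && (i == 0L || nchar(seqs[i]) >= nsite)) {
      i <- i + 1L
      labs[i] <- tk[1L]
      seqs[i] <- paste(tk[-1L], collapse = "")
    } else {
      seqs[i] <- paste0(seqs[i], paste(tk, collapse = ""))
    }
  }
  if (i < ntax) stop("PHYLIP file ", path, " has fewer taxa than header claims")
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop("duplicate taxon label(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  n <- nchar(seqs)
  if (any(n != nsite)) {
    off <- labs[n != nsite][1L]
    stop("unequal sequence lengths in ", path, " (e.g. taxon '", off, "')")
  }
  seq <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(seq) <- labs
  seq
}

#' Write a supermatrix to FASTA or relaxed PHYLIP
#'
#' @param m a \code{\link{supermatrix}}.
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @export
write_alignment <- function(m, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  sq <- apply(m$seq, 1L, paste, collapse = "")
  if (format == "fasta") {
    out <- character(2L * length(sq))
    out[c(TRUE, FALSE)] <- paste0(">", names(sq))
    out[c(FALSE, TRUE)] <- sq
  } else {
    out <- c(paste(length(sq), ncol(m$seq)), paste(names(sq), sq))
  }
  writeLines(out, path)
  invisible(path)
}

#' Concatenate locus alignments into a supermatrix
#'
#' Taxon sets may differ between loci; a taxon missing from a locus is padded
#' with gaps across that locus' columns.  Locus boundaries are recorded in
#' input order as 0-based half-open column ranges.
#'
#' @param x list of \code{\link{supermatrix}} objects, or a character vector
#'   of file paths.
#' @param format passed to \code{\link{read_alignment}} when \code{x} is a
#'   vector of paths.
#' @return a \code{\link{supermatrix}} with locus boundaries.
#' @export
concatenate_loci <- function(x, format = "fasta") {
  if (is.character(x)) {
    nms <- sub("\\.[^.]*$", "", basename(x))
    x <- lapply(x, read_alignment, format = format)
    names(x) <- nms
  }
  if (!length(x)) stop("no loci to concatenate")
  stopifnot(all(vapply(x, inherits, logical(1), "supermatrix")))
  nms <- names(x)
  if (is.null(nms)) nms <- paste0("locus", seq_along(x))
  taxa <- unique(unlist(lapply(x, `[[`, "taxa")))
  widths <- vapply(x, function(m) ncol(m$seq), integer(1))
  end <- cumsum(widths)
  start <- end - widths
  seq <- matrix("-", length(taxa), sum(widths), dimnames = list(taxa, NULL))
  for (i in seq_along(x)) {
    m <- x[[i]]
    seq[m$taxa, (start[i] + 1L):end[i]] <- m$seq
  }
  supermatrix(seq, loci = data.frame(name = nms, start = start, end = end))
}

#' Summarize alignment composition
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' nucleotide states each occur in two or more taxa.  Gap percentage is
#' computed over all characters; ambiguity codes are not counted as gaps.
#'
#' @param m a \code{\link{supermatrix}}.
#' @return a list of class \code{"alignment_summary"} with \code{n_sites},
#'   \code{pct_indels}, \code{n_parsimony_informative},
#'   \code{pct_parsimony_informative}.
#' @export
summarize_alignment <- function(m) {
  if (!ncol(m$seq)) stop("empty alignment")
  counts <- vapply(DNA_BASES, function(b) colSums(m$seq == b),
                   numeric(ncol(m$seq)))
  if (ncol(m$seq) == 1L) counts <- matrix(counts, nrow = 1L)
  inf <- rowSums(counts >= 2L) >= 2L
  out <- list(
    n_sites = ncol(m$seq),
    pct_indels = 100 * sum(m$seq == "-") / length(m$seq),
    n_parsimony_informative = sum(inf),
    pct_parsimony_informative = 100 * mean(inf))
  class(out) <- "alignment_summary"
  out
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("sites: %d | indels: %.2f%% | parsimony-informative: %d (%.2f%%)\n",
              x$n_sites, x$pct_indels, x$n_parsimony_informative,
              x$pct_parsimony_informative))
  invisible(x)
}
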