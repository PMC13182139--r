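#' Score a species-quartet from apomorphic and convergent counts
#'
#' The raw support for topology x is S(x) = Na(x) - Nc(x): the synapomorphic
#' site count minus the convergent count expected under the rival fitted
#' models.  Negative raw supports are clamped to zero, then supports are
#' normalized to sum to one, giving a score between 0 (no support) and 1
#' (full support) per topology.  The support distance SD12 is the gap
#' between the best and second-best normalized scores; RISK is
#' Nc(best)/Na(best), with an infinite sentinel when Na(best) = 0.  If no
#' topology has positive raw support the quartet is uninformative.  Exact
#' ties for the best topology are broken by canonical topology order
#' (x1 < x2 < x3) and flagged.
#'
#' @param pc a \code{\link{count_polarized_patterns}} result.
#' @param nc named numeric of three expected convergent counts (x1, x2, x3).
#' @return one-row data.frame: Na/Nc/s per topology, \code{best},
#'   \code{second}, \code{sd12}, \code{risk}, \code{tie}, \code{status}.
#' @export
score_quartet <- function(pc, nc) {
  topo <- c("x1", "x2", "x3")
  Na <- as.numeric(pc$Na[topo])
  Nc <- as.numeric(nc[topo])
  S <- pmax(Na - Nc, 0)
  if (sum(S) <= 0) {
    return(data.frame(
      Na1 = Na[1], Na2 = Na[2], Na3 = Na[3],
      Nc1 = Nc[1], Nc2 = Nc[2], Nc3 = Nc[3],
      s1 = NA_real_, s2 = NA_real_, s3 = NA_real_,
      best = NA_character_, second = NA_character_,
      sd12 = NA_real_, risk = NA_real_, tie = FALSE,
      status = "uninformative"))
  }
  s <- S / sum(S)
  ord <- order(-s, topo)  # canonical tie-break: x1 < x2 < x3
  best <- ord[1L]; second <- ord[2L]
  tie <- s[best] - s[second] < .Machine$double.eps * 4
  risk <- if (Na[best] > 0) Nc[best] / Na[best] else Inf
  data.frame(
    Na1 = Na[1], Na2 = Na[2], Na3 = Na[3],
    Nc1 = Nc[1], Nc2 = Nc[2], Nc3 = Nc[3],
    s1 = s[1], s2 = s[2], s3 = s[3],
    best = topo[best], second = topo[second],
    sd12 = s[best] - s[second], risk = risk, tie = tie,
    status = "scored")
}

#' RISK of a scored quartet
#'
#' Convergent-to-apomorphic signal ratio of the best-supported topology,
#' Nc(best)/Na(best).  Low values mean shared derived characters dominate;
#' values near or above one mean the apparent support is largely convergent
#' noise.  \code{Inf} (Na(best) = 0) always leads to rejection.
#'
#' @param score one-row data.frame from \code{\link{score_quartet}}.
#' @return nonnegative numeric (possibly \code{Inf}).
#' @export
compute_risk <- function(score) {
  if (is.na(score$best)) return(NA_real_)
  k <- match(score$best, c("x1", "x2", "x3"))
  na <- c(score$Na1, score$Na2, score$Na3)[k]
  nc <- c(score$Nc1, score$Nc2, score$Nc3)[k]
  if (na > 0) nc / na else Inf
}
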