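#' Optimize DIST and RISK thresholds for one clade-quartet
#'
#' Grid search over candidate thresholds taken at the deciles of the
#' observed support distances (SD12) and RISK values, plus the endpoints 0
#' and 1.  The objective balances decisiveness against data retention: the
#' margin between the best and second-best per-topology median supports
#' computed over the retained quartets, multiplied by the square root of the
#' retained fraction.  At least one quartet must remain; ties prefer the
#' larger retained set, then the smaller RISK threshold, then the smaller
#' DIST threshold.
#'
#' @param scores data.frame of scored quartets of one clade-quartet (rows
#'   from \code{\link{score_quartet}}).
#' @return one-row data.frame: \code{L_DIST}, \code{L_RISK},
#'   \code{provenance}; \code{NA} thresholds if no quartet is informative.
#' @export
optimize_thresholds <- function(scores) {
  inf <- scores[scores$status != "uninformative", , drop = FALSE]
  if (!nrow(inf))
    return(data.frame(L_DIST = NA_real_, L_RISK = NA_real_,
                      provenance = "empty"))
  qs <- seq(0, 1, by = 0.1)
  cand_d <- sort(unique(pmin(pmax(
    c(0, 1, stats::quantile(inf$sd12, qs, names = FALSE, type = 7)), 0), 1)))
  finite_r <- inf$risk[is.finite(inf$risk)]
  cand_r <- sort(unique(pmin(pmax(
    c(0, 1, if (length(finite_r))
      stats::quantile(finite_r, qs, names = FALSE, type = 7)), 0), 1)))
  best <- NULL
  for (lr in cand_r) for (ld in cand_d) {
    keep <- inf$sd12 >= ld & inf$risk <= lr
    n <- sum(keep)
    if (!n) next
    med <- vapply(c("s1", "s2", "s3"),
                  function(cl) stats::median(inf[[cl]][keep]), numeric(1))
    med <- sort(med, decreasing = TRUE)
    obj <- (med[1L] - med[2L]) * sqrt(n / nrow(inf))
    cand <- list(obj = obj, n = n, lr = lr, ld = ld)
    if (is.null(best) ||
        obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
         (n > best$n ||
          (n == best$n && (lr < best$lr ||
                           (lr == best$lr && ld < best$ld))))))
      best <- cand
  }
  # a RISK threshold that excludes nothing is reported as its canonical
  # representative 1 (the no-filtering threshold); the retained set is
  # unchanged, and clade-quartets dominated by convergent signal surface as
  # L_RISK = 1 exactly
  lr <- best$lr
  if (all(inf$risk[is.finite(inf$risk)] <= lr)) lr <- 1
  data.frame(L_DIST = best$ld, L_RISK = lr, provenance = "optimized")
}

#' Apply the DIST and RISK filters
#'
#' A quartet is retained only if it passes both filters: SD12 >= L_DIST and
#' RISK <= L_RISK (both bounds inclusive).  Rejected quartets are dropped
#' entirely -- the best topology is never replaced by the second-best.  For
#' reporting, DIST is checked first; the order does not affect the retained
#' set.
#'
#' @param scores data.frame of scored quartets with a \code{clade_quartet}
#'   column.
#' @param thresholds data.frame with \code{clade_quartet}, \code{L_DIST},
#'   \code{L_RISK} (one row per clade-quartet), or a single row applied to
#'   all.
#' @return \code{scores} with \code{status} set to \code{"retained"},
#'   \code{"rejected_dist"} or \code{"rejected_risk"} (uninformative rows
#'   unchanged).
#' @export
apply_filters <- function(scores, thresholds) {
  if (!"clade_quartet" %in% names(thresholds)) {
    thresholds <- data.frame(clade_quartet = unique(scores$clade_quartet),
                             L_DIST = thresholds$L_DIST,
                             L_RISK = thresholds$L_RISK)
  }
  i <- match(scores$clade_quartet, thresholds$clade_quartet)
  ld <- thresholds$L_DIST[i]
  lr <- thresholds$L_RISK[i]
  eligible <- scores$status != "uninformative" & !is.na(ld)
  st <- scores$status
  st[eligible] <- ifelse(
    scores$sd12[eligible] < ld[eligible], "rejected_dist",
    ifelse(scores$risk[eligible] > lr[eligible], "rejected_risk",
           "retained"))
  scores$status <- st
  scores
}

#' Per-species quartet rejection summary
#'
#' For every species and clade-quartet it participates in: the number of
#' scored (informative) quartets, the number rejected by either filter, and
#' the rejection percentage.  Species at or above 80 percent rejection are
#' flagged \code{"partial"}; fully rejected species are flagged
#' \code{"complete"}.
#'
#' @param scores filtered scores (see \code{\link{apply_filters}}) carrying
#'   species columns \code{a}, \code{b}, \code{c}, \code{o}.
#' @param per_clade_quartet if \code{TRUE}, one row per species and
#'   clade-quartet; otherwise one row per species over all quartets.
#' @return data.frame with \code{species}, optional \code{clade_quartet},
#'   \code{n_quartets}, \code{n_rejected}, \code{pct_rejected}, \code{flag}.
#' @export
rejection_summary <- function(scores, per_clade_quartet = FALSE) {
  inf <- scores[scores$status != "uninformative", , drop = FALSE]
  long <- do.call(rbind, lapply(c("a", "b", "c", "o"), function(col)
    data.frame(species = inf[[col]], clade_quartet = inf$clade_quartet,
               rejected = inf$status %in% c("rejected_dist", "rejected_risk"))))
  keys <- if (per_clade_quartet) c("species", "clade_quartet") else "species"
  agg <- stats::aggregate(long["rejected"], long[keys],
                          function(z) c(n = length(z), r = sum(z)))
  out <- data.frame(agg[keys],
                    n_quartets = agg$rejected[, "n"],
                    n_rejected = agg$rejected[, "r"])
  out$pct_rejected <- 100 * out$n_rejected / out$n_quartets
  out$flag <- ifelse(out$pct_rejected >= 100, "complete",
                     ifelse(out$pct_rejected >= 80, "partial", ""))
  out[order(-out$pct_rejected, out$species), , drop = FALSE]
}
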