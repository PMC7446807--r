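## Statistics: one-tailed Fisher enrichment of neighbor PFAM domains with
## Benjamini-Hochberg correction and pfam2go annotation, and TF-abundance
## scaling fits (power vs linear) with per-division model selection.

#' One-tailed (enrichment) Fisher exact test
#'
#' Upper-tail hypergeometric probability \eqn{P[X \ge a]} for the 2x2 table
#' \code{(a, b; c, d)} with fixed margins, where \code{a} counts foreground
#' items carrying the feature. Computed from the exact hypergeometric
#' distribution, so it is deterministic and matches exhaustive enumeration
#' over all tables with the same margins.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return p-value in (0, 1]; an all-zero table returns 1.
#' @examples
#' fisherOneTailed(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherOneTailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  if (sum(counts) == 0) return(1)
  ## X ~ Hypergeometric(white = a + b, black = c + d, drawn = a + c)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-controlling adjustment with monotonicity enforcement; the
#' input order is preserved in the output and a single p-value is returned
#' unchanged.
#'
#' @param p numeric vector of raw p-values, all in (0, 1].
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Neighbor-PFAM functional enrichment
#'
#' Tests each PFAM domain observed among a foreground gene set (typically
#' the divergent neighbors of one TF family) for over-representation
#' against a background gene set, using the one-tailed Fisher test with BH
#' correction, and annotates significant domains with their Gene Ontology
#' terms via a pfam2go mapping. The 2x2 table for a domain counts
#' foreground genes with/without it against the remaining background genes
#' with/without it, so cells always sum to the background size.
#'
#' @param foregroundIds character vector of foreground gene/protein ids;
#'   must be a subset of \code{backgroundIds}.
#' @param backgroundIds character vector of background ids (includes the
#'   foreground).
#' @param domains data.frame with columns \code{protein_id},
#'   \code{pfam_acc} annotating background members.
#' @param pfam2go optional data.frame from [parsePfam2Go()].
#' @param alpha FDR significance threshold (default 0.05).
#' @param familyPfam optional family label copied into every row.
#' @return data.frame with columns \code{family_pfam}, \code{neighbor_pfam},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{p_value}, \code{fdr},
#'   \code{significant}, \code{go_terms} (\code{;}-joined), ordered by
#'   p-value.
#' @export
enrichNeighborPfams <- function(foregroundIds, backgroundIds, domains,
                                pfam2go = NULL, alpha = 0.05,
                                familyPfam = NA_character_) {
  foregroundIds <- unique(foregroundIds)
  backgroundIds <- unique(backgroundIds)
  if (!all(foregroundIds %in% backgroundIds))
    stop("foreground genes must be a subset of the background")
  dom <- domains[domains$protein_id %in% backgroundIds, , drop = FALSE]
  dom$pfam_acc <- .stripVersion(dom$pfam_acc)
  dom <- unique(dom[, c("protein_id", "pfam_acc")])
  fgPfams <- sort(unique(dom$pfam_acc[dom$protein_id %in% foregroundIds]))
  nFg <- length(foregroundIds)
  nRest <- length(backgroundIds) - nFg
  rows <- lapply(fgPfams, function(pf) {
    carriers <- dom$protein_id[dom$pfam_acc == pf]
    a <- sum(foregroundIds %in% carriers)
    cc <- length(setdiff(carriers, foregroundIds))
    data.frame(family_pfam = familyPfam, neighbor_pfam = pf,
               a = a, b = nFg - a, c = cc, d = nRest - cc,
               p_value = fisherOneTailed(a, nFg - a, cc, nRest - cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(family_pfam = character(), neighbor_pfam = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric(), fdr = numeric(),
                      significant = logical(), go_terms = character(),
                      stringsAsFactors = FALSE))
  out$fdr <- bhAdjust(out$p_value)
  out$significant <- out$fdr <= alpha
  out$go_terms <- if (is.null(pfam2go)) NA_character_ else
    vapply(out$neighbor_pfam, function(pf) {
      g <- pfam2go[pfam2go$pfam_acc == pf, , drop = FALSE]
      if (!nrow(g)) return(NA_character_)
      paste(paste0(g$go_id, " (", g$go_term, ")"), collapse = "; ")
    }, character(1))
  out <- out[order(out$p_value, out$neighbor_pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit TF-abundance scaling models
#'
#' Fits both candidate models of TF count versus genome size (ORF count):
#' a power law \eqn{y = a x^b} by ordinary least squares on the log-log
#' scale, and a straight line \eqn{y = a + b x} by OLS on the raw scale.
#' \code{r2} and \code{pearson_r} are reported on each model's own fitting
#' scale. Points with zero TFs cannot enter the log-log fit and are
#' excluded from it with a warning.
#'
#' @param points data.frame with columns \code{n_orfs}, \code{n_tfs}
#'   (at least 3 points).
#' @return data.frame with rows \code{power} and \code{linear} and columns
#'   \code{model}, \code{a}, \code{b}, \code{r2}, \code{pearson_r},
#'   \code{n}. For the power row, \code{a} is the prefactor and \code{b}
#'   the exponent.
#' @export
fitScaling <- function(points) {
  x <- points$n_orfs
  y <- points$n_tfs
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(x <= 0)) stop("n_orfs must be positive")
  pos <- y > 0
  if (sum(pos) < 3L) stop("need at least 3 points with positive TF counts")
  if (any(!pos))
    warning(sum(!pos), " zero-TF point(s) excluded from the power fit")
  rsq <- function(fit, yy) 1 - sum(stats::resid(fit)^2) /
    sum((yy - mean(yy))^2)
  lf <- stats::lm(log(y[pos]) ~ log(x[pos]))
  powerRow <- data.frame(
    model = "power", a = exp(unname(stats::coef(lf)[1L])),
    b = unname(stats::coef(lf)[2L]),
    r2 = rsq(lf, log(y[pos])),
    pearson_r = stats::cor(log(x[pos]), log(y[pos])),
    n = sum(pos), stringsAsFactors = FALSE)
  ll <- stats::lm(y ~ x)
  linearRow <- data.frame(
    model = "linear", a = unname(stats::coef(ll)[1L]),
    b = unname(stats::coef(ll)[2L]),
    r2 = rsq(ll, y),
    pearson_r = stats::cor(x, y),
    n = length(x), stringsAsFactors = FALSE)
  rbind(powerRow, linearRow)
}

#' Select the better scaling model per taxonomic division
#'
#' Fits both models within each division of a census and picks the one
#' with the higher coefficient of determination on its own fitting scale;
#' when the two differ by less than \code{margin} the division is reported
#' as \code{"ambiguous"}. Divisions with fewer than \code{minGenomes}
#' genomes are skipped with a warning.
#'
#' @param census data.frame with columns \code{division}, \code{n_orfs},
#'   \code{n_tfs} (e.g. from [tfCensus()]).
#' @param minGenomes minimum genomes per division (default 10).
#' @param margin r-squared margin below which the call is ambiguous
#'   (default 0.01).
#' @return data.frame with columns \code{division}, \code{model},
#'   \code{r2_power}, \code{r2_linear}, \code{n}.
#' @export
selectModelPerDivision <- function(census, minGenomes = 10L, margin = 0.01) {
  divs <- unique(census$division[!is.na(census$division)])
  rows <- lapply(divs, function(dv) {
    sub <- census[!is.na(census$division) & census$division == dv, ,
                  drop = FALSE]
    if (nrow(sub) < minGenomes) {
      warning("division ", dv, " skipped: only ", nrow(sub), " genome(s)")
      return(NULL)
    }
    fits <- fitScaling(sub)
    r2p <- fits$r2[fits$model == "power"]
    r2l <- fits$r2[fits$model == "linear"]
    model <- if (abs(r2p - r2l) < margin) "ambiguous"
             else if (r2p > r2l) "power" else "linear"
    data.frame(division = dv, model = model, r2_power = r2p,
               r2_linear = r2l, n = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(division = character(), model = character(),
                      r2_power = numeric(), r2_linear = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
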