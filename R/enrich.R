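#' Hypergeometric over-representation analysis
#'
#' Tests each term for over-representation of the query genes within a
#' declared universe. With N universe genes, K in-universe term genes, n
#' in-universe query genes and an overlap of k, the p-value is the exact
#' hypergeometric upper tail P(X >= k); k = 0 gives p = 1 exactly. BH
#' adjustment runs over all tested terms; terms with no in-universe genes
#' are skipped. Results are sorted by p, then term name.
#'
#' @param query character vector of query gene symbols (for example an
#'   up- or down-regulated DE list, or a driver-gene list).
#' @param terms a \linkS4class{SignatureDB} of term gene sets.
#' @param universe character vector of universe gene symbols (conventionally
#'   all genes surviving QC in the cohort).
#' @param alpha significance level on the BH-adjusted q (default 0.05).
#' @return data.frame with columns \code{term}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{q}, \code{significant},
#'   \code{overlap} (comma-joined overlap genes).
#' @export
ora <- function(query, terms, universe, alpha = 0.05) {
  universe <- unique(universe)
  q <- intersect(query, universe)
  if (!length(q)) stop("empty query after universe intersection")
  N <- length(universe); n <- length(q)
  rows <- list()
  for (nm in names(terms)) {
    tg <- intersect(terms[[nm]], universe)
    K <- length(tg)
    if (K == 0) next
    ov <- intersect(q, tg)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(term = nm, k = k, n = n, K = K, N = N, p = p,
                             overlap = paste(sort(ov), collapse = ","))
  }
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      overlap = character()))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$term),
             c("term", "k", "n", "K", "N", "p", "q", "significant", "overlap")]
  rownames(out) <- NULL
  out
}
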