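#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes in a query of
#' size `n`, when `K` of the `M` universe genes carry the annotation:
#' `p = sum_{i = k}^{min(n, K)} C(K, i) C(M - K, n - i) / C(M, n)`.
#' The sum is evaluated in log space via `lchoose()` for numerical
#' stability at genome-scale counts.
#'
#' @param k Overlap count (query genes in the term).
#' @param n Query size.
#' @param K Term size.
#' @param M Universe size.
#' @return Upper-tail probability in \[0, 1\]; exactly 1 when `k = 0`.
#' @export
hypergeometric_tail <- function(k, n, K, M) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(M) == 1)
  if (k < 0 || n < 0 || K < 0 || K > M || n > M || k > min(n, K)) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), ",
         "K <= M, n <= M", call. = FALSE)
  }
  if (k == 0) return(1)
  i <- seq.int(k, min(n, K))
  log_terms <- lchoose(K, i) + lchoose(M - K, n - i) - lchoose(M, n)
  mx <- max(log_terms)
  p <- exp(mx) * sum(exp(log_terms - mx))
  min(p, 1)
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term for over-representation in the query via
#' the hypergeometric upper tail (one-sided Fisher test). The universe
#' defaults to the union of all annotated genes in the collection
#' (`universe_mode = "annotated-union"`); an explicit universe can be
#' attached to the collection instead. Query genes outside the universe
#' are dropped and counted. The EASE variant replaces the overlap `k`
#' with `k - 1`, a deliberately conservative score.
#'
#' @param query Character vector of normalized gene symbols.
#' @param annotations An `annotation_collection` from [read_gmt()] or
#'   [simulate_annotations()].
#' @param universe_mode `"annotated-union"` (default) or `"explicit"`
#'   (requires `annotations$universe`).
#' @param ease Use the EASE overlap `max(k - 1, 0)` in the tail
#'   (default `FALSE`).
#' @param adjust Multiple-testing adjustment for the `p_adj` column:
#'   `"bh"` (Benjamini-Hochberg) or `"none"`.
#' @return Data.frame with one row per term overlapping the query
#'   (`k >= 1`): `term_id`, `description`, `k`, `n`, `K`, `M`,
#'   `enrichment_ratio` (`(k/n) / (K/M)`), `p_raw`, `p_adj`; sorted by
#'   `p_raw` ascending, ties by term id. Attribute `n_dropped` counts
#'   query genes outside the universe.
#' @export
enrich_gene_set <- function(query, annotations,
                            universe_mode = c("annotated-union", "explicit"),
                            ease = FALSE, adjust = c("bh", "none")) {
  stopifnot(inherits(annotations, "annotation_collection"))
  universe_mode <- match.arg(universe_mode)
  adjust <- match.arg(adjust)
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query", call. = FALSE)
  universe <- if (universe_mode == "explicit") {
    if (is.null(annotations$universe)) {
      stop("universe_mode = 'explicit' but the collection has no universe",
           call. = FALSE)
    }
    unique(annotations$universe)
  } else {
    unique(unlist(annotations$terms, use.names = FALSE))
  }
  eff_query <- intersect(query, universe)
  n_dropped <- length(query) - length(eff_query)
  if (length(eff_query) == 0) {
    stop("no query gene lies in the universe", call. = FALSE)
  }
  M <- length(universe)
  n <- length(eff_query)
  rows <- lapply(names(annotations$terms), function(id) {
    genes <- intersect(annotations$terms[[id]], universe)
    k <- length(intersect(eff_query, genes))
    if (k == 0) return(NULL)
    K <- length(genes)
    k_test <- if (ease) max(k - 1, 0) else k
    data.frame(term_id = id,
               description = annotations$descriptions[[id]],
               k = k, n = n, K = K, M = M,
               enrichment_ratio = (k / n) / (K / M),
               p_raw = hypergeometric_tail(k_test, n, K, M),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame(term_id = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      M = integer(0), enrichment_ratio = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_raw,
                              method = if (adjust == "bh") "bh" else "none")
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment (via [stats::p.adjust()]) or the
#' identity. Values are returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"none"`.
#' @return Numeric vector, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (method == "none") return(p)
  stats::p.adjust(p, method = "BH")
}

#' Select significant top terms
#'
#' Keeps terms with raw p strictly below `alpha`, then truncates to the
#' `top_k` smallest p-values (ties broken by term id) - the usual
#' "top 10 GO terms / top 20 pathways" reporting rule.
#'
#' @param results Data.frame from [enrich_gene_set()].
#' @param alpha Significance level, strict `<` (default 0.05).
#' @param top_k Maximum number of terms returned (default 10).
#' @return The selected rows, sorted by `p_raw` then term id.
#' @export
select_top_terms <- function(results, alpha = 0.05, top_k = 10L) {
  stopifnot(is.data.frame(results),
            all(c("term_id", "p_raw") %in% names(results)))
  sig <- results[results$p_raw < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_raw, sig$term_id), , drop = FALSE]
  out <- utils::head(sig, top_k)
  rownames(out) <- NULL
  out
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Relative fold change of a target gene in treated vs control samples,
#' each normalized to a reference gene:
#' `dCt = Ct_target - Ct_ref` per condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^-ddCt`.
#' When replicate Ct values are supplied, per-group means are taken
#' before differencing.
#'
#' @param ct_target_treated,ct_ref_treated Ct values (cycles) of target
#'   and reference gene in the treated condition.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return Fold change (dimensionless); 1 means no change, 0.5 one
#'   doubling less, 4 two doublings more.
#' @examples
#' ddct_fold_change(25, 18, 24, 18)  # 0.5: one cycle later than control
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated,
            ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  d_treated <- mean(ct_target_treated) - mean(ct_ref_treated)
  d_control <- mean(ct_target_control) - mean(ct_ref_control)
  2^-(d_treated - d_control)
}
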