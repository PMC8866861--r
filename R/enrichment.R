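#' Classic per-term Fisher (hypergeometric) enrichment test
#'
#' For each term with at least one annotated gene, tests over-representation
#' of the term among the study genes by the upper-tail hypergeometric
#' probability `P(X >= k | N, K, n)`, where N is the annotated universe,
#' K the term's propagated background count, n the study-set size and k
#' the study genes annotated to the term. The expected count is `n * K / N`.
#' Study genes outside the annotated universe are dropped (count reported).
#'
#' @param study character vector of study gene ids.
#' @param annot an [propagate()]d `annotation_map`.
#' @return data.frame per term: term, K, k, expected, p_classic; attribute
#'   `dropped` = number of study genes outside the universe, `n` = study
#'   size used.
#' @export
classic_fisher <- function(study, annot) {
  universe <- names(annot$propagated)
  dropped <- sum(!study %in% universe)
  study <- intersect(study, universe)
  n <- length(study); N <- annot$N
  terms <- names(annot$term_genes)
  K <- lengths(annot$term_genes)
  k <- vapply(annot$term_genes, function(g) sum(study %in% g), integer(1))
  res <- data.frame(term = terms, K = as.integer(K), k = as.integer(k),
                    expected = n * K / N,
                    p_classic = hyper_upper_tail(k, N, K, n),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dropped") <- dropped
  attr(res, "n") <- n
  res
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Exact summation via [stats::phyper()]; `k = 0` gives 1 by convention.
#' @param k observed count(s).
#' @param N universe size; `K` annotated in background; `n` draws.
#' @return numeric vector of tail probabilities.
#' @export
hyper_upper_tail <- function(k, N, K, n) {
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Elim-style DAG-decorrelated enrichment p-values
#'
#' Processes terms in order of decreasing depth (children strictly before
#' parents; ties broken by lexicographic term id). Each term's Fisher test
#' uses only its annotated genes not yet eliminated at that term; if the
#' resulting p-value falls below `cutoff`, the term's (remaining) annotated
#' genes are marked eliminated for all of its ancestors. This penalizes
#' general terms whose apparent signal is owned by a more specific
#' descendant. Leaves always keep their classic p-value, and with
#' `cutoff -> 0` nothing is eliminated and every p equals classic.
#'
#' @param graph an [ontology_graph()].
#' @param annot a propagated `annotation_map`.
#' @param study character vector of study gene ids.
#' @param cutoff elimination threshold in (0, 1), default 0.01.
#' @return named numeric vector of decorrelated p-values per term (terms
#'   with all genes eliminated get p = 1).
#' @export
elim_enrichment <- function(graph, annot, study, cutoff = 0.01) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("elim cutoff must lie in (0, 1)", call. = FALSE)
  study <- intersect(study, names(annot$propagated))
  n <- length(study); N <- annot$N
  terms <- names(annot$term_genes)
  depth <- graph$depth[terms]
  ord <- terms[order(-depth, terms)]
  eliminated <- lapply(setNames(vector("list", length(terms)), terms),
                       function(x) character(0))
  p_out <- setNames(rep(1, length(terms)), terms)
  for (t in ord) {
    genes <- setdiff(annot$term_genes[[t]], eliminated[[t]])
    K <- length(genes)
    if (K == 0L) { p_out[t] <- 1; next }
    k <- sum(study %in% genes)
    p_out[t] <- hyper_upper_tail(k, N, K, n)
    if (p_out[t] < cutoff) {
      for (a in intersect(term_ancestors(graph, t), terms))
        eliminated[[a]] <- union(eliminated[[a]], genes)
    }
  }
  p_out
}

#' Full enrichment report with the >`min_significant` reporting filter
#'
#' Runs the classic and elim tests and keeps terms represented by strictly
#' more than `min_significant` study genes (k > 10 by default), sorted by
#' decorrelated p-value.
#'
#' @param graph an [ontology_graph()].
#' @param annot a propagated `annotation_map`.
#' @param study study gene set.
#' @param cutoff elim cutoff (default 0.01).
#' @param min_significant strict lower bound on k for reporting
#'   (default 10).
#' @return data.frame: term, name, K, k, expected, p_classic, p_elim;
#'   attributes `n`, `dropped`.
#' @export
enrichment_report <- function(graph, annot, study, cutoff = 0.01,
                              min_significant = 10) {
  rows <- classic_fisher(study, annot)
  pe <- elim_enrichment(graph, annot, study, cutoff = cutoff)
  rows$p_elim <- unname(pe[rows$term])
  rows$name <- graph$terms$name[match(rows$term, graph$terms$id)]
  keep <- rows$k > min_significant
  out <- rows[keep, c("term", "name", "K", "k", "expected",
                      "p_classic", "p_elim")]
  out <- out[order(out$p_elim, out$p_classic, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- attr(rows, "n")
  attr(out, "dropped") <- attr(rows, "dropped")
  out
}

#' Infer the annotation-universe size implied by an (n, K, expected) triple
#'
#' Inverts the expected-count identity `expected = n * K / N`, used to
#' check the internal consistency of printed enrichment tables.
#' @param n study-set size; `K` background count; `expected` printed
#'   expected count.
#' @return implied universe size N.
#' @export
infer_universe <- function(n, K, expected) n * K / expected
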