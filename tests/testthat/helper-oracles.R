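# Independent brute-force oracles. These deliberately recompute statistics
# through a different path than the package (pairwise U counting instead of
# rank sums; log-binomial pmf summation instead of phyper).

# exact two-sided Mann-Whitney p by full labeling enumeration of U
brute_mw_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  u_of <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(x), n1)
  us <- apply(combos, 2, function(idx) u_of(x[idx], x[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# upper-tail hypergeometric by direct pmf summation
brute_hyper_upper <- function(k, N, K, n) {
  if (k > min(K, n)) return(0)
  x <- k:min(K, n)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# smallest usable design: 1 control cond + 1 dose per arm
tiny_design <- function(reps = 2, ctrl = 2)
  study_design(nacl_doses = 50, sorbitol_doses = 100,
               replicates = reps, control_replicates = ctrl)

# raw expr_set from a bare matrix, inventing gene/sample names as needed
as_raw_es <- function(m, design) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- design$samples$sample
  expr_set(m, design, "raw")
}

# crafted 3-term chain root -> P -> C where P is annotated only through C
elim_fixture <- function(n_genes = 50, n_child = 10) {
  graph <- ontology_graph(
    terms = data.frame(id = c("R", "P", "C"),
                       name = c("root", "parent", "child"),
                       namespace = "biological_process"),
    edges = data.frame(child = c("P", "C"), parent = c("R", "P"),
                       relation = "is_a"))
  genes <- sprintf("g%02d", seq_len(n_genes))
  ann <- rbind(
    data.frame(gene = genes[seq_len(n_child)], term = "C"),
    data.frame(gene = genes[(n_child + 1):n_genes], term = "R"))
  list(graph = graph, annot = propagate(graph, ann),
       study = genes[seq_len(n_child)], genes = genes)
}

# construct a minimal differential_result for set-algebra tests
fake_result <- function(genes, sig, dir) {
  structure(data.frame(gene = genes, U = 0, p = 1, padj = 1,
                       significant = sig, direction = dir,
                       max_abs_log2fc = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("differential_result", "data.frame"))
}
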