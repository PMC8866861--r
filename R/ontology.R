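#' Ontology DAG container
#'
#' Directed acyclic graph of ontology terms with child-to-parent edges of
#' kind `is_a` or `part_of`. Validates acyclicity and (after namespace
#' restriction) a single root from which every term is reachable.
#'
#' @param terms data.frame with columns id, name, namespace.
#' @param edges data.frame with columns child, parent, relation.
#' @return object of class `ontology_graph`: list with `terms`, `edges`,
#'   `parents` (named list id -> parent ids), `root`, `depth` (named
#'   integer, longest path to root).
#' @export
ontology_graph <- function(terms, edges) {
  if (anyDuplicated(terms$id)) stop("duplicate term ids", call. = FALSE)
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$child, edges$parent), terms$id)
    if (length(unknown))
      stop("edges reference unknown terms: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  parents <- lapply(parents, unique)

  roots <- terms$id[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ", length(roots),
         call. = FALSE)

  depth <- ontology_depths(terms$id, parents, roots)
  if (anyNA(depth))
    stop("malformed ontology: cycle detected or term unreachable from root",
         call. = FALSE)
  structure(list(terms = terms, edges = edges, parents = parents,
                 root = roots, depth = depth), class = "ontology_graph")
}

# longest-path-to-root depths by Kahn-style topological relaxation;
# NA for cyclic/unreachable terms
ontology_depths <- function(ids, parents, root) {
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  depth[root] <- 0L
  remaining <- setdiff(ids, root)
  repeat {
    progressed <- FALSE
    keep <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      pd <- depth[parents[[remaining[k]]]]
      if (!anyNA(pd)) {
        depth[remaining[k]] <- max(pd) + 1L
        progressed <- TRUE
      } else keep[k] <- TRUE
    }
    remaining <- remaining[keep]
    if (!length(remaining) || !progressed) break
  }
  depth
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges),
      "edges, max depth", max(x$depth), "\n")
  invisible(x)
}

#' All ancestors of a term (excluding the term itself)
#' @param graph an [ontology_graph()].
#' @param id term id.
#' @return character vector of ancestor ids.
#' @export
term_ancestors <- function(graph, id) {
  seen <- character(0)
  frontier <- graph$parents[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(graph$parents[new], use.names = FALSE))
  }
  seen
}

#' Parse an OBO 1.2-dialect ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, relationship:
#' part_of, is_obsolete), drops obsolete terms, restricts to one namespace
#' and validates the DAG. Edges to terms outside the retained namespace are
#' dropped.
#'
#' @param path path to an OBO file.
#' @param namespace namespace to retain (default `"biological_process"`).
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]\\s*$", lines)
  if (!length(starts)) stop("no [Term] stanzas found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (s in seq_along(starts)) {
    chunk <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    field <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), chunk, value = TRUE))
      sub("\\s*(!.*)?$", "", v)  # strip trailing comments
    }
    id <- field("id")
    if (!length(id)) stop("parse error: [Term] stanza without id",
                          call. = FALSE)
    if (any(tolower(field("is_obsolete")) == "true")) next
    ns <- field("namespace")
    ns <- if (length(ns)) ns[1] else namespace
    if (!identical(ns, namespace)) next
    nm <- field("name")
    terms[[length(terms) + 1L]] <- data.frame(
      id = id[1], name = if (length(nm)) nm[1] else id[1],
      namespace = ns, stringsAsFactors = FALSE)
    isa <- field("is_a")
    rel <- field("relationship")
    po <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    if (length(isa) || length(po))
      edges[[length(edges) + 1L]] <- data.frame(
        child = id[1], parent = c(isa, po),
        relation = rep(c("is_a", "part_of"), c(length(isa), length(po))),
        stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(0), parent = character(0),
               relation = character(0))
  edges <- edges[edges$parent %in% terms$id, , drop = FALSE]
  ontology_graph(terms, edges)
}

#' Write an ontology graph as an OBO file
#' @param graph an [ontology_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 paste0("namespace: ", graph$terms$namespace[i])), con)
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' True-path propagation of direct annotations
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term (via `is_a` and `part_of`). Returns the propagated map and the
#' annotated-universe size N (genes with at least one propagated
#' annotation).
#'
#' @param graph an [ontology_graph()].
#' @param annotations data.frame with columns gene, term (direct,
#'   pre-propagation annotations).
#' @param unknown what to do with annotation rows whose term is absent from
#'   the graph: `"skip"` (drop with a warning) or `"error"`.
#' @return object of class `annotation_map`: list with `direct` and
#'   `propagated` (named list gene -> term ids), `term_genes` (named list
#'   term -> gene ids, propagated), `N`.
#' @export
propagate <- function(graph, annotations, unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  bad <- !annotations$term %in% graph$terms$id
  if (any(bad)) {
    msg <- paste0(sum(bad), " annotation rows reference unknown terms")
    if (unknown == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    annotations <- annotations[!bad, , drop = FALSE]
  }
  anc <- lapply(setNames(graph$terms$id, graph$terms$id),
                function(t) c(t, term_ancestors(graph, t)))
  direct <- lapply(split(annotations$term, annotations$gene), unique)
  propagated <- lapply(direct, function(tt)
    unique(unlist(anc[tt], use.names = FALSE)))
  pairs_gene <- rep(names(propagated), lengths(propagated))
  pairs_term <- unlist(propagated, use.names = FALSE)
  term_genes <- lapply(split(pairs_gene, pairs_term), unique)
  structure(list(direct = direct, propagated = propagated,
                 term_genes = term_genes, N = length(propagated)),
            class = "annotation_map")
}

#' Write / read a two-column gene-to-term annotation TSV
#' @param annotations data.frame gene/term.
#' @param path file path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
}
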