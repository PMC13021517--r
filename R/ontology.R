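#' Construct a cell-type ontology DAG
#'
#' Builds the structured label space used throughout the package: a directed
#' acyclic graph whose nodes are cell-type terms and whose edges are
#' child -> parent `is_a` (subtype) relations. Node order is fixed at
#' construction (lexicographic by node identifier) so that index `i` refers
#' to the same class in every downstream matrix and vector.
#'
#' @param nodes character vector of unique node identifiers (e.g. ontology
#'   term IDs).
#' @param edges two-column object (`child`, `parent`) of directed `is_a`
#'   edges; may have zero rows.
#' @param display_names optional named character vector of human-readable
#'   names, indexed by node identifier.
#' @return An object of class `ontology_dag` with components `nodes`
#'   (sorted identifiers), `edges` (data.frame with columns `child`,
#'   `parent`) and `display_names`.
#' @examples
#' dag <- ontology_dag(
#'   nodes = c("T_cell", "CD4_T_cell", "lymphocyte"),
#'   edges = data.frame(child = c("T_cell", "CD4_T_cell"),
#'                      parent = c("lymphocyte", "T_cell"))
#' )
#' n_nodes(dag)
#' @export
ontology_dag <- function(nodes, edges = NULL, display_names = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (length(nodes) == 0L) stop("ontology must contain at least one node")
  nodes <- sort(nodes, method = "radix")

  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges[[1]]),
                        parent = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
    dangling <- setdiff(unique(c(edges$child, edges$parent)), nodes)
    if (length(dangling) > 0L) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(dangling, collapse = ", "))
    }
    if (any(edges$child == edges$parent)) {
      stop("self-loop edge(s) on: ",
           paste(unique(edges$child[edges$child == edges$parent]),
                 collapse = ", "))
    }
    edges <- unique(edges)
    edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
    rownames(edges) <- NULL
  }

  dag <- structure(
    list(nodes = nodes, edges = edges, display_names = display_names),
    class = "ontology_dag"
  )
  cyc <- .find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  tax <- classify_nodes(x)
  cat(sprintf("ontology_dag: %d nodes, %d is_a edges (%d leaves, %d internal, %d isolated)\n",
              length(x$nodes), nrow(x$edges), sum(tax$is_leaf),
              sum(tax$is_internal), sum(tax$is_isolated)))
  invisible(x)
}

#' Number of classes in an ontology
#' @param dag an `ontology_dag`.
#' @return integer count of nodes.
#' @export
n_nodes <- function(dag) length(dag$nodes)

# depth-first search for a directed cycle over child->parent edges;
# returns the node sequence of one cycle, or NULL if acyclic
.find_cycle <- function(dag) {
  nodes <- dag$nodes
  adj <- split(dag$edges$parent, factor(dag$edges$child, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  parent_of <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, idx = 0L))
    state[[start]] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (top$idx < length(nbrs)) {
        stack[[length(stack)]]$idx <- top$idx + 1L
        nxt <- nbrs[[top$idx + 1L]]
        if (state[[nxt]] == 1L) {
          cyc <- nxt
          cur <- top$node
          while (!identical(cur, nxt)) {
            cyc <- c(cur, cyc)
            cur <- parent_of[[cur]]
          }
          return(c(nxt, cyc))
        }
        if (state[[nxt]] == 0L) {
          state[[nxt]] <- 1L
          parent_of[[nxt]] <- top$node
          stack[[length(stack) + 1L]] <- list(node = nxt, idx = 0L)
        }
      } else {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

.as_igraph <- function(dag) {
  g <- igraph::make_empty_graph(n = length(dag$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = dag$nodes)
  if (nrow(dag$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(dag$edges$child, dag$edges$parent))
  }
  g
}

#' Load an ontology from a file
#'
#' Reads either a tab-separated edge list (`child<TAB>parent`, `#` comments
#' allowed, optionally a third column ignored) or an OBO-format subset.
#' Only `[Term]` stanzas with `id`, `name` and `is_a` lines are interpreted
#' in OBO input; any other relation (e.g. `part_of` in a `relationship`
#' line) is ignored with a warning, because only the `is_a` subtype
#' relation defines the label hierarchy.
#'
#' @param path path to the ontology file.
#' @param format one of `"auto"` (default; sniffs for an OBO `[Term]`
#'   stanza), `"edgelist"` or `"obo"`.
#' @return an [ontology_dag()].
#' @export
load_ontology <- function(path, format = c("auto", "edgelist", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\[Term\\]\\s*$", lines))) "obo" else "edgelist"
  }
  if (format == "obo") .parse_obo(lines) else .parse_edgelist(lines)
}

.parse_edgelist <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("edge list is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  # single isolated nodes may be declared as one-column rows
  singletons <- unlist(lapply(parts[bad], `[[`, 1L))
  pairs <- parts[!bad]
  child <- vapply(pairs, `[[`, character(1), 1L)
  parent <- vapply(pairs, `[[`, character(1), 2L)
  nodes <- unique(c(child, parent, singletons))
  ontology_dag(nodes, data.frame(child = child, parent = parent))
}

.parse_obo <- function(lines) {
  term_starts <- grep("^\\[", lines)
  if (length(term_starts) == 0L) stop("no stanzas found in OBO input")
  stanza_type <- sub("^\\[(.*)\\]\\s*$", "\\1", lines[term_starts])
  bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(0); names_v <- character(0)
  child <- character(0); parent <- character(0)
  skipped <- character(0)
  for (k in seq_along(term_starts)) {
    body <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    if (stanza_type[k] != "Term") {
      skipped <- c(skipped, stanza_type[k])
      next
    }
    id_line <- grep("^id:", body, value = TRUE)
    if (length(id_line) == 0L) stop("OBO [Term] stanza without an id line")
    id <- trimws(sub("^id:", "", id_line[1]))
    ids <- c(ids, id)
    nm <- grep("^name:", body, value = TRUE)
    if (length(nm) > 0L) {
      names_v[id] <- trimws(sub("^name:", "", nm[1]))
    }
    isa <- grep("^is_a:", body, value = TRUE)
    for (l in isa) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      child <- c(child, id)
      parent <- c(parent, target)
    }
    rel <- grep("^relationship:", body, value = TRUE)
    if (length(rel) > 0L) {
      skipped <- c(skipped, sub("^relationship:\\s*(\\S+).*$", "\\1", rel))
    }
  }
  if (length(skipped) > 0L) {
    warning("ignored non-is_a OBO content: ",
            paste(unique(skipped), collapse = ", "))
  }
  missing <- setdiff(parent, ids)
  if (length(missing) > 0L) {
    stop("is_a target(s) without a [Term] stanza: ",
         paste(missing, collapse = ", "))
  }
  ontology_dag(ids, data.frame(child = child, parent = parent),
               display_names = if (length(names_v)) names_v else NULL)
}

#' Write an ontology as an edge-list TSV
#'
#' Isolated nodes (no edges) are written as single-column rows so the node
#' set round-trips through [load_ontology()].
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology_edgelist <- function(dag, path) {
  rows <- character(0)
  if (nrow(dag$edges) > 0L) {
    rows <- paste(dag$edges$child, dag$edges$parent, sep = "\t")
  }
  touched <- unique(c(dag$edges$child, dag$edges$parent))
  rows <- c(rows, setdiff(dag$nodes, touched))
  writeLines(rows, path)
  invisible(path)
}

#' Reachability (partial-order) matrix of an ontology
#'
#' Returns the C x C binary matrix `R` with `R[i, j] = 1` iff class `j` is
#' reachable from class `i`, i.e. `j` equals `i` or `j` is a descendant
#' (subtype) of `i`. Since stored edges run child -> parent, reachability is
#' the transitive closure of the *inverted* adjacency, with the diagonal
#' forced to 1 (reflexivity). Each descendant contributes a single entry no
#' matter how many paths connect it, so multi-parent terms are never double
#' counted when probability mass is aggregated.
#'
#' The result is a partial order: reflexive, antisymmetric and transitive.
#'
#' @param dag an `ontology_dag`.
#' @return a dense 0/1 integer matrix with dimnames equal to the node order.
#' @export
reachability <- function(dag) {
  g <- .as_igraph(dag)
  # rows: ancestor i; columns: descendant j; follow edges child->parent
  # backwards, i.e. mode = "in" from each node over the stored direction
  d <- igraph::distances(g, mode = "in")
  R <- (is.finite(d)) * 1L
  storage.mode(R) <- "integer"
  dimnames(R) <- list(dag$nodes, dag$nodes)
  R
}

#' Ancestor sets of every node
#'
#' @param dag an `ontology_dag`.
#' @return named list: for each node, the character vector of its strict
#'   ancestors (excluding the node itself).
#' @export
ancestors <- function(dag) {
  R <- reachability(dag)
  out <- lapply(seq_along(dag$nodes), function(j) {
    anc <- dag$nodes[R[, j] == 1L]
    setdiff(anc, dag$nodes[j])
  })
  stats::setNames(out, dag$nodes)
}

#' Prune an ontology to an observed label set
#'
#' Restricts the DAG to the cell types actually observed in a training set,
#' the standard first step before building the loss. The pruned node set is
#' exactly `observed`; an edge `u -> v` is kept iff `v` is an ancestor of
#' `u` in the full ontology and no other observed node lies strictly
#' between them on any path (the transitive reduction of the induced
#' ancestry partial order). Ancestry among observed nodes is therefore
#' preserved exactly while the edge set stays minimal.
#'
#' @param dag the full `ontology_dag`.
#' @param observed character vector of observed node identifiers.
#' @return a pruned `ontology_dag`.
#' @export
prune_to_labels <- function(dag, observed) {
  observed <- unique(as.character(observed))
  missing <- setdiff(observed, dag$nodes)
  if (length(missing) > 0L) {
    stop("observed label(s) not in ontology: ", paste(missing, collapse = ", "))
  }
  R <- reachability(dag)
  Ro <- R[observed, observed, drop = FALSE]
  # strict ancestry among observed nodes
  anc <- Ro == 1L & !diag(length(observed)) == 1L
  child <- character(0); parent <- character(0)
  for (u in observed) {
    ancs <- observed[anc[, match(u, observed)]]
    for (v in ancs) {
      # drop u->v when some observed w sits strictly between: v > w > u
      mids <- setdiff(ancs, v)
      if (length(mids) > 0L &&
          any(anc[match(v, observed), match(mids, observed)])) {
        next
      }
      child <- c(child, u); parent <- c(parent, v)
    }
  }
  ontology_dag(observed, data.frame(child = child, parent = parent),
               display_names = dag$display_names)
}

#' Classify ontology nodes as leaf/internal and connected/isolated
#'
#' A node is a *leaf* if it has no children in the (pruned) ontology and
#' *internal* otherwise; it is *connected* if at least one parent or child
#' is present in the graph and *isolated* if it has neither ancestors nor
#' descendants represented. These categories describe where hierarchical
#' loss propagation can and cannot act.
#'
#' @param dag an `ontology_dag` (typically already pruned).
#' @return data.frame with columns `node`, `is_leaf`, `is_internal`,
#'   `is_connected`, `is_isolated`, one row per node in node order.
#' @export
classify_nodes <- function(dag) {
  has_child <- dag$nodes %in% dag$edges$parent
  has_parent <- dag$nodes %in% dag$edges$child
  data.frame(
    node = dag$nodes,
    is_leaf = !has_child,
    is_internal = has_child,
    is_connected = has_child | has_parent,
    is_isolated = !(has_child | has_parent),
    stringsAsFactors = FALSE
  )
}
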