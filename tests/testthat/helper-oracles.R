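# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with R/: closures are computed by naive
# per-node DFS, confusion counts by explicit loops, and Holm adjustment by
# literal step-down enumeration.

# brute-force transitive closure: R[i, j] = 1 iff j == i or j is a
# descendant of i, found by DFS over parent->child (inverted is_a) edges
oracle_reachability <- function(dag) {
  n <- length(dag$nodes)
  R <- matrix(0L, n, n, dimnames = list(dag$nodes, dag$nodes))
  children_of <- function(v) dag$edges$child[dag$edges$parent == v]
  for (i in seq_len(n)) {
    seen <- character(0)
    stack <- dag$nodes[i]
    while (length(stack) > 0L) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, children_of(v))
    }
    R[i, match(seen, dag$nodes)] <- 1L
  }
  R
}

# random multi-parent DAG: edges only from higher-indexed (deeper) nodes to
# lower-indexed ones, so acyclicity holds by construction
random_dag <- function(n, p_edge = 0.15) {
  nodes <- sprintf("N%03d", seq_len(n))
  child <- character(0); parent <- character(0)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (stats::runif(1) < p_edge) {
          child <- c(child, nodes[i]); parent <- c(parent, nodes[j])
        }
      }
    }
  }
  ontology_dag(nodes, data.frame(child = child, parent = parent))
}

# explicit per-cell confusion tally under the descendant-correct rule
oracle_confusion <- function(preds, truths, R, C) {
  tp <- fp <- fn <- integer(C)
  for (i in seq_along(preds)) {
    p <- preds[i]; t <- truths[i]
    ok <- p == t || (!is.null(R) && R[t, p] == 1L)
    if (ok) {
      tp[t] <- tp[t] + 1L
    } else {
      fp[p] <- fp[p] + 1L
      fn[t] <- fn[t] + 1L
    }
  }
  data.frame(class = seq_len(C), tp = tp, fp = fp, fn = fn)
}

oracle_macro_f1 <- function(cs, include) {
  f1 <- numeric(length(include))
  for (k in seq_along(include)) {
    i <- include[k]
    prec <- if (cs$tp[i] + cs$fp[i] > 0) cs$tp[i] / (cs$tp[i] + cs$fp[i]) else 0
    rec <- if (cs$tp[i] + cs$fn[i] > 0) cs$tp[i] / (cs$tp[i] + cs$fn[i]) else 0
    f1[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1)
}

# literal Holm step-down: sort, multiply k-th smallest by (m - k + 1),
# running maximum, cap at 1, restore input order
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    val <- min(1, (m - k + 1) * p[o[k]])
    running <- max(running, val)
    adj[o[k]] <- running
  }
  adj
}

# central finite-difference gradient of a scalar function of a matrix
fd_grad <- function(f, Z, h = 1e-6) {
  G <- Z * 0
  for (i in seq_along(Z)) {
    Zp <- Z; Zm <- Z
    Zp[i] <- Zp[i] + h
    Zm[i] <- Zm[i] - h
    G[i] <- (f(Zp) - f(Zm)) / (2 * h)
  }
  G
}

make_chain <- function() {
  # C is_a B is_a A; lexicographic node order A, B, C
  ontology_dag(c("A", "B", "C"),
               data.frame(child = c("C", "B"), parent = c("B", "A")))
}

random_prob <- function(C) {
  p <- stats::rexp(C)
  p / sum(p)
}
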