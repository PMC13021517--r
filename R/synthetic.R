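#' Configuration for the synthetic atlas generator
#'
#' Defines a desk-scale single-cell atlas with the three statistical
#' features that motivate hierarchy-aware training: cluster-structured
#' counts per leaf cell type, mixed-granularity annotations (a fraction of
#' cells labelled at an ancestor of their true leaf type) and study-level
#' distribution shift for out-of-distribution evaluation.
#'
#' @param n_leaves number of leaf cell types.
#' @param max_depth maximum ontology depth (edges from root to any leaf).
#' @param extra_edge_prob probability that a non-root node receives a
#'   second parent, making the ontology a true DAG rather than a tree.
#' @param n_genes number of genes; must be at least
#'   `n_leaves * markers_per_leaf`.
#' @param markers_per_leaf marker genes elevated in each leaf's program.
#' @param nb_mean baseline negative-binomial mean per background gene
#'   (relative scale; programs are rescaled to `library_size_target`).
#' @param marker_fold fold elevation of a leaf's markers over baseline.
#' @param nb_dispersion negative-binomial size parameter; `Inf` gives
#'   Poisson counts.
#' @param library_size_target expected total counts per cell.
#' @param lib_jitter_sd log-normal sd of the per-cell library-size factor.
#' @param granularity_gamma probability, per cell, that its leaf label is
#'   coarsened to a uniformly chosen strict ancestor.
#' @param n_studies number of simulated studies.
#' @param study_effect_sd log-scale sd of the gene-wise multiplicative
#'   study effect (the source of OOD shift).
#' @param donor_effect_sd log-scale sd of a gene-wise donor effect
#'   (default 0: all within-study variation comes from sampling noise).
#' @param cells_per_study cells simulated per study.
#' @param donors_per_study donors per study; cells are assigned to donors
#'   in contiguous blocks.
#' @param seed integer seed; every generator consuming this config is
#'   bitwise reproducible given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 8L, max_depth = 3L, extra_edge_prob = 0.1,
                       n_genes = 60L, markers_per_leaf = 5L, nb_mean = 1,
                       marker_fold = 8, nb_dispersion = 2,
                       library_size_target = 2000, lib_jitter_sd = 0.05,
                       granularity_gamma = 0.4, n_studies = 4L,
                       study_effect_sd = 0.8, donor_effect_sd = 0,
                       cells_per_study = 300L, donors_per_study = 3L,
                       seed = 1L) {
  cfg <- list(n_leaves = as.integer(n_leaves), max_depth = as.integer(max_depth),
              extra_edge_prob = extra_edge_prob, n_genes = as.integer(n_genes),
              markers_per_leaf = as.integer(markers_per_leaf),
              nb_mean = nb_mean, marker_fold = marker_fold,
              nb_dispersion = nb_dispersion,
              library_size_target = library_size_target,
              lib_jitter_sd = lib_jitter_sd,
              granularity_gamma = granularity_gamma,
              n_studies = as.integer(n_studies),
              study_effect_sd = study_effect_sd,
              donor_effect_sd = donor_effect_sd,
              cells_per_study = as.integer(cells_per_study),
              donors_per_study = as.integer(donors_per_study),
              seed = as.integer(seed))
  probs <- c(extra_edge_prob = cfg$extra_edge_prob,
             granularity_gamma = cfg$granularity_gamma)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad) > 0L) {
    stop("field(s) must lie in [0, 1]: ", paste(bad, collapse = ", "))
  }
  stopifnot(cfg$n_leaves >= 1L, cfg$max_depth >= 0L, cfg$n_genes >= 1L,
            cfg$markers_per_leaf >= 1L, cfg$nb_mean > 0, cfg$marker_fold > 0,
            cfg$nb_dispersion > 0, cfg$library_size_target > 0,
            cfg$lib_jitter_sd >= 0, cfg$n_studies >= 1L,
            cfg$study_effect_sd >= 0, cfg$donor_effect_sd >= 0,
              cfg$cells_per_study >= 1L, cfg$donors_per_study >= 1L)
  if (cfg$n_genes < cfg$n_leaves * cfg$markers_per_leaf) {
    stop("n_genes must be at least n_leaves * markers_per_leaf")
  }
  structure(cfg, class = "sim_config")
}

.with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a rooted cell-type ontology
#'
#' Builds a rooted DAG with exactly `n_leaves` leaves and depth at most
#' `max_depth` by recursively partitioning the leaf set into 2-3 child
#' groups, then adds, with probability `extra_edge_prob` per non-root
#' node, one extra parent from a strictly shallower level (cycles are
#' impossible because every edge points from deeper to shallower).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an [ontology_dag()].
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_leaves > 1L && cfg$max_depth < 1L) {
    stop("cannot place ", cfg$n_leaves, " leaves at max_depth 0")
  }
  .with_seed(cfg$seed, {
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("CT:%04d", counter)
    }
    child <- character(0); parent <- character(0)
    depth <- integer(0)
    root <- new_id()
    depth[root] <- 0L
    grow <- function(node, n, rem_depth) {
      if (n == 1L) return(invisible(NULL))
      k <- if (rem_depth == 1L) n else min(n, sample(2:3, 1L))
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      for (sz in sizes) {
        kid <- new_id()
        child <<- c(child, kid); parent <<- c(parent, node)
        depth[kid] <<- depth[[node]] + 1L
        grow(kid, sz, rem_depth - 1L)
      }
      invisible(NULL)
    }
    grow(root, cfg$n_leaves, cfg$max_depth)
    nodes <- names(depth)
    # occasional second parent from a strictly shallower non-ancestor
    if (cfg$extra_edge_prob > 0 && length(nodes) > 2L) {
      anc_of <- function(v) {
        out <- character(0); cur <- v
        repeat {
          ps <- parent[child == cur]
          if (length(ps) == 0L) break
          out <- c(out, ps); cur <- ps[1]
        }
        unique(out)
      }
      for (v in setdiff(nodes, root)) {
        if (stats::runif(1) >= cfg$extra_edge_prob) next
        cand <- nodes[depth[nodes] < depth[[v]]]
        cand <- setdiff(cand, c(anc_of(v), v))
        if (length(cand) > 0L) {
          pick <- cand[sample.int(length(cand), 1L)]
          child <- c(child, v); parent <- c(parent, pick)
        }
      }
    }
    ontology_dag(nodes, data.frame(child = child, parent = parent))
  })
}

#' Simulate a hierarchically structured count atlas
#'
#' Each cell draws a leaf cell type uniformly; the leaf defines a
#' mean-expression program in which its marker genes are elevated by
#' `marker_fold` over baseline, rescaled so the expected library size is
#' `library_size_target`. Counts are negative binomial around the program
#' mean, multiplied by a gene-wise log-normal study effect (and optional
#' donor effect) plus a per-cell library-size jitter. Cells are assigned
#' to studies and, within each study, to contiguous donor blocks.
#'
#' Observed labels start equal to the true leaf labels; apply
#' [coarsen_labels()] to introduce mixed annotation granularity.
#'
#' @param dag an [ontology_dag()], typically from [generate_ontology()].
#' @param cfg a [sim_config()].
#' @return object of class `synthetic_atlas`: integer `counts`
#'   (cells x genes), a `cells` data.frame (`cell_id`, `true_label`,
#'   `observed_label`, `study`, `donor`), `genes`, leaf `programs`
#'   (leaf x gene expected counts), the `dag` and the `config`.
#' @export
simulate_counts <- function(dag, cfg) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(cfg, "sim_config"))
  tax <- classify_nodes(dag)
  leaves <- tax$node[tax$is_leaf]
  if (length(leaves) == 0L) stop("ontology has no leaves")
  G <- cfg$n_genes
  .with_seed(cfg$seed + 1L, {
    programs <- matrix(cfg$nb_mean, nrow = length(leaves), ncol = G,
                       dimnames = list(leaves, sprintf("G%04d", seq_len(G))))
    for (i in seq_along(leaves)) {
      block <- ((i - 1L) * cfg$markers_per_leaf + 1L):(i * cfg$markers_per_leaf)
      programs[i, block] <- cfg$nb_mean * cfg$marker_fold
    }
    programs <- programs * (cfg$library_size_target / rowSums(programs))

    n_cells <- cfg$n_studies * cfg$cells_per_study
    study <- rep(sprintf("study%d", seq_len(cfg$n_studies)),
                 each = cfg$cells_per_study)
    donor_block <- ceiling(seq_len(cfg$cells_per_study) /
                             ceiling(cfg$cells_per_study / cfg$donors_per_study))
    donor <- paste0(study, "_d", rep(donor_block, cfg$n_studies))
    leaf_idx <- sample.int(length(leaves), n_cells, replace = TRUE)

    study_fac <- matrix(exp(stats::rnorm(cfg$n_studies * G, 0,
                                         cfg$study_effect_sd)),
                        nrow = cfg$n_studies)
    donors <- unique(donor)
    donor_fac <- matrix(exp(stats::rnorm(length(donors) * G, 0,
                                         cfg$donor_effect_sd)),
                        nrow = length(donors), dimnames = list(donors, NULL))
    lib_fac <- exp(stats::rnorm(n_cells, 0, cfg$lib_jitter_sd))

    counts <- matrix(0L, nrow = n_cells, ncol = G)
    study_idx <- rep(seq_len(cfg$n_studies), each = cfg$cells_per_study)
    for (i in seq_len(n_cells)) {
      mu <- programs[leaf_idx[i], ] * study_fac[study_idx[i], ] *
        donor_fac[donor[i], ] * lib_fac[i]
      counts[i, ] <- if (is.finite(cfg$nb_dispersion)) {
        stats::rnbinom(G, mu = mu, size = cfg$nb_dispersion)
      } else {
        stats::rpois(G, lambda = mu)
      }
    }
    dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)),
                             colnames(programs))
    cells <- data.frame(cell_id = rownames(counts),
                        true_label = leaves[leaf_idx],
                        observed_label = leaves[leaf_idx],
                        study = study, donor = donor,
                        stringsAsFactors = FALSE)
    structure(list(counts = counts, cells = cells,
                   genes = colnames(programs), programs = programs,
                   dag = dag, config = cfg),
              class = "synthetic_atlas")
  })
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat(sprintf("synthetic_atlas: %d cells x %d genes, %d studies, %d label classes\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cells$study)),
              length(unique(x$cells$observed_label))))
  invisible(x)
}

#' Coarsen annotations to mixed granularity
#'
#' Independently for each cell, with probability `gamma` the observed
#' label is replaced by a uniformly chosen strict ancestor of its true
#' leaf type (the root included); otherwise the leaf label is kept. This
#' emulates atlases in which some studies annotate broad categories while
#' others distinguish fine-grained subtypes.
#'
#' @param atlas a `synthetic_atlas`.
#' @param gamma coarsening probability in \[0, 1\]; defaults to the
#'   config's `granularity_gamma`.
#' @param seed seed for the per-cell coin flips and ancestor draws;
#'   defaults to the config seed.
#' @return the atlas with `cells$observed_label` updated.
#' @export
coarsen_labels <- function(atlas, gamma = NULL, seed = NULL) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  if (is.null(gamma)) gamma <- atlas$config$granularity_gamma
  if (is.null(seed)) seed <- atlas$config$seed + 2L
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  anc <- ancestors(atlas$dag)
  .with_seed(seed, {
    n <- nrow(atlas$cells)
    flip <- stats::runif(n) < gamma
    obs <- atlas$cells$true_label
    for (i in which(flip)) {
      a <- anc[[obs[i]]]
      if (length(a) > 0L) obs[i] <- a[sample.int(length(a), 1L)]
    }
    atlas$cells$observed_label <- obs
    atlas
  })
}

#' Split an atlas into train / in-distribution test / OOD test
#'
#' The OOD test set is every cell of the held-out studies — entire studies
#' unseen during training, the setting where annotation conventions and
#' technical effects shift. The remaining cells are partitioned into train
#' and in-distribution test by donor (never by cell): within each retained
#' study, the last `id_donor_frac` fraction of donors goes to the ID test
#' split.
#'
#' @param atlas a `synthetic_atlas`.
#' @param held_out_studies character vector of study ids; must be a proper
#'   nonempty subset of the atlas's studies.
#' @param id_donor_frac fraction of donors per retained study reserved for
#'   the ID test split (default 1/3).
#' @return list of three `synthetic_atlas` objects: `train`, `id_test`,
#'   `ood_test`.
#' @export
split_id_ood <- function(atlas, held_out_studies, id_donor_frac = 1 / 3) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  studies <- unique(atlas$cells$study)
  held_out_studies <- unique(as.character(held_out_studies))
  if (length(held_out_studies) == 0L) stop("held_out_studies must be nonempty")
  if (!all(held_out_studies %in% studies)) {
    stop("unknown study id(s): ",
         paste(setdiff(held_out_studies, studies), collapse = ", "))
  }
  if (setequal(held_out_studies, studies)) {
    stop("cannot hold out every study; nothing would remain for training")
  }
  take <- function(keep) {
    a <- atlas
    a$counts <- atlas$counts[keep, , drop = FALSE]
    a$cells <- atlas$cells[keep, , drop = FALSE]
    rownames(a$cells) <- NULL
    a
  }
  is_ood <- atlas$cells$study %in% held_out_studies
  id_test <- rep(FALSE, nrow(atlas$cells))
  for (s in setdiff(studies, held_out_studies)) {
    in_s <- atlas$cells$study == s
    dns <- sort(unique(atlas$cells$donor[in_s]))
    n_id <- max(1L, floor(length(dns) * id_donor_frac))
    id_donors <- utils::tail(dns, n_id)
    id_test <- id_test | (in_s & atlas$cells$donor %in% id_donors)
  }
  list(train = take(!is_ood & !id_test),
       id_test = take(!is_ood & id_test),
       ood_test = take(is_ood))
}

#' Size-factor normalization and log transform
#'
#' Scales every cell to a total of `target` counts (size-factor
#' normalization) and applies the natural-log transform with a pseudocount
#' of 1, `f(x) = log(x + 1)`.
#'
#' @param counts nonnegative matrix (cells x genes).
#' @param target per-cell total after scaling (default 10,000).
#' @return numeric matrix of normalized log-expression, same shape.
#' @export
normalize_counts <- function(counts, target = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    ids <- rownames(counts)[tot == 0]
    if (is.null(ids)) ids <- which(tot == 0)
    stop("cell(s) with zero total counts: ", paste(ids, collapse = ", "))
  }
  log1p(counts * (target / tot))
}

#' Drop rarely observed label classes
#'
#' Removes every observed-label class (and its cells) that is supported by
#' fewer than `min_cells` cells or fewer than `min_donors` donors —
#' the kind of inclusion filter large curated atlases apply before
#' training.
#'
#' @param atlas a `synthetic_atlas`.
#' @param min_cells minimum cells per class.
#' @param min_donors minimum distinct donors per class.
#' @return the filtered atlas, with the dropped class names in attribute
#'   `"dropped"`.
#' @export
apply_inclusion_filters <- function(atlas, min_cells = 0L, min_donors = 0L) {
  stopifnot(inherits(atlas, "synthetic_atlas"),
            min_cells >= 0L, min_donors >= 0L)
  lab <- atlas$cells$observed_label
  n_cells <- table(lab)
  n_donors <- tapply(atlas$cells$donor, lab, function(d) length(unique(d)))
  keep_class <- names(n_cells)[as.integer(n_cells) >= min_cells &
                                 as.integer(n_donors[names(n_cells)]) >= min_donors]
  dropped <- setdiff(names(n_cells), keep_class)
  if (length(keep_class) == 0L) stop("inclusion filters dropped every class")
  keep <- lab %in% keep_class
  atlas$counts <- atlas$counts[keep, , drop = FALSE]
  atlas$cells <- atlas$cells[keep, , drop = FALSE]
  rownames(atlas$cells) <- NULL
  attr(atlas, "dropped") <- dropped
  atlas
}
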