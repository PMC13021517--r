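#' Desk-scale CE-vs-HCE out-of-distribution benchmark
#'
#' Runs the full comparison the package exists to support, at a size that
#' completes in minutes on one CPU: a fixed synthetic ontology, replicate
#' atlases with mixed-granularity labels and study-level shift, matched
#' CE- and HCE-trained classifiers per seed, and descendant-aware macro F1
#' on a donor-partitioned in-distribution split and a held-out-study OOD
#' split.
#'
#' The ontology is generated once from `cfg$seed`; each replicate seed
#' re-draws the counts, the label coarsening and the weight initialisation
#' so that CE and HCE runs are paired within a seed. The last study is held
#' out for OOD evaluation.
#'
#' @param seeds integer vector of replicate seeds (one paired CE/HCE run
#'   each).
#' @param cfg a [sim_config()] describing the atlas.
#' @param architectures subset of `c("linear", "mlp")`.
#' @param hidden_dims hidden widths for the MLP arm.
#' @param epochs,batch_size,learning_rate,momentum training hyperparameters
#'   shared by both arms; the loss is the only difference between them.
#' @return object of class `hce_benchmark`: `results` (one row per
#'   seed x architecture x loss x split with its macro F1), `f1_ood`
#'   (per-architecture list of runs x classes F1 matrices for each loss),
#'   the `dag`, the reachability matrix and the config.
#' @export
run_ood_benchmark <- function(seeds, cfg = sim_config(),
                              architectures = c("linear", "mlp"),
                              hidden_dims = 32L, epochs = 80L,
                              batch_size = 64L, learning_rate = 0.01,
                              momentum = 0.9) {
  architectures <- match.arg(architectures, c("linear", "mlp"),
                             several.ok = TRUE)
  dag <- generate_ontology(cfg)
  R <- reachability(dag)
  C <- n_nodes(dag)
  results <- NULL
  f1_ood <- lapply(architectures, function(a)
    list(ce = matrix(NA_real_, length(seeds), C,
                     dimnames = list(NULL, dag$nodes)),
         hce = matrix(NA_real_, length(seeds), C,
                      dimnames = list(NULL, dag$nodes))))
  names(f1_ood) <- architectures

  for (k in seq_along(seeds)) {
    run_seed <- (abs(seeds[k]) %% 500000000L) + 7L
    acfg <- cfg
    acfg$seed <- run_seed
    atlas <- simulate_counts(dag, acfg)
    atlas <- coarsen_labels(atlas)
    held <- utils::tail(sort(unique(atlas$cells$study)), 1L)
    splits <- split_id_ood(atlas, held)
    Xtr <- normalize_counts(splits$train$counts)
    Xid <- normalize_counts(splits$id_test$counts)
    Xood <- normalize_counts(splits$ood_test$counts)
    ytr <- match(splits$train$cells$observed_label, dag$nodes)
    yid <- match(splits$id_test$cells$observed_label, dag$nodes)
    yood <- match(splits$ood_test$cells$observed_label, dag$nodes)

    for (arch in architectures) {
      spec <- classifier_spec(arch, input_dim = ncol(Xtr), output_dim = C,
                              hidden_dims = if (arch == "mlp") hidden_dims
                                            else NULL)
      for (loss in c("ce", "hce")) {
        tc <- train_config(loss_kind = loss, epochs = epochs,
                           batch_size = batch_size,
                           learning_rate = learning_rate,
                           momentum = momentum, seed = run_seed)
        fit <- suppressWarnings(
          train_classifier(spec, Xtr, ytr, R = R, config = tc))
        for (split in c("id_test", "ood_test")) {
          X <- if (split == "id_test") Xid else Xood
          y <- if (split == "id_test") yid else yood
          rep_ <- evaluate_predictions(predict_label(fit, X), y, R = R,
                                       include = "present")
          results <- rbind(results, data.frame(
            seed = seeds[k], arch = arch, loss = loss, split = split,
            macro_f1 = rep_$macro_f1))
          if (split == "ood_test") {
            f1_ood[[arch]][[loss]][k, ] <- rep_$per_class$f1
          }
        }
      }
    }
  }
  rownames(results) <- NULL
  structure(list(results = results, f1_ood = f1_ood, dag = dag, R = R,
                 config = cfg, seeds = seeds),
            class = "hce_benchmark")
}

#' Summarise a benchmark: mean macro F1 and the paired CE-vs-HCE test
#'
#' @param bench an `hce_benchmark` from [run_ood_benchmark()].
#' @return list with `means` (mean macro F1 per architecture, loss and
#'   split), `ood_gain` (per-architecture mean HCE - CE OOD difference,
#'   relative gain in percent, and the paired two-sided t-test p-value on
#'   the per-seed OOD macro F1).
#' @export
summarise_benchmark <- function(bench) {
  stopifnot(inherits(bench, "hce_benchmark"))
  res <- bench$results
  means <- stats::aggregate(macro_f1 ~ arch + loss + split, data = res, FUN = mean)
  ood_gain <- lapply(unique(res$arch), function(a) {
    ce <- res$macro_f1[res$arch == a & res$loss == "ce" &
                         res$split == "ood_test"]
    hce <- res$macro_f1[res$arch == a & res$loss == "hce" &
                          res$split == "ood_test"]
    p <- if (length(ce) >= 2L && stats::sd(hce - ce) > 0) {
      stats::t.test(hce, ce, paired = TRUE)$p.value
    } else NA_real_
    list(arch = a, mean_ce = mean(ce), mean_hce = mean(hce),
         mean_delta = mean(hce - ce),
         gain_pct = 100 * (mean(hce) - mean(ce)) / mean(ce),
         paired_p = p)
  })
  names(ood_gain) <- unique(res$arch)
  list(means = means, ood_gain = ood_gain)
}

#' @export
print.hce_benchmark <- function(x, ...) {
  s <- summarise_benchmark(x)
  cat(sprintf("hce_benchmark: %d seeds, ontology of %d nodes\n",
              length(x$seeds), n_nodes(x$dag)))
  print(s$means)
  for (g in s$ood_gain) {
    cat(sprintf("OOD %s: CE %.3f vs HCE %.3f (gain %+.1f%%, paired p = %.3g)\n",
                g$arch, g$mean_ce, g$mean_hce, g$gain_pct, g$paired_p))
  }
  invisible(x)
}
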