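#' Decision-tree configuration
#'
#' Shallow trees (the printed explanation trees use one to three split
#' levels), with minimum-leaf-fraction pruning and a fixed impurity
#' criterion so refits are deterministic.
#'
#' @param max_depth Maximum tree depth (default 3).
#' @param min_leaf_fraction Minimum fraction of cases per leaf (default 0.05).
#' @param split_criterion `"gini"` or `"information"`.
#' @param cp Complexity parameter passed to the recursive-partitioning fit.
#' @param seed RNG seed (the fit itself is deterministic; recorded for
#'   provenance).
#' @return Object of class `tree_config`.
#' @export
tree_config <- function(max_depth = 3, min_leaf_fraction = 0.05,
                        split_criterion = c("gini", "information"),
                        cp = 0.01, seed = 1) {
  stopifnot(max_depth >= 1, min_leaf_fraction >= 0, min_leaf_fraction < 0.5)
  structure(list(max_depth = max_depth, min_leaf_fraction = min_leaf_fraction,
                 split_criterion = match.arg(split_criterion), cp = cp,
                 seed = as.integer(seed)), class = "tree_config")
}

#' Fit an explanation tree
#'
#' Classification tree mapping per-case features (baseline concentrations
#' and derived ratios) to response categories. Deterministic for fixed data
#' and configuration; single-class input yields a degenerate single-leaf
#' report flagged `degenerate = TRUE`.
#'
#' @param features data.frame of numeric features (no missing values).
#' @param labels Factor (or coercible) of class labels, one per row.
#' @param cfg A [tree_config()].
#' @return Object of class `tree_report`: `nodes` (data.frame of node id,
#'   feature, threshold, n, class counts, predicted class, accuracy),
#'   `misclassification`, `root_feature`, `root_threshold`, `degenerate`,
#'   and the underlying `fit`.
#' @export
fit_tree <- function(features, labels, cfg = tree_config()) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(features) == length(labels))
  if (anyNA(features)) stop("features must not contain missing values", call. = FALSE)
  n <- length(labels)
  if (nlevels(labels) < 2) {
    nodes <- data.frame(node = 1L, feature = "<leaf>", threshold = NA_real_,
                        direction = NA_character_, n = n,
                        predicted = levels(labels),
                        accuracy = 1, stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, misclassification = 0,
                          root_feature = NA_character_,
                          root_threshold = NA_real_, degenerate = TRUE,
                          fit = NULL, config = cfg, class_counts = table(labels)),
                     class = "tree_report"))
  }
  dat <- data.frame(.label = labels, features, check.names = TRUE)
  set.seed(cfg$seed)
  fit <- rpart::rpart(
    .label ~ ., data = dat, method = "class",
    parms = list(split = cfg$split_criterion),
    control = rpart::rpart.control(
      maxdepth = cfg$max_depth, cp = cfg$cp, xval = 0,
      minbucket = max(1L, ceiling(cfg$min_leaf_fraction * n)),
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  fr <- fit$frame
  node_ids <- as.integer(rownames(fr))
  nlev <- nlevels(labels)
  counts <- fr$yval2[, 1 + seq_len(nlev), drop = FALSE]
  colnames(counts) <- levels(labels)
  predicted <- levels(labels)[fr$yval2[, 1]]
  acc <- vapply(seq_len(nrow(fr)), function(i) {
    counts[i, fr$yval2[i, 1]] / fr$n[i]
  }, numeric(1))
  thr <- rep(NA_real_, nrow(fr))
  dir <- rep(NA_character_, nrow(fr))
  if (!is.null(fit$splits) && nrow(fit$splits) > 0) {
    internal <- which(fr$var != "<leaf>")
    thr[internal] <- fit$splits[seq_along(internal), "index"]
    # ncat -1: left child holds x < threshold; +1: left child holds x >= it
    dir[internal] <- ifelse(fit$splits[seq_along(internal), "ncat"] < 0,
                            "<", ">=")
  }
  nodes <- data.frame(node = node_ids, feature = as.character(fr$var),
                      threshold = thr, direction = dir, n = fr$n,
                      predicted = predicted, accuracy = acc,
                      stringsAsFactors = FALSE)
  nodes <- cbind(nodes, as.data.frame(counts))
  pred <- stats::predict(fit, type = "class")
  structure(list(nodes = nodes,
                 misclassification = mean(pred != labels),
                 root_feature = nodes$feature[1],
                 root_threshold = nodes$threshold[1],
                 degenerate = nodes$feature[1] == "<leaf>",
                 fit = fit, config = cfg, class_counts = table(labels)),
            class = "tree_report")
}

#' @export
print.tree_report <- function(x, ...) {
  if (x$degenerate) {
    cat("tree_report: degenerate (single leaf)\n")
  } else {
    cat(sprintf("tree_report: root %s @ %.4g, misclassification %.3f\n",
                x$root_feature, x$root_threshold, x$misclassification))
  }
  for (i in seq_len(nrow(x$nodes))) {
    nd <- x$nodes[i, ]
    depth <- floor(log2(nd$node))
    lab <- if (nd$feature == "<leaf>") {
      sprintf("leaf -> %s (n=%d, acc=%.2f)", nd$predicted, nd$n, nd$accuracy)
    } else {
      sprintf("split %s %s %.4g (left) (n=%d)", nd$feature, nd$direction,
              nd$threshold, nd$n)
    }
    cat(strrep("  ", depth + 1), lab, "\n", sep = "")
  }
  invisible(x)
}

#' Thresholds used for one feature, root-to-leaf order
#'
#' @param report A `tree_report`.
#' @param feature Feature name.
#' @return Numeric vector (empty when the feature is not split on).
#' @export
extract_threshold <- function(report, feature) {
  nd <- report$nodes
  nd$threshold[nd$feature == feature & !is.na(nd$threshold)]
}

#' DOT-format rendering of a tree report
#'
#' @param report A `tree_report`.
#' @return Character scalar with a graphviz digraph.
#' @export
tree_dot <- function(report) {
  nd <- report$nodes
  lines <- c("digraph tree {", "  node [shape=box];")
  for (i in seq_len(nrow(nd))) {
    lab <- if (nd$feature[i] == "<leaf>") {
      sprintf("%s\\nn=%d acc=%.2f", nd$predicted[i], nd$n[i], nd$accuracy[i])
    } else {
      sprintf("%s %s %.4g\\nn=%d", nd$feature[i], nd$direction[i],
              nd$threshold[i], nd$n[i])
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$node[i], lab))
  }
  for (i in nd$node) {
    for (child in c(2L * i, 2L * i + 1L)) {
      if (child %in% nd$node) {
        lines <- c(lines, sprintf("  n%d -> n%d;", i, child))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Two-stage explanation of the pAkt response
#'
#' Stage one classifies cases into `change` versus `no_change`
#' (the closed +/-10% band on the perturbed/baseline pAkt ratio); stage two
#' is fitted only on the `change` subset, separating `increase` from
#' `decrease`. When the change subset is empty or single-class, stage two is
#' skipped with a notice.
#'
#' @param population An `ensemble` with the condition simulated.
#' @param condition Condition label (e.g. a 0.5%-oxygen step).
#' @param readout Response readout (default `"pAkt"`).
#' @param rule A [category_rule()].
#' @param totals Phospho/total mapping.
#' @param cfg A [tree_config()].
#' @param features Optional pre-computed [feature_table()].
#' @return List of class `two_stage_report`: `stage1`, `stage2` (`NULL` when
#'   skipped), `skipped_stage2`, `categories`.
#' @export
two_stage_akt_analysis <- function(population, condition, readout = "pAkt",
                                   rule = category_rule(),
                                   totals = phospho_totals_map(),
                                   cfg = tree_config(), features = NULL) {
  if (is.null(features)) features <- feature_table(population, totals)
  tab <- phenotype_table(population, condition, readout, rule, totals)
  tab <- tab[match(rownames(features), tab$case_id), ]
  ok <- !is.na(tab$ratio)
  feats <- features[ok, , drop = FALSE]
  cats <- droplevels(tab$category[ok])
  stage1_lab <- factor(ifelse(cats == "no_change", "no_change", "change"),
                       levels = c("no_change", "change"))
  stage1 <- fit_tree(feats, stage1_lab, cfg)
  chg <- cats != "no_change"
  stage2 <- NULL; skipped <- FALSE
  if (sum(chg) == 0 || nlevels(droplevels(cats[chg])) < 2) {
    skipped <- TRUE
  } else {
    stage2 <- fit_tree(feats[chg, , drop = FALSE], droplevels(cats[chg]), cfg)
  }
  structure(list(stage1 = stage1, stage2 = stage2, skipped_stage2 = skipped,
                 categories = cats), class = "two_stage_report")
}
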