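#' Agglomerative clustering of a distance matrix
#'
#' Runs standard Lance-Williams agglomeration on a pairwise dissimilarity
#' matrix and returns the full merge tree annotated with the two quantities
#' the isomorphic threshold is built from: `W0`, the root (maximum) merge
#' height, and `W1`, the larger height of the root's two children.
#'
#' Heights follow the convention of the clustering stacks used in
#' multi-crystal pipelines: for `ward`, `centroid` and `median` the
#' Lance-Williams update runs in squared-distance space and the reported
#' heights are its square roots, so `ward` here is `stats::hclust`'s
#' `"ward.D2"` applied to the supplied distances. The d_CC matrix is treated
#' as Euclidean-like; Ward's Euclidean assumption is not formally met, which
#' mirrors how the field's pipelines use it.
#'
#' @param D An `iso_dist` from [build_distance_matrix()] /
#'   [cell_distance_matrix()], a `dist`, or a symmetric matrix with zero
#'   diagonal.
#' @param method Linkage: `"ward"` (default), `"single"`, `"complete"`,
#'   `"average"`, `"weighted"`, `"centroid"`, `"median"`.
#' @return An object of class `iso_dendrogram`: list with the underlying
#'   `hclust` object, `labels`, `method`, per-node `members`, `W0`, `W1`.
#' @export
linkage_cluster <- function(D, method = c("ward", "single", "complete",
                                          "average", "weighted", "centroid",
                                          "median")) {
  method <- match.arg(method)
  labels <- NULL
  if (inherits(D, "iso_dist")) {
    labels <- D$labels
    D <- D$values
  }
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort_config("D must be a square distance matrix, dist or iso_dist")
  }
  if (any(!is.finite(D))) abort_data("distance matrix contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) abort_data("distance matrix must be symmetric")
  if (is.null(labels)) labels <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2) abort_data("need at least 2 items to cluster")

  squared <- method %in% c("ward", "centroid", "median")
  hc_method <- switch(method, ward = "ward.D2", weighted = "mcquitty", method)
  d_in <- stats::as.dist(if (method %in% c("centroid", "median")) D^2 else D)
  hc <- hclust(d_in, method = hc_method)
  if (method %in% c("centroid", "median")) hc$height <- sqrt(pmax(hc$height, 0))
  hc$labels <- labels

  members <- node_members(hc)
  heights <- hc$height
  W0 <- heights[n - 1]
  W1 <- if (n == 2) 0 else max(vapply(hc$merge[n - 1, ], function(ch) {
    if (ch < 0) 0 else heights[ch]
  }, numeric(1)))

  structure(
    list(hclust = hc, labels = labels, method = method,
         members = members, W0 = W0, W1 = W1,
         inversions = any(diff(heights) < -1e-12)),
    class = "iso_dendrogram"
  )
}

# List of leaf-index sets, one per merge node (hclust row order).
node_members <- function(hc) {
  n <- length(hc$height) + 1
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members[[i]] <- unlist(lapply(hc$merge[i, ], function(ch) {
      if (ch < 0) -ch else members[[ch]]
    }))
  }
  members
}

#' @export
print.iso_dendrogram <- function(x, ...) {
  cat(sprintf("<iso_dendrogram> %d leaves, %s linkage, W0=%.4g W1=%.4g (W1/W0=%.3g)%s\n",
              length(x$labels), x$method, x$W0, x$W1,
              if (x$W0 > 0) x$W1 / x$W0 else NA_real_,
              if (isTRUE(x$inversions)) " [height inversions]" else ""))
  invisible(x)
}

#' Extract the root height and larger child-of-root height
#'
#' `W0` is the maximum merge (Ward) height of the dendrogram; `W1` is the
#' larger of the two heights at which the root's children were themselves
#' assembled (0 for a leaf child). When the data split into two structures,
#' `W1` is the natural isomorphic threshold separating them.
#'
#' @param tree An `iso_dendrogram` from [linkage_cluster()].
#' @return Named numeric vector `c(W0 = , W1 = )`.
#' @export
extract_w0_w1 <- function(tree) {
  if (!inherits(tree, "iso_dendrogram")) {
    abort_config("`tree` must be an iso_dendrogram")
  }
  if (length(tree$labels) < 2) abort_data("tree must have at least 2 leaves")
  c(W0 = tree$W0, W1 = tree$W1)
}

#' Isomorphic threshold from the maximum Ward distance
#'
#' The threshold below which clusters are nominated as distinct structures is
#' defined as `W1 = R * W0`, with the ratio `R` calibrated by simulation to
#' 0.6-0.7 for several hundred data sets.
#'
#' @param W0 Maximum Ward distance (root height), >= 0.
#' @param R Ratio in (0, 1).
#' @return `R * W0`.
#' @examples
#' isomorphic_threshold(1.29, 0.6)  # 0.774
#' @export
isomorphic_threshold <- function(W0, R) {
  if (!is_scalar_number(W0) || W0 < 0) abort_config("W0 must be >= 0")
  if (!is.numeric(R) || any(R <= 0 | R >= 1)) {
    abort_config("R must lie strictly between 0 and 1")
  }
  R * W0
}

#' Nominate candidate polymorph clusters under the isomorphic threshold
#'
#' Cuts the dendrogram at the isomorphic threshold `R_high * W0` and returns
#' the maximal nodes whose height lies at or below it: each such cluster is a
#' candidate structural polymorph. Clusters holding fewer than
#' `min_cluster_fraction` of the leaves are reported separately as outliers
#' (small, internally spread clusters typically emanating from poor chunks).
#'
#' @param tree An `iso_dendrogram`.
#' @param R_low,R_high The calibrated ratio interval (defaults 0.6-0.7); the
#'   report carries both cut levels, candidates are taken at `R_high`.
#' @param min_cluster_fraction Minimum fraction of leaves for a candidate
#'   (default 0.05).
#' @return An object of class `polymorph_report`: list with
#'   `threshold_interval` (`c(R_low, R_high) * W0`), `candidates` and
#'   `outliers` tibbles (`node_id`, `height`, `n_members`, `members`
#'   list-column of chunk ids), `W0`, `R_low`, `R_high`.
#' @export
nominate_polymorphs <- function(tree, R_low = 0.6, R_high = 0.7,
                                min_cluster_fraction = 0.05) {
  if (!inherits(tree, "iso_dendrogram")) {
    abort_config("`tree` must be an iso_dendrogram")
  }
  if (R_low > R_high) abort_config("R_low must not exceed R_high")
  thr <- isomorphic_threshold(tree$W0, c(R_low, R_high))
  hc <- tree$hclust
  n <- length(tree$labels)

  # maximal nodes with height <= threshold, found by descending from the root
  collect <- function(node) {
    if (node < 0) {
      return(list(list(node_id = node, height = 0, members = -node)))
    }
    if (hc$height[node] <= thr[2]) {
      return(list(list(node_id = node, height = hc$height[node],
                       members = tree$members[[node]])))
    }
    c(collect(hc$merge[node, 1]), collect(hc$merge[node, 2]))
  }
  found <- if (tree$W0 <= thr[2]) {
    list(list(node_id = n - 1L, height = tree$W0,
              members = seq_len(n)))
  } else {
    collect(n - 1L)
  }

  nodes <- tibble(
    node_id = vapply(found, function(x) as.integer(x$node_id), integer(1)),
    height = vapply(found, function(x) x$height, numeric(1)),
    n_members = vapply(found, function(x) length(x$members), integer(1)),
    members = purrr::map(found, function(x) tree$labels[x$members])
  )
  small <- nodes$n_members < min_cluster_fraction * n
  structure(
    list(threshold_interval = thr,
         candidates = nodes[!small, , drop = FALSE],
         outliers = nodes[small, , drop = FALSE],
         W0 = tree$W0, R_low = R_low, R_high = R_high,
         n_leaves = n),
    class = "polymorph_report"
  )
}

#' @export
print.polymorph_report <- function(x, ...) {
  cat(sprintf("<polymorph_report> threshold %.4g-%.4g (W0=%.4g, R=%.2g-%.2g)\n",
              x$threshold_interval[1], x$threshold_interval[2],
              x$W0, x$R_low, x$R_high))
  cat(sprintf("  %d candidate cluster(s), %d outlier cluster(s)\n",
              nrow(x$candidates), nrow(x$outliers)))
  for (i in seq_len(nrow(x$candidates))) {
    cat(sprintf("  candidate %d: %d chunks at height %.4g\n",
                i, x$candidates$n_members[i], x$candidates$height[i]))
  }
  invisible(x)
}

#' Score a dendrogram's flat cut against ground-truth labels
#'
#' Cuts the tree into `k` flat clusters at the `k - 1` highest merges and
#' returns the best achievable labelling accuracy: the maximum, over
#' injective assignments of clusters to labels, of the fraction of leaves
#' whose cluster is assigned their true label.
#'
#' @param tree An `iso_dendrogram`.
#' @param labels Ground-truth labels, one per leaf. Either unnamed in leaf
#'   order (the order of `tree$labels`) or named by chunk id.
#' @param k Number of flat clusters (default 2, the two-structure case).
#' @return A score in `[0, 1]`; 1 is perfect classification.
#' @export
classification_score <- function(tree, labels, k = 2) {
  if (!inherits(tree, "iso_dendrogram")) {
    abort_config("`tree` must be an iso_dendrogram")
  }
  n <- length(tree$labels)
  if (k < 2) abort_config("k must be at least 2")
  if (k > n) abort_config("k exceeds the number of leaves")
  if (!is.null(names(labels))) {
    if (!all(tree$labels %in% names(labels))) {
      abort_data("named labels must cover every leaf")
    }
    labels <- labels[tree$labels]
  }
  if (length(labels) != n) abort_data("need one label per leaf")
  cl <- cutree(tree$hclust, k = k)
  tab <- table(cl, labels)
  best_assignment_count(unclass(tab)) / n
}

# Maximum-weight injective assignment of rows to columns of a count matrix,
# by bitmask dynamic programming over the smaller dimension.
best_assignment_count <- function(tab) {
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  k <- nrow(tab)
  L <- ncol(tab)
  if (L > 20) abort_config("too many distinct labels for exact assignment")
  memo <- new.env(hash = TRUE)
  rec <- function(row, mask) {
    if (row > k) return(0)
    key <- paste(row, mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0
    for (col in seq_len(L)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) == 0) {
        best <- max(best, tab[row, col] + rec(row + 1, bitwOr(mask, bit)))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1, 0L)
}

#' @method tidy iso_dendrogram
#' @export
tidy.iso_dendrogram <- function(x, ...) {
  hc <- x$hclust
  n <- length(x$labels)
  tibble(
    node_id = seq_len(n - 1L),
    height = hc$height,
    n_members = lengths(x$members),
    members = purrr::map(x$members, function(ii) x$labels[ii])
  )
}

#' @method glance iso_dendrogram
#' @export
glance.iso_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$labels), linkage = x$method,
         W0 = x$W0, W1 = x$W1,
         R_obs = if (x$W0 > 0) x$W1 / x$W0 else NA_real_,
         inversions = x$inversions)
}

#' @method tidy polymorph_report
#' @export
tidy.polymorph_report <- function(x, ...) {
  assign_rows <- function(df, is_outlier) {
    purrr::map2_dfr(df$node_id, df$members, function(id, mem) {
      tibble(chunk_id = mem, candidate_id = id, is_outlier = is_outlier)
    })
  }
  dplyr::bind_rows(assign_rows(x$candidates, FALSE),
                   assign_rows(x$outliers, TRUE))
}

#' @method glance polymorph_report
#' @export
glance.polymorph_report <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates), n_outlier_clusters = nrow(x$outliers),
         threshold_low = x$threshold_interval[1],
         threshold_high = x$threshold_interval[2],
         W0 = x$W0)
}

#' Dendrogram as a ggplot
#'
#' Draws the merge tree with leaves on the x axis and merge height on the y
#' axis, with the isomorphic-threshold band overlaid.
#'
#' @param object An `iso_dendrogram`.
#' @param R_low,R_high Threshold band to draw (defaults 0.6-0.7 of `W0`);
#'   `NULL` suppresses the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iso_dendrogram
#' @export
autoplot.iso_dendrogram <- function(object, R_low = 0.6, R_high = 0.7, ...) {
  hc <- object$hclust
  n <- length(object$labels)
  xpos <- numeric(n - 1)
  leaf_x <- match(seq_len(n), hc$order)
  segs <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    child_xy <- vapply(hc$merge[i, ], function(ch) {
      if (ch < 0) c(leaf_x[-ch], 0) else c(xpos[ch], hc$height[ch])
    }, numeric(2))
    xpos[i] <- mean(child_xy[1, ])
    h <- hc$height[i]
    segs[[i]] <- tibble(
      x = c(child_xy[1, 1], child_xy[1, 1], child_xy[1, 2]),
      xend = c(child_xy[1, 1], child_xy[1, 2], child_xy[1, 2]),
      y = c(child_xy[2, 1], h, h),
      yend = c(h, h, child_xy[2, 2])
    )
  }
  segs <- dplyr::bind_rows(segs)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[hc$order],
                                guide = ggplot2::guide_axis(angle = 90)) +
    ggplot2::labs(x = NULL, y = sprintf("%s distance", object$method)) +
    ggplot2::theme_minimal()
  if (!is.null(R_low) && !is.null(R_high)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = R_low * object$W0,
                               ymax = R_high * object$W0,
                               alpha = 0.15, fill = "steelblue")
  }
  p
}
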