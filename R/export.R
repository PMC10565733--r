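# Dendrogram serialisation: JSON node list, Newick with branch lengths
# (parent height - child height), and the flat assignment table.

#' Export a dendrogram as JSON
#'
#' One object per merge node with `node_id`, `children` (negative ids are
#' leaves, numbered -1..-n in label order), `height` and `members` (chunk
#' ids).
#'
#' @param tree An `iso_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_json <- function(tree, path) {
  hc <- tree$hclust
  nodes <- purrr::map(seq_along(hc$height), function(i) {
    list(node_id = i, children = hc$merge[i, ], height = hc$height[i],
         members = tree$labels[tree$members[[i]]])
  })
  jsonlite::write_json(
    list(linkage = tree$method, W0 = tree$W0, W1 = tree$W1,
         leaves = tree$labels, nodes = nodes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are `parent height - child height` (leaves have height 0),
#' so root-to-leaf path lengths equal `W0`.
#'
#' @param tree An `iso_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  hc <- tree$hclust
  fmt <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.10g", gsub("[(),:; ]", "_", tree$labels[-node]),
              parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%.10g",
              fmt(hc$merge[node, 1], h), fmt(hc$merge[node, 2], h),
              parent_height - h)
    }
  }
  root <- length(hc$height)
  writeLines(sprintf("(%s,%s);",
                     fmt(hc$merge[root, 1], hc$height[root]),
                     fmt(hc$merge[root, 2], hc$height[root])), path)
  invisible(path)
}

#' Export flat cluster assignments as TSV
#'
#' Writes one row per chunk with its candidate cluster id and outlier flag,
#' as produced by [nominate_polymorphs()].
#'
#' @param report A `polymorph_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(report, path) {
  utils::write.table(tidy(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
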