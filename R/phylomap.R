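# Mapping continuous shape distances onto a phylogeny: tip matching with
# name normalization, and ancestral values by squared-change parsimony on an
# unweighted tree (all edges equal), the standard choice when a composite
# topology carries no meaningful branch lengths.

normalize_name <- function(x) gsub("[ _]+", " ", tolower(trimws(x)))

#' Squared-change parsimony ancestral reconstruction
#'
#' Internal node values minimising the sum over edges of squared
#' parent-child differences, with equal edge weights and tip values fixed.
#' This is the classical linear (harmonic) reconstruction: each internal
#' value is the mean of its neighbours, solved exactly as a sparse linear
#' system.
#'
#' @param tree an [ape::phylo] tree (branch lengths ignored).
#' @param tip_values numeric vector named by tip label (all tips present).
#' @return Numeric vector of internal-node values, named by node number
#'   (`ape` numbering: tips are `1..n`, internals `n+1 ..`).
#' @export
squared_change_parsimony <- function(tree, tip_values) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  if (!all(tree$tip.label %in% names(tip_values)))
    stop("tip_values must cover every tip label")
  vals <- tip_values[tree$tip.label]
  edges <- tree$edge  # parent (internal id), child
  total <- n_tip + n_node
  # graph Laplacian over all nodes; internal nodes unknown, tips fixed
  ii <- c(edges[, 1], edges[, 2])
  deg <- tabulate(ii, nbins = total)
  internal <- (n_tip + 1):total
  L <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = rep(-1, 2 * nrow(edges)),
                            dims = c(total, total)) +
    Matrix::Diagonal(total, deg)
  A <- L[internal, internal, drop = FALSE]
  b <- -as.vector(L[internal, seq_len(n_tip), drop = FALSE] %*% vals)
  sol <- as.vector(Matrix::solve(A, b))
  names(sol) <- as.character(internal)
  sol
}

#' Map shape distances onto a phylogeny
#'
#' Matches taxa to tree tips case-insensitively after underscore/space
#' normalization, reports unmatched tips (never drops them silently), prunes
#' them for the reconstruction, and fills internal nodes by squared-change
#' parsimony.
#'
#' @param tree an [ape::phylo] object, a Newick string, or a path to a
#'   Newick file.
#' @param distances data.frame with `specimen_id` and `d_pc123`
#'   (as from [pc_distance()]), or a named numeric vector.
#' @return An `annotated_tree`: `tree` (pruned, matched tips), `full_tree`,
#'   `tip_values`, `node_values`, `unmatched_tips`.
#' @export
map_distances <- function(tree, distances) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(distances)) {
    vals <- distances$d_pc123
    names(vals) <- distances$specimen_id
  } else {
    vals <- distances
  }
  lookup <- stats::setNames(as.numeric(vals), normalize_name(names(vals)))
  tipn <- normalize_name(tree$tip.label)
  matched <- tipn %in% names(lookup)
  if (sum(matched) < 2) {
    sugg <- vapply(tree$tip.label[!matched][seq_len(min(3, sum(!matched)))],
                   function(tp) {
                     d <- utils::adist(normalize_name(tp), names(lookup))
                     names(lookup)[which.min(d)]
                   }, character(1))
    stop("fewer than 2 tree tips match the distance table; nearest name ",
         "suggestions: ", paste(names(sugg), "->", sugg, collapse = "; "))
  }
  unmatched <- tree$tip.label[!matched]
  pruned <- if (length(unmatched)) ape::drop.tip(tree, unmatched) else tree
  tip_values <- lookup[normalize_name(pruned$tip.label)]
  names(tip_values) <- pruned$tip.label
  node_values <- squared_change_parsimony(pruned, tip_values)
  structure(list(tree = pruned, full_tree = tree, tip_values = tip_values,
                 node_values = node_values, unmatched_tips = unmatched),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("annotated tree: %d matched tips, %d internal nodes",
              length(x$tip_values), length(x$node_values)))
  if (length(x$unmatched_tips))
    cat(sprintf(", %d unmatched tips (%s%s)", length(x$unmatched_tips),
                paste(utils::head(x$unmatched_tips, 3), collapse = ", "),
                if (length(x$unmatched_tips) > 3) ", ..." else ""))
  cat("\n  tip value range:",
      paste(signif(range(x$tip_values), 4), collapse = " .. "), "\n")
  invisible(x)
}

# newick with FigTree-style [&value=x] node comments
annotated_newick_clade <- function(at, node) {
  tr <- at$tree
  n_tip <- length(tr$tip.label)
  if (node <= n_tip)
    return(sprintf("%s[&value=%.6g]", gsub(" ", "_", tr$tip.label[node]),
                   at$tip_values[[node]]))
  children <- tr$edge[tr$edge[, 1] == node, 2]
  sprintf("(%s)[&value=%.6g]",
          paste(vapply(children, function(ch)
            annotated_newick_clade(at, ch), character(1)), collapse = ","),
          at$node_values[[as.character(node)]])
}

#' Write an annotated tree
#'
#' Newick with `[&value=x]` comments on every node (FigTree-compatible),
#' plus a CSV of node values.
#'
#' @param at an `annotated_tree`.
#' @param newick_path,csv_path output paths (either may be `NULL`).
#' @return Invisibly, the Newick string.
#' @export
write_annotated_tree <- function(at, newick_path = NULL, csv_path = NULL) {
  root <- length(at$tree$tip.label) + 1L
  nwk <- paste0(annotated_newick_clade(at, root), ";")
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(csv_path)) {
    df <- rbind(
      data.frame(node_id = at$tree$tip.label,
                 type = "tip", value = unname(at$tip_values)),
      data.frame(node_id = paste0("node_", names(at$node_values)),
                 type = "internal", value = unname(at$node_values)))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(nwk)
}
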