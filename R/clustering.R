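#' Hierarchical variable clustering with deterministic leaf order
#'
#' Orders variables so that highly-correlated ones sit next to each other:
#' the column order of VISOVA displays and clustered heatmaps. Distances
#' default to `1 - r` (so anti-correlated variables land far apart);
#' `1 - |r|` is available when only the strength of association should
#' drive the layout. Agglomeration is implemented with explicit
#' tie-breaks so that the leaf order is identical across runs and
#' platforms:
#' * among tied minimum-distance merges, the pair whose clusters contain
#'   the lowest original variable indices merges first;
#' * each internal node puts the subtree with the smaller average
#'   original index on the left.
#'
#' Undefined correlation cells are resolved to 0 with a warning (one dead
#' variable must not abort a 150-variable report).
#'
#' @param corr a `corr_matrix`
#' @param linkage_method `"average"`, `"complete"` or `"ward"` (Ward on
#'   squared distances, as in `hclust(method = "ward.D2")`)
#' @param distance `"1-r"` or `"1-|r|"`
#' @return a `variable_ordering`: list with `variables` (input order),
#'   `leaf_order` (variable names in dendrogram order), `merge`
#'   (hclust-style merge matrix), `height`, `linkage_method`, `distance`
#' @export
cluster_variables <- function(corr,
                              linkage_method = c("average", "complete", "ward"),
                              distance = c("1-r", "1-|r|")) {
  linkage_method <- match.arg(linkage_method)
  distance <- match.arg(distance)
  vars <- corr$variables
  p <- length(vars)

  r <- corr$r
  if (any(corr$undefined)) {
    warn_viva("analytics", sprintf(
      "%d undefined correlation cell(s) treated as 0 for clustering",
      sum(corr$undefined & upper.tri(corr$undefined, diag = TRUE))))
    r[corr$undefined] <- 0
    diag(r) <- 1
  }
  d <- switch(distance, "1-r" = 1 - r, "1-|r|" = 1 - abs(r))

  if (p == 1L) {
    return(structure(list(variables = vars, leaf_order = vars,
                          leaf_index = 1L,
                          merge = matrix(integer(0), 0, 2),
                          height = numeric(0),
                          linkage_method = linkage_method,
                          distance = distance),
                     class = "variable_ordering"))
  }

  hc <- agglomerate(d, linkage_method)
  leaf_index <- order_leaves(hc$merge, p)
  structure(list(variables = vars, leaf_order = vars[leaf_index],
                 leaf_index = leaf_index,
                 merge = hc$merge, height = hc$height,
                 linkage_method = linkage_method, distance = distance),
            class = "variable_ordering")
}

# Agglomerative clustering via Lance-Williams updates on the full distance
# matrix, with lexicographic tie-breaking on the clusters' minimum original
# indices. O(p^3), fine at phenome scale (p ~ few hundred).
agglomerate <- function(d, linkage_method) {
  p <- nrow(d)
  work <- (d + t(d)) / 2   # guard against floating-point asymmetry
  if (linkage_method == "ward") work <- work^2
  diag(work) <- Inf
  active <- rep(TRUE, p)
  size <- rep(1, p)
  node <- -seq_len(p)            # hclust convention: negative = leaf
  minidx <- seq_len(p)           # smallest original index per cluster
  merge <- matrix(0L, p - 1L, 2L)
  height <- numeric(p - 1L)

  for (step in seq_len(p - 1L)) {
    w <- work
    w[!active, ] <- Inf
    w[, !active] <- Inf
    w[lower.tri(w, diag = TRUE)] <- Inf
    dmin <- min(w)
    cand <- which(w == dmin, arr.ind = TRUE)
    # tie-break: lowest pair of cluster minimum original indices
    key1 <- pmin(minidx[cand[, 1]], minidx[cand[, 2]])
    key2 <- pmax(minidx[cand[, 1]], minidx[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- min(cand[pick, ]); j <- max(cand[pick, ])

    height[step] <- if (linkage_method == "ward") sqrt(dmin) else dmin
    merge[step, ] <- sort_merge_pair(node[i], node[j])

    ni <- size[i]; nj <- size[j]
    others <- which(active); others <- others[others != i & others != j]
    for (k in others) {
      nk <- size[k]
      work[i, k] <- work[k, i] <- switch(linkage_method,
        average  = (ni * work[i, k] + nj * work[j, k]) / (ni + nj),
        complete = max(work[i, k], work[j, k]),
        ward     = ((ni + nk) * work[i, k] + (nj + nk) * work[j, k] -
                      nk * work[i, j]) / (ni + nj + nk))
    }
    active[j] <- FALSE
    size[i] <- ni + nj
    node[i] <- step
    minidx[i] <- min(minidx[i], minidx[j])
  }
  list(merge = merge, height = height)
}

# hclust writes leaf (negative) before node, else ascending
sort_merge_pair <- function(a, b) {
  if (a < 0 && b > 0) c(a, b)
  else if (a > 0 && b < 0) c(b, a)
  else sort(c(a, b))
}

# leaf order: recursive traversal putting the subtree with the smaller
# average original index on the left (ties: smaller minimum index)
order_leaves <- function(merge, p) {
  leaves_of <- vector("list", nrow(merge))
  get_leaves <- function(id) if (id < 0) -id else leaves_of[[id]]
  for (s in seq_len(nrow(merge))) {
    a <- get_leaves(merge[s, 1]); b <- get_leaves(merge[s, 2])
    ka <- c(mean(a), min(a)); kb <- c(mean(b), min(b))
    left_first <- ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] <= kb[2])
    leaves_of[[s]] <- if (left_first) c(a, b) else c(b, a)
  }
  as.integer(leaves_of[[nrow(merge)]])
}

#' @export
print.variable_ordering <- function(x, ...) {
  cat(sprintf("<variable_ordering> %d variables, %s linkage on %s\n",
              length(x$variables), x$linkage_method, x$distance))
  cat("leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a variable ordering to an hclust object
#' @param ordering a `variable_ordering` with >= 2 variables
#' @return a `stats::hclust` object
#' @export
as_hclust <- function(ordering) {
  if (length(ordering$variables) < 2L)
    stop_viva("analytics", "need at least 2 variables for an hclust tree")
  structure(list(merge = ordering$merge, height = ordering$height,
                 order = ordering$leaf_index,
                 labels = ordering$variables,
                 method = ordering$linkage_method,
                 call = NULL, dist.method = ordering$distance),
            class = "hclust")
}

#' Export a variable ordering's linkage as a table
#'
#' One row per merge: `child1`, `child2` (negative = leaf index, positive
#' = earlier merge row), `height`, `size` (leaves under the merge) — the
#' standard encoding of agglomerative linkage.
#'
#' @param ordering a `variable_ordering`
#' @export
linkage_table <- function(ordering) {
  m <- ordering$merge
  size <- numeric(nrow(m))
  sz <- function(id) if (id < 0) 1 else size[id]
  for (s in seq_len(nrow(m))) size[s] <- sz(m[s, 1]) + sz(m[s, 2])
  data.frame(child1 = m[, 1], child2 = m[, 2],
             height = ordering$height, size = as.integer(size))
}

#' Export a variable ordering's dendrogram as Newick
#' @param ordering a `variable_ordering` with >= 2 variables
#' @return a single Newick string
#' @export
as_newick <- function(ordering) {
  ape::write.tree(ape::as.phylo(as_hclust(ordering)))
}
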