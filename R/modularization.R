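# Modularization: flux-pattern matrices and hierarchical clustering of
# flux-variation patterns.

#' Convert a flux matrix to a flux-pattern matrix
#'
#' Encodes, for each reaction, whether the flux rises (+1), falls (-1) or
#' stays the same (0, within `tol`) between consecutive samples after the
#' columns are reordered by `permutation`. An N x M matrix yields an
#' N x (M-1) pattern matrix.
#'
#' @param values numeric matrix, reactions x samples.
#' @param permutation integer column order (a bijection on `1:ncol`); default
#'   identity.
#' @param tol tie tolerance on flux differences.
#' @return integer matrix with entries in `{-1, 0, 1}`.
#' @export
to_flux_pattern <- function(values, permutation = seq_len(ncol(values)),
                            tol = FMB_ZERO_TOL) {
  M <- ncol(values)
  if (length(permutation) != M || !setequal(permutation, seq_len(M)))
    stop_fmb("permutation must be a bijection on 1..%d", M)
  v <- values[, permutation, drop = FALSE]
  d <- v[, -1, drop = FALSE] - v[, -M, drop = FALSE]
  p <- sign(d)
  p[abs(d) <= tol] <- 0L
  storage.mode(p) <- "integer"
  rownames(p) <- rownames(values)
  p
}

# Random permutations for pattern generation, reproducible from `seed`.
pattern_permutations <- function(M, n_perms, seed) {
  with_seed(seed, lapply(seq_len(n_perms), function(i) sample.int(M)))
}

#' Adjoin flux-pattern matrices over random sample orders
#'
#' The pattern of a row depends on the sample order, so `n_perms` independent
#' uniformly random column permutations are drawn and their pattern matrices
#' concatenated horizontally, giving an N x `n_perms`*(M-1) matrix whose row
#' distances average out the arbitrariness of any single ordering.
#'
#' @param values numeric matrix, reactions x samples.
#' @param n_perms number of adjoined pattern matrices.
#' @param seed integer seed for the permutations.
#' @param permutations optional explicit list of permutations (overrides
#'   `n_perms`/`seed`), used mainly for testing.
#' @inheritParams to_flux_pattern
#' @return integer matrix with entries in `{-1, 0, 1}`.
#' @export
build_adjoined_pattern <- function(values, n_perms = 300, seed = 1,
                                   permutations = NULL, tol = FMB_ZERO_TOL) {
  if (is.null(permutations))
    permutations <- pattern_permutations(ncol(values), n_perms, seed)
  do.call(cbind, lapply(permutations, function(p) to_flux_pattern(values, p, tol)))
}

#' Pairwise pattern distances without materializing the adjoined matrix
#'
#' Squared Euclidean distances are additive across the concatenated
#' permutation blocks, so the full adjoined matrix (which for 300
#' permutations of 2000 samples has ~600k columns) never needs to exist at
#' once. Results are identical to `dist(build_adjoined_pattern(...))`.
#'
#' @inheritParams build_adjoined_pattern
#' @return a `stats::dist` object over the rows of `values`.
#' @export
pattern_dist <- function(values, n_perms = 300, seed = 1, permutations = NULL,
                         tol = FMB_ZERO_TOL) {
  if (is.null(permutations))
    permutations <- pattern_permutations(ncol(values), n_perms, seed)
  acc <- NULL
  for (p in permutations) {
    d2 <- stats::dist(to_flux_pattern(values, p, tol))^2
    acc <- if (is.null(acc)) d2 else acc + d2
  }
  sqrt(acc)
}

#' Inconsistency coefficient of hierarchical-clustering links
#'
#' For each merge of the dendrogram, compares its height with the heights of
#' the links up to `depth` levels below it (the link itself and, at the
#' default depth 2, its direct child links): the coefficient is
#' `(h - mean(heights)) / sd(heights)`, and 0 when all those heights are
#' equal. Links joining two singletons have coefficient 0.
#'
#' @param hc an object of class `hclust`.
#' @param depth number of link generations included, >= 1.
#' @return numeric vector, one coefficient per merge.
#' @export
inconsistency_coefficient <- function(hc, depth = 2) {
  n_links <- nrow(hc$merge)
  below <- function(k, d) {
    # links within d generations below (and including) link k
    if (d == 0) return(integer(0))
    kids <- hc$merge[k, ]
    kids <- kids[kids > 0]
    c(k, unlist(lapply(kids, below, d = d - 1)))
  }
  vapply(seq_len(n_links), function(k) {
    hs <- hc$height[below(k, depth)]
    if (length(hs) < 2) return(0)
    s <- stats::sd(hs)
    if (s == 0) 0 else (hc$height[k] - mean(hs)) / s
  }, numeric(1))
}

# Cut the tree on the inconsistency coefficient: a link survives when its
# coefficient is <= cutoff and every link below it survives too; clusters are
# the leaf sets connected by surviving links.
cut_inconsistent <- function(hc, inc, cutoff) {
  n <- length(hc$order)
  keep <- logical(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    kids_ok <- all(keep[kids[kids > 0]])
    keep[k] <- kids_ok && inc[k] <= cutoff
  }
  # union-find over leaves through surviving links
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  leaf_of <- function(node) if (node < 0) -node else leftmost[node]
  leftmost <- integer(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]
    leftmost[k] <- if (a < 0) -a else leftmost[a]
    if (keep[k]) {
      la <- leaf_of(hc$merge[k, 1]); lb <- leaf_of(hc$merge[k, 2])
      parent[find(lb)] <- find(la)
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Hierarchically cluster reactions into metabolic modules
#'
#' Average-linkage agglomeration on Euclidean distances between
#' flux-pattern rows, cut where the link inconsistency coefficient exceeds
#' `cutoff` (criterion `"inconsistent"`, depth 2) or at raw merge height
#' `cutoff` (criterion `"distance"`). Clusters are numbered 1..C in
#' ascending order of their smallest member row index, so numbering is
#' deterministic. Singleton input yields one singleton cluster.
#'
#' @param x a pattern matrix (rows clustered) or a precomputed `dist`.
#' @param cutoff cut threshold (default 1.0).
#' @param criterion `"inconsistent"` or `"distance"`.
#' @param depth inconsistency depth.
#' @param labels row labels when `x` is a `dist` without labels.
#' @return object of class `fmb_clusters`: list with `assignment` (named
#'   integer vector), `hclust`, `inconsistency`, `n_clusters`.
#' @export
hierarchical_cluster <- function(x, cutoff = 1.0,
                                 criterion = c("inconsistent", "distance"),
                                 depth = 2, labels = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(x, "dist")) {
    d <- x
    labels <- labels %||% attr(d, "Labels")
  } else {
    if (nrow(x) == 1) {
      assign <- stats::setNames(1L, rownames(x))
      return(structure(list(assignment = assign, hclust = NULL,
                            inconsistency = numeric(0), n_clusters = 1L),
                       class = "fmb_clusters"))
    }
    d <- stats::dist(x)
    labels <- labels %||% rownames(x)
  }
  hc <- stats::hclust(d, method = "average")
  inc <- inconsistency_coefficient(hc, depth)
  raw <- if (criterion == "inconsistent") cut_inconsistent(hc, inc, cutoff)
         else stats::cutree(hc, h = cutoff)
  # renumber ascending by smallest member index
  first <- vapply(split(seq_along(raw), raw), min, 1L)
  newid <- stats::setNames(rank(first), names(first))
  assign <- as.integer(newid[as.character(raw)])
  names(assign) <- labels
  structure(list(assignment = assign, hclust = hc, inconsistency = inc,
                 n_clusters = max(assign)),
            class = "fmb_clusters")
}

#' @export
print.fmb_clusters <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("fmb_clusters: %d reactions in %d clusters (sizes %d..%d)\n",
              length(x$assignment), x$n_clusters, min(sizes), max(sizes)))
  invisible(x)
}

#' Reinsert collapsed duplicate reactions into their clusters
#'
#' Each removed duplicate joins the cluster of its retained representative.
#'
#' @param clusters an `fmb_clusters` over core reactions.
#' @param duplicate_groups as returned inside [select_core()]
#'   (representative id -> member ids).
#' @return an `fmb_clusters` with the enlarged assignment.
#' @export
reinsert_duplicates <- function(clusters, duplicate_groups) {
  assign <- clusters$assignment
  for (rep_id in names(duplicate_groups)) {
    if (!rep_id %in% names(assign))
      stop_fmb("duplicate-group representative '%s' is not clustered", rep_id)
    members <- duplicate_groups[[rep_id]]
    assign[members] <- assign[[rep_id]]
  }
  clusters$assignment <- assign
  clusters
}

#' Write the cluster roster as TSV
#'
#' @param clusters an `fmb_clusters` (after [reinsert_duplicates()]).
#' @param duplicate_groups the duplicate bookkeeping from [select_core()].
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, duplicate_groups, path) {
  ids <- names(clusters$assignment)
  rep_of <- rep(NA_character_, length(ids)); names(rep_of) <- ids
  for (r in names(duplicate_groups)) rep_of[duplicate_groups[[r]]] <- r
  df <- data.frame(reaction_id = ids, cluster_id = clusters$assignment,
                   is_duplicate = !is.na(rep_of), representative_id = rep_of,
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, df$reaction_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
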