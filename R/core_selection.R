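# Core-reaction selection: perturbation-responsive, almost-always-active,
# duplicate-collapsed reactions of the flux matrix.

#' Paired t-test of perturbation response per reaction
#'
#' Pairs the i-th control sample with the i-th perturbed sample and computes
#' the two-sided paired t-test p-value of the per-sample flux differences for
#' every reaction. Reactions whose differences are identically zero are
#' untouched by the perturbation and get p = 1; a constant non-zero
#' difference gets p = 0.
#'
#' @param fm an `fmb_flux_matrix` with equally many columns per condition.
#' @param conditions length-2 character naming the two compared conditions.
#' @return named numeric vector of p-values, one per reaction.
#' @export
paired_t_test <- function(fm, conditions = c("control", "perturbed")) {
  a <- fm$values[, fm$conditions == conditions[1], drop = FALSE]
  b <- fm$values[, fm$conditions == conditions[2], drop = FALSE]
  if (ncol(a) != ncol(b))
    stop_fmb("paired t-test needs equal sample counts per condition (%d vs %d)",
             ncol(a), ncol(b))
  if (ncol(a) < 2) stop_fmb("paired t-test needs at least 2 samples per condition")
  d <- a - b
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (ncol(d) - 1))
  tt <- m / (s / sqrt(ncol(d)))
  p <- 2 * stats::pt(-abs(tt), df = ncol(d) - 1)
  # differences constant at numerical noise level: untouched (p = 1) when the
  # mean shift is also below the zero tolerance, certain shift (p = 0) otherwise
  degen <- s <= FMB_ZERO_TOL
  p[degen] <- ifelse(abs(m[degen]) <= FMB_ZERO_TOL, 1, 0)
  stats::setNames(p, rownames(fm$values))
}

#' Fraction of samples in which each reaction is active
#'
#' @param fm an `fmb_flux_matrix`.
#' @param condition condition label.
#' @param tol absolute flux threshold below which a flux counts as zero.
#' @return named numeric vector in `[0, 1]`.
#' @export
activity_fraction <- function(fm, condition, tol = FMB_ZERO_TOL) {
  if (!condition %in% fm$conditions)
    stop_fmb("condition '%s' not present in flux matrix", condition)
  v <- fm$values[, fm$conditions == condition, drop = FALSE]
  rowMeans(abs(v) > tol)
}

#' Group duplicate reactions
#'
#' Duplicate reactions carry exactly the same flux value in every sample
#' (stoichiometrically coupled); they add no statistical information. Rows
#' are grouped when their max-norm distance is at most `tol`, closed
#' transitively; each group's representative is its lexicographically
#' smallest reaction id.
#'
#' @param values numeric matrix, reactions in rows (with rownames).
#' @param tol max-norm equality tolerance.
#' @return named list: representative id -> character vector of the other
#'   member ids (groups of size one are omitted).
#' @export
find_duplicates <- function(values, tol = 1e-9) {
  n <- nrow(values)
  ids <- rownames(values)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(values[i, ] - values[j, ])) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(ids, roots)
  groups <- groups[vapply(groups, length, 1L) > 1]
  out <- stats::setNames(list(), character(0))
  for (g in groups) {
    g <- sort(g)
    out[[g[1]]] <- g[-1]
  }
  out[order(names(out))]
}

#' Select core reactions from a flux matrix
#'
#' Applies, in order: (1) significance filter, keeping reactions whose
#' paired-t p-value is below `p_thresh`; (2) activity filter, keeping
#' reactions with non-zero flux in strictly more than `act_thresh` of the
#' samples of at least one condition; (3) duplicate collapse, keeping one
#' representative per group of identical rows. Removed duplicates are kept in
#' the bookkeeping so they can be reinserted into their representative's
#' cluster later.
#'
#' @param fm an `fmb_flux_matrix`.
#' @param p_thresh significance threshold on the paired-t p-value.
#' @param act_thresh activity-fraction threshold (strict inequality).
#' @param dup_tol max-norm tolerance for duplicate rows.
#' @param conditions the two condition labels.
#' @return an object of class `fmb_core`: list with `p_values`, `activity`
#'   (matrix reaction x condition), `duplicate_groups`, `core_ids`,
#'   `reduced` (an `fmb_flux_matrix` restricted to core rows) and `counts`
#'   (sizes after each filter stage).
#' @export
select_core <- function(fm, p_thresh = 1e-2, act_thresh = 0.95, dup_tol = 1e-9,
                        conditions = c("control", "perturbed")) {
  p <- paired_t_test(fm, conditions)
  act <- vapply(conditions, function(cc) activity_fraction(fm, cc), numeric(nrow(fm$values)))
  rownames(act) <- rownames(fm$values)

  sig_ids <- names(p)[p < p_thresh]
  active_ids <- sig_ids[apply(act[sig_ids, , drop = FALSE] > act_thresh, 1, any)]
  dup <- find_duplicates(fm$values[active_ids, , drop = FALSE], tol = dup_tol)
  drop <- unlist(dup, use.names = FALSE)
  core_ids <- setdiff(active_ids, drop)
  if (!length(core_ids))
    stop_fmb("no core reactions: every reaction failed the significance/activity filters")

  reduced <- fm
  reduced$values <- fm$values[core_ids, , drop = FALSE]
  reduced$reaction_ids <- core_ids
  structure(list(p_values = p, activity = act, duplicate_groups = dup,
                 core_ids = core_ids, reduced = reduced,
                 counts = c(initial = nrow(fm$values),
                            significant = length(sig_ids),
                            active = length(active_ids),
                            core = length(core_ids))),
            class = "fmb_core")
}

#' @export
print.fmb_core <- function(x, ...) {
  cat(sprintf("fmb_core: %d -> %d -> %d -> %d reactions (significance, activity, duplicate collapse)\n",
              x$counts["initial"], x$counts["significant"], x$counts["active"], x$counts["core"]))
  invisible(x)
}

#' Write the per-reaction core-selection table
#'
#' @param core an `fmb_core`.
#' @param path TSV output path.
#' @export
write_core_table <- function(core, path) {
  ids <- names(core$p_values)
  rep_of <- rep(NA_character_, length(ids)); names(rep_of) <- ids
  for (r in names(core$duplicate_groups)) rep_of[core$duplicate_groups[[r]]] <- r
  df <- data.frame(reaction_id = ids, p_value = core$p_values,
                   activity_control = core$activity[, 1],
                   activity_perturbed = core$activity[, 2],
                   is_core = ids %in% core$core_ids,
                   duplicate_of = rep_of, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
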