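# Reaction essentiality by single-deletion flux balance analysis.

# Build per-reaction bounds with measured constraints relaxed to
# [mean - sigma, mean + sigma] intervals (intersected with model bounds).
# The growth-rate measurement (any constraint on the biomass reaction) is
# dropped: with growth pinned, deletion growth would be trivially fixed.
constrained_bounds <- function(model, constraints, condition) {
  lower <- model$lower; upper <- model$upper
  if (!is.null(constraints) && nrow(constraints)) {
    sub <- constraints_for(constraints, condition, model)
    sub <- sub[sub$reaction_id != (model$biomass_id %||% ""), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      id <- sub$reaction_id[i]
      lower[id] <- max(lower[id], sub$mean[i] - sub$sigma[i])
      upper[id] <- min(upper[id], sub$mean[i] + sub$sigma[i])
      if (lower[id] > upper[id])
        stop_fmb("constraint interval for '%s' incompatible with model bounds", id)
    }
  }
  list(lower = lower, upper = upper)
}

#' Maximum growth rate by flux balance analysis
#'
#' Maximizes the biomass flux subject to mass balance, model bounds, and the
#' experimental constraints fixed to their `mean +/- sigma` intervals (no
#' randomization). The growth-rate measurement itself is removed from the
#' constraint set for this computation.
#'
#' @param model an [fmb_model] with a biomass reaction.
#' @param constraints optional [fmb_constraints].
#' @param condition condition whose constraints apply.
#' @return maximal growth rate (1/h equivalent of the biomass flux).
#' @export
max_growth <- function(model, constraints = NULL, condition = "control") {
  if (is.na(model$biomass_id)) stop_fmb("model has no biomass reaction")
  bds <- constrained_bounds(model, constraints, condition)
  obj <- as.numeric(model$reactions == model$biomass_id)
  sol <- solve_lp(obj, model$S, rep(0, nrow(model$S)), bds$lower, bds$upper,
                  maximize = TRUE)
  if (sol$status != "optimal")
    stop_fmb("growth FBA %s under '%s' constraints", sol$status, condition)
  sol$value
}

#' Essentiality of a single reaction
#'
#' Removes the reaction (both bounds set to zero), recomputes the maximal
#' growth rate, and scales it against the intact reference:
#' `e = clamp(1 - g_deletion / g_reference, 0, 1)`. Essentiality 0 means the
#' deletion leaves growth unchanged; 1 means growth stops entirely (an
#' infeasible deletion problem also scores 1).
#'
#' @inheritParams max_growth
#' @param reaction_id reaction to delete.
#' @param g_ref optional precomputed reference growth (> 0).
#' @return essentiality in `[0, 1]`.
#' @export
reaction_essentiality <- function(model, constraints = NULL, condition = "control",
                                  reaction_id, g_ref = NULL) {
  if (!reaction_id %in% model$reactions)
    stop_fmb("unknown reaction '%s'", reaction_id)
  if (is.null(g_ref)) g_ref <- max_growth(model, constraints, condition)
  if (g_ref <= 0) stop_fmb("reference growth rate is zero; essentiality undefined")
  g_del <- tryCatch(max_growth(apply_knockout(model, reaction_id), constraints, condition),
                    error = function(e) 0)
  min(1, max(0, 1 - g_del / g_ref))
}

#' Essentiality table over all reactions and conditions
#'
#' Computes per-condition essentiality for every reaction of the model
#' (under the perturbed condition the knockout reactions are removed from
#' the reference model first), plus unweighted cluster means when a cluster
#' assignment is supplied.
#'
#' @param model an [fmb_model].
#' @param constraints an [fmb_constraints] (may be `NULL`).
#' @param perturbation knockouts defining the perturbed reference model.
#' @param clusters optional `fmb_clusters`; enables cluster averages.
#' @param conditions condition labels (first = control).
#' @return list with `table` (`data.frame`: reaction_id, condition, g_ref,
#'   g_del, essentiality, cluster_id), `cluster_means` and `overall_means`
#'   (named by condition).
#' @export
essentiality_table <- function(model, constraints = NULL,
                               perturbation = fmb_perturbation(), clusters = NULL,
                               conditions = c("control", "perturbed")) {
  assign <- if (!is.null(clusters)) clusters$assignment else NULL
  rows <- list()
  for (cond in conditions) {
    ref_model <- if (cond == conditions[1]) model else apply_knockout(model, perturbation)
    g_ref <- max_growth(ref_model, constraints, cond)
    g_del <- vapply(model$reactions, function(rid) {
      tryCatch(max_growth(apply_knockout(ref_model, rid), constraints, cond),
               error = function(e) 0)
    }, numeric(1))
    ess <- pmin(1, pmax(0, 1 - g_del / g_ref))
    rows[[cond]] <- data.frame(
      reaction_id = model$reactions, condition = cond, g_ref = g_ref,
      g_del = g_del, essentiality = ess,
      cluster_id = if (is.null(assign)) NA_integer_
                   else unname(assign[model$reactions]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  overall <- vapply(conditions, function(cc)
    mean(tab$essentiality[tab$condition == cc]), numeric(1))
  cluster_means <- NULL
  if (!is.null(assign)) {
    sub <- tab[!is.na(tab$cluster_id), ]
    cluster_means <- stats::aggregate(essentiality ~ condition + cluster_id,
                                      data = sub, FUN = mean)
  }
  list(table = tab, cluster_means = cluster_means, overall_means = overall)
}
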