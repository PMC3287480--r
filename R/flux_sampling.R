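# Flux-matrix generation: randomized experimental targets reconciled by
# least-absolute-deviation constraint-based flux analysis.

#' Draw randomized constraint targets
#'
#' For every measured reaction of one condition, draws a target flux from a
#' normal distribution centred on the measured mean, truncated (by rejection
#' sampling) to within one standard deviation of it, so random errors never
#' exceed the reported measurement error. `sigma = 0` degenerates to the mean.
#'
#' @param constraints an [fmb_constraints] table (see [load_constraints()]).
#' @param condition condition label to draw for.
#' @param seed integer seed; draws are reproducible given the seed.
#' @return `data.frame` with columns `reaction_id`, `class`, `mean`, `sigma`,
#'   `target`.
#' @export
draw_constraint_targets <- function(constraints, condition, seed) {
  sub <- constraints_for(constraints, condition)
  if (!nrow(sub) && nrow(constraints) && !condition %in% constraints$condition)
    stop_fmb("condition '%s' not present in constraint table", condition)
  targets <- with_seed(seed, vapply(seq_len(nrow(sub)), function(i) {
    mu <- sub$mean[i]; sg <- sub$sigma[i]
    if (sg == 0) return(mu)
    repeat {
      x <- stats::rnorm(1, mu, sg)
      if (abs(x - mu) <= sg) return(x)
    }
  }, numeric(1)))
  data.frame(reaction_id = sub$reaction_id, class = sub$class,
             mean = sub$mean, sigma = sub$sigma,
             target = if (nrow(sub)) targets else numeric(0),
             stringsAsFactors = FALSE)
}

#' Solve one least-absolute-deviation flux reconciliation
#'
#' Finds the steady-state flux distribution closest (in L1 distance) to the
#' randomized experimental targets: minimizes
#' `sum_k |v_k - target_k|` subject to `S v = 0` and bound constraints,
#' via the standard positive/negative deviation-variable LP. Because the LAD
#' optimum can be degenerate in the unmeasured fluxes, a secondary LP then
#' holds the measured fluxes at their achieved values and minimizes
#' `sum_j |v_j|` (parsimonious flux distribution), making the returned vector
#' a deterministic function of the targets.
#'
#' @param model an [fmb_model].
#' @param targets output of [draw_constraint_targets()], or a `data.frame`
#'   with columns `reaction_id` and `target`.
#' @return list with `fluxes` (named vector), `residual` (achieved L1
#'   deviation) and `targets`.
#' @export
solve_lad_fba <- function(model, targets) {
  missing <- setdiff(targets$reaction_id, model$reactions)
  if (length(missing))
    stop_fmb("target reaction(s) not in model: %s", paste(missing, collapse = ", "))
  n <- length(model$reactions)
  K <- nrow(targets)
  kidx <- match(targets$reaction_id, model$reactions)

  # variables: v (n), then d+ and d- per target
  n_all <- n + 2 * K
  A_eq <- cbind(model$S, matrix(0, nrow(model$S), 2 * K))
  b_eq <- rep(0, nrow(model$S))
  if (K) {
    dev <- matrix(0, K, n_all)
    dev[cbind(seq_len(K), kidx)] <- 1
    dev[cbind(seq_len(K), n + seq_len(K))] <- -1
    dev[cbind(seq_len(K), n + K + seq_len(K))] <- 1
    A_eq <- rbind(A_eq, dev)
    b_eq <- c(b_eq, targets$target)
  }
  obj <- c(rep(0, n), rep(1, 2 * K))
  lower <- c(model$lower, rep(0, 2 * K))
  upper <- c(model$upper, rep(Inf, 2 * K))
  sol <- solve_lp(obj, A_eq, b_eq, lower, upper)
  if (sol$status != "optimal")
    stop_fmb("LAD flux reconciliation %s: S v = 0 has no solution within bounds%s",
             sol$status,
             if (K) sprintf(" (constrained reactions: %s)",
                            paste(targets$reaction_id, collapse = ", ")) else "")
  v1 <- sol$x[seq_len(n)]
  residual <- sol$value

  # secondary parsimonious LP: fix achieved measured fluxes, min sum |v|;
  # exactly met targets are snapped to the target value so solver epsilon
  # never leaks into downstream equality comparisons
  hit <- abs(v1[kidx] - targets$target) <= 1e-9
  v1[kidx[hit]] <- targets$target[hit]
  lower2 <- model$lower; upper2 <- model$upper
  lower2[kidx] <- upper2[kidx] <- v1[kidx]
  n2 <- 3 * n
  A2 <- cbind(model$S, matrix(0, nrow(model$S), 2 * n))
  abs_rows <- cbind(diag(n), -diag(n), diag(n))   # v - e+ + e- = 0
  A2 <- rbind(A2, abs_rows)
  b2 <- c(rep(0, nrow(model$S)), rep(0, n))
  sol2 <- solve_lp(c(rep(0, n), rep(1, 2 * n)), A2, b2,
                   c(lower2, rep(0, 2 * n)), c(upper2, rep(Inf, 2 * n)))
  v <- if (sol2$status == "optimal") sol2$x[seq_len(n)] else v1
  names(v) <- model$reactions
  list(fluxes = v, residual = residual, targets = targets)
}

#' Sample a flux matrix under control and perturbed conditions
#'
#' Repeats randomized-target LAD reconciliation `n_per_condition` times for
#' the control condition (unmodified model) and for the perturbed condition
#' (model after [apply_knockout()]), and merges all columns into one
#' reactions x samples flux matrix. Per-column seeds are derived
#' deterministically from `master_seed` and the (condition, index) pair, so
#' either condition can be regenerated independently.
#'
#' @param model an [fmb_model].
#' @param constraints an [fmb_constraints] table with both conditions.
#' @param perturbation an [fmb_perturbation] (or character vector of knockout
#'   reaction ids) applied under the perturbed condition.
#' @param n_per_condition samples per condition (>= 2).
#' @param master_seed integer master seed.
#' @param conditions length-2 character, condition labels in sampling order.
#' @return an object of class `fmb_flux_matrix`: list with `values`
#'   (N x 2n matrix), `conditions` (per-column labels), `master_seed`.
#' @export
sample_flux_matrix <- function(model, constraints, perturbation = fmb_perturbation(),
                               n_per_condition, master_seed,
                               conditions = c("control", "perturbed")) {
  if (n_per_condition < 2) stop_fmb("n_per_condition must be >= 2")
  models <- list(model, apply_knockout(model, perturbation))
  cols <- vector("list", 2 * n_per_condition)
  lab <- character(2 * n_per_condition)
  resid <- numeric(2 * n_per_condition)
  k <- 0
  for (ci in 1:2) {
    cond <- conditions[ci]
    for (i in seq_len(n_per_condition)) {
      k <- k + 1
      tg <- draw_constraint_targets(constraints, cond, derive_seed(master_seed, cond, i))
      sol <- tryCatch(solve_lad_fba(models[[ci]], tg),
                      error = function(e) stop_fmb("sample %d (%s): %s", i, cond,
                                                   conditionMessage(e)))
      cols[[k]] <- sol$fluxes
      resid[k] <- sol$residual
      lab[k] <- cond
    }
  }
  values <- do.call(cbind, cols)
  values[abs(values) < FMB_ZERO_TOL] <- 0   # zero-tolerance rule for downstream stages
  colnames(values) <- paste0(lab, ":", c(seq_len(n_per_condition), seq_len(n_per_condition)))
  structure(list(values = values, reaction_ids = model$reactions,
                 conditions = lab, residuals = resid,
                 master_seed = master_seed),
            class = "fmb_flux_matrix")
}

#' @export
print.fmb_flux_matrix <- function(x, ...) {
  cat(sprintf("fmb_flux_matrix: %d reactions x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", unique(x$conditions),
                            table(x$conditions)[unique(x$conditions)]), collapse = ", ")))
  invisible(x)
}

#' Write / read a flux matrix as TSV
#'
#' Reactions in rows, samples in columns; the header row carries
#' `condition:index` sample labels.
#' @param fm an `fmb_flux_matrix`.
#' @param path file path.
#' @export
write_flux_tsv <- function(fm, path) {
  df <- data.frame(reaction_id = rownames(fm$values) %||% fm$reaction_ids,
                   fm$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
read_flux_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$reaction_id
  lab <- sub(":.*$", "", colnames(values))
  structure(list(values = values, reaction_ids = df$reaction_id,
                 conditions = lab, residuals = NULL, master_seed = NA_integer_),
            class = "fmb_flux_matrix")
}
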