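# Synthetic fixtures: branched toy metabolic models with designed module
# structure, and discrete Bayesian-network data simulators.

#' Specification for a synthetic branched toy model
#'
#' Describes a model in which a single substrate uptake splits into
#' `n_modules` parallel linear chains that reconverge on one biomass
#' precursor. Each chain is stoichiometrically coupled, so its reactions are
#' a designed module with within-module flux correlation exactly 1; the
#' branch-split reactions carry experimental constraints with non-zero sigma
#' so randomized targets drive anticorrelated variation across modules.
#' The perturbed condition knocks out the first chain's branch reaction and
#' shifts the measured means so flux reroutes through the sibling chains.
#'
#' @param n_modules number of parallel chains (>= 2).
#' @param reactions_per_module reactions per chain (>= 2).
#' @param sigma_scale relative measurement error of the branch constraints.
#' @param uptake total substrate uptake rate (mmol/gDCW/h, positive number;
#'   the uptake exchange flux is its negative).
#' @return a `toy_model_spec` list.
#' @export
toy_model_spec <- function(n_modules = 3, reactions_per_module = 4,
                           sigma_scale = 0.1, uptake = 3) {
  if (n_modules < 2) stop_fmb("need at least 2 modules")
  if (reactions_per_module < 2) stop_fmb("need at least 2 reactions per module")
  structure(list(n_modules = n_modules,
                 reactions_per_module = reactions_per_module,
                 sigma_scale = sigma_scale, uptake = uptake),
            class = "toy_model_spec")
}

#' Build the synthetic toy model, constraints and ground truth
#'
#' Constructs the model of a [toy_model_spec()] together with a two-condition
#' constraint table and the ground truth used to score pipeline recovery.
#' Design of the constraints: the uptake exchange and the growth rate are
#' measured exactly (`sigma = 0`), so these pseudo-reactions are pinned and
#' provably untouched by the perturbation; every chain's branch reaction
#' except the last carries a noisy measurement (the last chain is the
#' unmeasured slack route), so each randomized target set is exactly
#' achievable and the LAD residual is zero. Under the perturbed condition the
#' first branch is knocked out (and measured as zero, as a knockout flux
#' would be) and the remaining measured branches absorb its share.
#'
#' @param spec a [toy_model_spec()].
#' @return list with `model` ([fmb_model]), `constraints`
#'   ([fmb_constraints]-style `data.frame`), `perturbation`
#'   ([fmb_perturbation]), `truth` (list: `module_of` named labels for chain
#'   reactions, `responsive` expected core set, `knockout`).
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  nm <- spec$n_modules; rp <- spec$reactions_per_module
  rows <- list()
  add <- function(id, eq, lb, ub, sub) rows[[length(rows) + 1]] <<-
    data.frame(reaction_id = id, equation = eq, lower_bound = lb,
               upper_bound = ub, subsystem = sub, stringsAsFactors = FALSE)
  U <- spec$uptake
  add("EX_glc", "Sx <->", -10 * U, 0, "Exchange")
  add("UPT", "Sx -> S", 0, 10 * U, "Transport")
  module_of <- character(0)
  for (mi in seq_len(nm)) {
    mets <- c("S", paste0("M", mi, "_", seq_len(rp - 1)), "P")
    for (ri in seq_len(rp)) {
      id <- sprintf("M%d_r%d", mi, ri)
      # the penultimate reaction doubles its product so the last chain
      # reaction carries twice the branch flux: correlated but not duplicate
      coef <- if (ri == rp - 1) "2 " else ""
      eq <- sprintf("%s -> %s%s", mets[ri], coef, mets[ri + 1])
      add(id, eq, 0, 10 * U, sprintf("Module%d", mi))
      module_of[id] <- sprintf("module%d", mi)
    }
  }
  add("BIOMASS", "P -> Bx", 0, 100 * U, "Biomass")
  add("EX_bio", "Bx ->", 0, 100 * U, "Exchange")
  df <- do.call(rbind, rows)

  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(tsv))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  model <- read_model_tsv(tsv)

  growth <- 2 * U          # last chain step doubles flux; biomass collects it
  branch_ids <- sprintf("M%d_r1", seq_len(nm))
  share <- U / nm
  sg <- spec$sigma_scale * share
  con <- list()
  crow <- function(id, cond, mu, sigma, cls) con[[length(con) + 1]] <<-
    data.frame(reaction_id = id, condition = cond, mean = mu, sigma = sigma,
               class = cls, stringsAsFactors = FALSE)
  for (cond in c("control", "perturbed")) {
    crow("EX_glc", cond, -U, 0, "FMT")
    crow("BIOMASS", cond, growth, 0, "FMT")
  }
  # measured branches: all but the slack (last) chain
  for (mi in seq_len(nm - 1)) {
    crow(branch_ids[mi], "control", share, sg, "C13")
    if (mi == 1) crow(branch_ids[mi], "perturbed", 0, 0, "C13")
    else crow(branch_ids[mi], "perturbed", U / (nm - 1), sg * 1.5, "C13")
  }
  constraints <- do.call(rbind, con)
  class(constraints) <- c("fmb_constraints", "data.frame")

  perturbation <- fmb_perturbation(branch_ids[1], label = "branch-1 knockout")
  truth <- list(module_of = module_of,
                responsive = names(module_of),
                knockout = branch_ids[1])
  list(model = model, constraints = constraints, perturbation = perturbation,
       truth = truth)
}

#' Write the toy fixture to disk as ordinary pipeline inputs
#'
#' Emits `model.tsv`, `constraints.csv` and `truth.json` so tests and runs
#' exercise the real file-reading paths.
#'
#' @param spec a [toy_model_spec()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_toy_fixture <- function(spec = toy_model_spec(), dir) {
  fx <- make_toy_model(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_tsv(fx$model, file.path(dir, "model.tsv"))
  utils::write.csv(fx$constraints, file.path(dir, "constraints.csv"), row.names = FALSE)
  jsonlite::write_json(list(module_of = as.list(fx$truth$module_of),
                            responsive = fx$truth$responsive,
                            knockout = fx$truth$knockout),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Simulate a discrete dataset from a known Bayesian network
#'
#' Ancestral sampling: nodes are visited in topological order and each state
#' is drawn from the node's conditional probability table given the sampled
#' parent states.
#'
#' @param adj DAG adjacency matrix with dimnames (`adj[i,j]=1` for i -> j).
#' @param cpts named list of CPT arrays as produced by [fit_cpts()] (leading
#'   dimensions: parent states in node order; last dimension: node states).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return integer matrix, variables in rows, samples in columns.
#' @export
simulate_bn_dataset <- function(adj, cpts, n_samples, seed = 1) {
  nodes <- rownames(adj)
  ord <- topo_order(adj)
  if (is.null(ord)) stop_fmb("adjacency is cyclic; cannot sample ancestrally")
  out <- matrix(0L, length(nodes), n_samples, dimnames = list(nodes, NULL))
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      for (v in ord) {
        node <- nodes[v]
        cpt <- cpts[[node]]
        parents <- attr(cpt, "parents")
        idx <- if (length(parents)) out[parents, s] else 1
        probs <- do.call(`[`, c(list(cpt), as.list(idx), list(TRUE)))
        out[node, s] <- sample.int(length(probs), 1, prob = probs)
      }
    }
  })
  out
}

#' Build a CPT array by hand
#'
#' Convenience for constructing ground-truth networks in simulations: wraps
#' a probability matrix (rows = parent configurations in mixed-radix order
#' with the first parent varying fastest, columns = node states) into the
#' array layout used by [fit_cpts()] and [simulate_bn_dataset()].
#'
#' @param probs numeric matrix of row-normalized probabilities.
#' @param parent_states integer vector of parent state counts (in node
#'   order), or empty for a root node.
#' @param parents character vector of parent names (same order).
#' @return CPT array with a `parents` attribute.
#' @export
make_cpt <- function(probs, parent_states = integer(0), parents = character(0)) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-8)) stop_fmb("CPT rows must sum to 1")
  dims <- c(parent_states, ncol(probs))
  if (!length(parent_states)) dims <- c(1, ncol(probs))
  cpt <- array(as.vector(probs), dim = dims)
  attr(cpt, "parents") <- parents
  cpt
}
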