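# Fixtures built in code: tiny models, random LAD instances, oracles.

# write a model TSV from lines and read it back
model_from_lines <- function(lines) {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tsubsystem", lines), tsv)
  on.exit(unlink(tsv))
  read_model_tsv(tsv)
}

# linear chain in -> A -> B -> out; all fluxes equal at steady state
chain_model <- function(cap_mid = 10) {
  model_from_lines(c(
    "EX_in\tA <->\t-10\t0\tExchange",
    sprintf("R_mid\tA -> B\t0\t%g\tCore", cap_mid),
    "EX_out\tB ->\t0\t10\tExchange"))
}

# sole uptake capped at 1, two parallel branches capped at 0.5 each,
# biomass yield 0.5 per substrate, plus an unused side reaction
two_branch_model <- function() {
  model_from_lines(c(
    "EX_S\tSx <->\t-1000\t0\tExchange",
    "UPT\tSx -> S\t0\t1\tTransport",
    "BR1\tS -> P\t0\t0.5\tBranches",
    "BR2\tS -> P\t0\t0.5\tBranches",
    "ALT\tS -> W\t0\t1000\tSide",
    "EX_W\tW ->\t0\t1000\tExchange",
    "BIOMASS\t2 P -> Bx\t0\t1000\tBiomass",
    "EX_B\tBx ->\t0\t1000\tExchange"))
}

# random small LAD instance; v = 0 is always feasible (bounds straddle 0),
# so the LP is feasible and bounded
rand_lad_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:10, 1)
  m <- sample(2:(n - 1), 1)
  repeat {
    S <- matrix(sample(c(-2:-1, 0, 0, 1:2), m * n, replace = TRUE), m, n)
    if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(m)), paste0("r", seq_len(n)))
  lower <- -round(stats::runif(n, 0, 5), 2)
  upper <- round(stats::runif(n, 0.5, 5), 2)
  K <- sample(seq_len(n - 1), 1)
  kidx <- sort(sample(seq_len(n), K))
  targets <- round(stats::runif(K, -2, 2), 3)
  list(S = S, lower = lower, upper = upper, kidx = kidx, targets = targets)
}

inst_to_model <- function(inst) {
  n <- ncol(inst$S)
  fmb_model(inst$S, inst$lower, inst$upper, reversible = inst$lower < 0,
            biomass_id = NA_character_, exchange = rep(TRUE, n))
}

# batch LAD residuals from an independent scipy/HiGHS formulation
lad_oracle_residuals <- function(instances) {
  enc <- lapply(instances, function(it) list(
    S = unname(apply(it$S, 1, function(r) as.numeric(r), simplify = FALSE)),
    lower = ifelse(is.finite(it$lower), it$lower, -1e30),
    upper = ifelse(is.finite(it$upper), it$upper, 1e30),
    kidx = it$kidx, targets = it$targets))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(enc, fin, digits = NA)
  status <- system2("python", c(test_path("lad_oracle.py"), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python LP oracle call failed")
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  res$residual
}

run_toy_pipeline <- function(seed, n_per_condition = 200, n_perms = 20,
                             spec = toy_model_spec(3, 4)) {
  fx <- make_toy_model(spec)
  fm <- sample_flux_matrix(fx$model, fx$constraints, fx$perturbation,
                           n_per_condition, seed)
  core <- select_core(fm)
  d <- pattern_dist(core$reduced$values, n_perms, derive_perm_seed(seed))
  cl <- hierarchical_cluster(d, labels = rownames(core$reduced$values))
  cl <- reinsert_duplicates(cl, core$duplicate_groups)
  list(fixture = fx, fm = fm, core = core, clusters = cl)
}

derive_perm_seed <- function(seed) as.integer((as.numeric(seed) * 7919) %% 2147483647)

toy_truth_ari <- function(run) {
  truth <- run$fixture$truth$module_of
  got <- run$clusters$assignment[names(truth)]
  mclust::adjustedRandIndex(got, truth)
}
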