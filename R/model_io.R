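# Metabolic model container and plain-text I/O.

#' Construct a metabolic model
#'
#' A metabolic model is the substrate of all flux computations: a
#' stoichiometric matrix `S` (metabolites x reactions), per-reaction flux
#' bounds in mmol/gDCW/h, reversibility flags, and a designated biomass
#' reaction. Exchange reactions (those with an empty side in their equation)
#' and the biomass reaction are pseudo-reactions allowed to be mass-unbalanced.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns, with
#'   dimnames giving metabolite and reaction ids.
#' @param lower,upper numeric vectors of flux bounds per reaction.
#' @param reversible logical vector per reaction.
#' @param biomass_id id of the biomass (growth) reaction, or `NA`.
#' @param subsystem optional character vector of subsystem labels.
#' @param exchange optional logical vector flagging exchange pseudo-reactions;
#'   by default reactions whose column of `S` is all non-negative or all
#'   non-positive with a single metabolite are flagged.
#' @return an object of class `fmb_model`.
#' @export
fmb_model <- function(S, lower, upper, reversible, biomass_id = NA_character_,
                      subsystem = NULL, exchange = NULL) {
  S <- as.matrix(S)
  rxns <- colnames(S)
  mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    stop_fmb("S must have metabolite row names and reaction column names")
  if (anyDuplicated(rxns)) stop_fmb("duplicate reaction ids in model")
  n <- ncol(S)
  stopifnot(length(lower) == n, length(upper) == n, length(reversible) == n)
  if (is.null(subsystem)) subsystem <- rep("", n)
  if (is.null(exchange)) exchange <- colSums(S != 0) <= 1
  m <- structure(list(
    S = S, metabolites = mets, reactions = rxns,
    lower = stats::setNames(as.numeric(lower), rxns),
    upper = stats::setNames(as.numeric(upper), rxns),
    reversible = stats::setNames(as.logical(reversible), rxns),
    subsystem = stats::setNames(as.character(subsystem), rxns),
    exchange = stats::setNames(as.logical(exchange), rxns),
    biomass_id = biomass_id), class = "fmb_model")
  validate_model(m)
  m
}

validate_model <- function(m) {
  bad <- m$lower > m$upper
  if (any(bad)) stop_fmb("lower bound exceeds upper bound for: %s",
                         paste(m$reactions[bad], collapse = ", "))
  irr_neg <- !m$reversible & m$lower < 0
  if (any(irr_neg)) stop_fmb("irreversible reaction with negative lower bound: %s",
                             paste(m$reactions[irr_neg], collapse = ", "))
  pseudo <- m$exchange | (!is.na(m$biomass_id) & m$reactions == m$biomass_id)
  empty <- colSums(m$S != 0) == 0
  if (any(empty & !pseudo))
    stop_fmb("empty stoichiometry column for non-exchange reaction: %s",
             paste(m$reactions[empty & !pseudo], collapse = ", "))
  if (!is.na(m$biomass_id) && !(m$biomass_id %in% m$reactions))
    stop_fmb("biomass reaction '%s' not in model", m$biomass_id)
  invisible(m)
}

#' @export
print.fmb_model <- function(x, ...) {
  cat(sprintf("fmb_model: %d metabolites x %d reactions (%d reversible, %d exchange)\n",
              nrow(x$S), ncol(x$S), sum(x$reversible), sum(x$exchange)))
  if (!is.na(x$biomass_id)) cat("biomass reaction:", x$biomass_id, "\n")
  invisible(x)
}

# ---- reaction equation grammar ------------------------------------------
# "2 A + B <-> C"; "->" irreversible, "<->" reversible; an empty side marks
# an exchange pseudo-reaction ("A ->" exports A, negative flux imports it).

parse_equation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else if (grepl("->", eq, fixed = TRUE)) "->" else
    stop_fmb("equation lacks '->' or '<->': '%s'", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(txt, sgn) {
    txt <- trimws(txt)
    if (txt == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") stop_fmb("empty term in equation side '%s'", txt)
      parts <- strsplit(tm, "\\s+")[[1]]
      coef <- suppressWarnings(as.numeric(parts[1]))
      if (length(parts) > 1 && !is.na(coef)) {
        met <- paste(parts[-1], collapse = " ")
      } else {
        coef <- 1; met <- tm
      }
      cur <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- cur + sgn * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  coefs <- lhs
  for (met in names(rhs)) {
    cur <- if (met %in% names(coefs)) coefs[[met]] else 0
    coefs[met] <- cur + rhs[[met]]
  }
  list(coefs = coefs, reversible = arrow == "<->",
       exchange = nchar(trimws(sides[1])) == 0 || nchar(trimws(sides[2])) == 0)
}

format_coef <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  has_dec <- grepl(".", s, fixed = TRUE)
  s[has_dec] <- sub("\\.$", "", sub("0+$", "", s[has_dec]))
  s
}

format_equation <- function(coefs, reversible) {
  fmt_side <- function(v) {
    if (!length(v)) return("")
    paste(vapply(seq_along(v), function(i) {
      cf <- abs(v[i])
      if (cf == 1) names(v)[i] else paste(format_coef(cf), names(v)[i])
    }, ""), collapse = " + ")
  }
  lhs <- coefs[coefs < 0]; rhs <- coefs[coefs > 0]
  trimws(paste(fmt_side(lhs), if (reversible) "<->" else "->", fmt_side(rhs)))
}

# ---- model TSV -----------------------------------------------------------

#' Read a metabolic model from TSV
#'
#' Expects a UTF-8 tab-separated file with one header row and columns
#' `reaction_id`, `equation`, `lower_bound`, `upper_bound`, `subsystem`.
#' The biomass reaction is the first one whose subsystem is `"Biomass"`
#' (case-insensitive) unless `biomass_id` is given.
#'
#' @param path file path.
#' @param biomass_id optional explicit biomass reaction id.
#' @return an [fmb_model].
#' @export
read_model_tsv <- function(path, biomass_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", "equation", "lower_bound", "upper_bound", "subsystem")
  if (!all(need %in% names(df)))
    stop_fmb("model TSV must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$reaction_id))
    stop_fmb("duplicate reaction id in %s: %s", path,
             paste(unique(df$reaction_id[duplicated(df$reaction_id)]), collapse = ", "))
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_equation(df$equation[i]),
             error = function(e) stop_fmb("line %d (%s): %s", i + 1L,
                                          df$reaction_id[i], conditionMessage(e)))
  })
  mets <- unique(unlist(lapply(parsed, function(p) names(p$coefs))))
  S <- matrix(0, length(mets), nrow(df), dimnames = list(mets, df$reaction_id))
  for (i in seq_along(parsed)) S[names(parsed[[i]]$coefs), i] <- parsed[[i]]$coefs
  if (is.null(biomass_id)) {
    hit <- which(tolower(df$subsystem) == "biomass")
    biomass_id <- if (length(hit)) df$reaction_id[hit[1]] else NA_character_
  }
  fmb_model(S, df$lower_bound, df$upper_bound,
            vapply(parsed, `[[`, TRUE, "reversible"),
            biomass_id = biomass_id, subsystem = df$subsystem,
            exchange = vapply(parsed, `[[`, TRUE, "exchange"))
}

#' Write a metabolic model to TSV
#'
#' Inverse of [read_model_tsv()]; a file written here and read back yields an
#' identical model, and re-writing reproduces the file byte for byte.
#'
#' @param model an [fmb_model].
#' @param path output file path.
#' @export
write_model_tsv <- function(model, path) {
  eqs <- vapply(seq_along(model$reactions), function(j) {
    coefs <- model$S[, j]
    coefs <- coefs[coefs != 0]
    format_equation(coefs, model$reversible[j])
  }, "")
  df <- data.frame(reaction_id = model$reactions, equation = eqs,
                   lower_bound = format_coef(model$lower),
                   upper_bound = format_coef(model$upper),
                   subsystem = model$subsystem, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- knockouts -----------------------------------------------------------

#' Define a perturbation (set of reaction knockouts)
#'
#' @param knockout_reaction_ids character vector of reaction ids forced to
#'   zero flux (may be empty for the control condition).
#' @param label free-text label.
#' @return an object of class `fmb_perturbation`.
#' @export
fmb_perturbation <- function(knockout_reaction_ids = character(), label = "") {
  structure(list(knockout_reaction_ids = as.character(knockout_reaction_ids),
                 label = label), class = "fmb_perturbation")
}

#' Apply reaction knockouts to a model
#'
#' Returns a copy of the model with both flux bounds of each knocked-out
#' reaction set to zero; the input model is not modified.
#'
#' @param model an [fmb_model].
#' @param spec an [fmb_perturbation] or a character vector of reaction ids.
#' @return a new [fmb_model].
#' @export
apply_knockout <- function(model, spec) {
  ids <- if (inherits(spec, "fmb_perturbation")) spec$knockout_reaction_ids else as.character(spec)
  if (!length(ids)) return(model)
  missing <- setdiff(ids, model$reactions)
  if (length(missing))
    stop_fmb("unknown reaction id(s) in knockout spec: %s", paste(missing, collapse = ", "))
  model$lower[ids] <- 0
  model$upper[ids] <- 0
  model
}

# ---- experimental constraints -------------------------------------------

#' Load an experimental-constraint table
#'
#' Reads a CSV with columns `reaction_id`, `condition`, `mean`, `sigma`,
#' `class`. Each row states that under `condition` the flux of `reaction_id`
#' was measured as `mean` +/- `sigma` (mmol/gDCW/h). `class` separates
#' intracellular 13C-derived fluxes (`C13`) from culture-level rates such as
#' growth and uptake (`FMT`). Uptake exchange fluxes are negative by
#' convention.
#'
#' @param path CSV file path.
#' @param conditions allowed condition labels.
#' @return a `data.frame` of class `fmb_constraints`.
#' @export
load_constraints <- function(path, conditions = c("control", "perturbed")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "condition", "mean", "sigma", "class")
  if (!all(need %in% names(df)))
    stop_fmb("constraints CSV must have columns: %s", paste(need, collapse = ", "))
  df <- df[, need]
  if (nrow(df)) {
    if (any(df$sigma < 0)) stop_fmb("negative sigma in constraints file")
    bad <- !df$condition %in% conditions
    if (any(bad)) stop_fmb("unknown condition label(s): %s",
                           paste(unique(df$condition[bad]), collapse = ", "))
    if (!all(df$class %in% c("C13", "FMT")))
      stop_fmb("constraint class must be 'C13' or 'FMT'")
  }
  class(df) <- c("fmb_constraints", "data.frame")
  df
}

# Subset for one condition, checking ids against a model.
constraints_for <- function(constraints, condition, model = NULL) {
  sub <- constraints[constraints$condition == condition, , drop = FALSE]
  if (!is.null(model)) {
    missing <- setdiff(sub$reaction_id, model$reactions)
    if (length(missing))
      stop_fmb("constrained reaction(s) not in model: %s", paste(missing, collapse = ", "))
  }
  sub
}
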