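# Constraint-based metabolic network analysis: model container, GPR rules,
# expression-derived constraints, FVA, capability probes, perturbation calls
# and the reaction-metabolite perturbation network.

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `compartment`, and
#'   optionally `formula` (element tags used by mass-balance checks).
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`
#'   (boolean gene rule string, `""` for none) and optionally `subsystem`.
#' @param S stoichiometric matrix (metabolite x reaction), dimnames matching
#'   the id columns. Negative coefficients are substrates.
#' @return An object of class `metabolic_model`. Exchange reactions
#'   (single-metabolite columns) are auto-detected.
#' @export
metabolic_model <- function(id, metabolites, reactions, S) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == nrow(metabolites), ncol(S) == nrow(reactions))
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (any(reactions$lb > reactions$ub))
    stop2("reaction with lb > ub")
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$reversible <- reactions$lb < 0
  for (g in reactions$gpr) parse_gpr(g)  # must parse
  exchanges <- reactions$id[colSums(S != 0) == 1L]
  structure(list(id = id, metabolites = metabolites,
                 reactions = reactions, S = S, exchanges = exchanges),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions (%d exchanges)\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              length(x$exchanges)))
  invisible(x)
}

# ---- GPR rules ------------------------------------------------------------

# Recursive-descent parser for boolean gene rules: identifiers, "and", "or",
# parentheses. Returns NULL for empty rules, otherwise a nested list tree
# list(op=, args=) / list(gene=).
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  tokens <- regmatches(text, gregexpr(
    "\\(|\\)|[A-Za-z0-9_.:-]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; tokens[pos - 1L] }
  parse_or <- function() {
    node <- parse_and()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) node else list(op = "or", args = args)
  }
  parse_and <- function() {
    node <- parse_atom()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) node else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) stop2("GPR parse error: unexpected end in '%s'", text)
    if (tok == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop2("GPR parse error: missing ')' in '%s'", text)
      advance()
      return(node)
    }
    if (tok %in% c(")", "and", "or", "AND", "OR"))
      stop2("GPR parse error: unexpected '%s' in '%s'", tok, text)
    advance()
    list(gene = tok)
  }
  out <- parse_or()
  if (pos <= length(tokens))
    stop2("GPR parse error: trailing tokens in '%s'", text)
  out
}

# Canonical string form of a parsed GPR tree.
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.null(a$op) && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR rule against gene activity multipliers
#'
#' AND maps to the minimum of operand activities (an enzyme complex is as
#' available as its scarcest subunit), OR to the maximum (isoenzymes
#' substitute). An empty rule evaluates to 1 (unconstrained); genes absent
#' from `activities` default to 1.
#'
#' @param expression GPR rule string or parsed tree.
#' @param activities named numeric vector or list, gene -> activity in (0,1].
#' @return Scalar reaction activity.
#' @export
evaluate_gpr <- function(expression, activities) {
  tree <- if (is.character(expression)) parse_gpr(expression) else expression
  if (is.null(tree)) return(1)
  activities <- unlist(activities)
  rec <- function(node) {
    if (!is.null(node$gene)) {
      a <- activities[node$gene]
      if (is.na(a)) 1 else unname(a)
    } else {
      vals <- vapply(node$args, rec, numeric(1))
      if (node$op == "and") min(vals) else max(vals)
    }
  }
  rec(tree)
}

# ---- expression-derived constraints --------------------------------------

#' Build an expression constraint set
#'
#' @param activities named numeric vector, gene -> multiplier in (0, 1\];
#'   1 means unperturbed.
#' @param epsilon relative tolerance used downstream when calling FVA
#'   perturbations (default 0.01).
#' @param derivation free-text provenance tag.
#' @return `expression_constraints` object.
#' @export
expression_constraint_set <- function(activities, epsilon = 0.01,
                                      derivation = "manual") {
  activities <- unlist(activities)
  if (any(activities <= 0 | activities > 1))
    stop2("activity multipliers must lie in (0, 1]")
  if (epsilon <= 0) stop2("epsilon must be > 0")
  structure(list(activities = activities, epsilon = epsilon,
                 derivation = derivation),
            class = "expression_constraints")
}

#' Derive gene activity multipliers from a two-group expression table
#'
#' For each gene the multiplier is the group-B / group-A mean expression
#' ratio, clamped into \[0.05, 1\]: genes expressed at least as highly in B
#' are left unconstrained, downregulated genes scale their reactions'
#' bounds by the observed fold-change, floored at 0.05.
#'
#' @param expression gene x sample numeric matrix (rownames = gene ids).
#' @param groups character/factor of length ncol(expression) with two levels;
#'   the first level (alphabetically, or of a factor) is the reference A.
#' @param genes optional subset of genes to derive multipliers for.
#' @param floor lower clamp for the multiplier (default 0.05).
#' @return `expression_constraints` object.
#' @export
activities_from_expression <- function(expression, groups, genes = NULL,
                                       floor = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop2("need exactly two groups")
  a <- levels(groups)[1]; b <- levels(groups)[2]
  if (is.null(genes)) genes <- rownames(expression)
  genes <- intersect(genes, rownames(expression))
  if (!length(genes)) stop2("no requested genes found in expression table")
  fc <- rowMeans(expression[genes, groups == b, drop = FALSE]) /
    rowMeans(expression[genes, groups == a, drop = FALSE])
  mult <- pmin(1, pmax(floor, fc))
  expression_constraint_set(stats::setNames(mult, genes),
                            derivation = sprintf("fold_change(%s/%s)", b, a))
}

#' Apply expression constraints to a model
#'
#' Each reaction's activity `a_r` is its GPR rule evaluated over the gene
#' multipliers (AND = min, OR = max). Bounds are scaled toward zero:
#' `lb' = a_r * lb` when `lb < 0`, `ub' = a_r * ub` when `ub > 0`; bounds
#' already at or beyond zero in the shrinking direction are untouched. The
#' input model is not modified.
#'
#' @param model `metabolic_model`.
#' @param constraints `expression_constraints`.
#' @return A new constrained `metabolic_model`.
#' @export
apply_expression_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(constraints, "expression_constraints"))
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    a_r <- evaluate_gpr(rx$gpr[i], constraints$activities)
    if (a_r < 1) {
      if (rx$lb[i] < 0) rx$lb[i] <- a_r * rx$lb[i]
      if (rx$ub[i] > 0) rx$ub[i] <- a_r * rx$ub[i]
    }
  }
  out <- model
  out$reactions <- rx
  out
}

# ---- FVA and capability ---------------------------------------------------

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its steady-state flux over
#' the full feasible region `S v = 0`, `lb <= v <= ub` (no objective
#' fixation: the feasible space itself is evaluated, not a growth-optimal
#' slice).
#'
#' @param model `metabolic_model`.
#' @param reactions optional character vector restricting the scan.
#' @return data.frame with columns `reaction`, `vmin`, `vmax` and attribute
#'   `tol` (solver tolerance).
#' @export
run_fva <- function(model, reactions = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- model$reactions$id
  if (is.null(reactions)) reactions <- ids
  if (!all(reactions %in% ids)) stop2("unknown reaction in FVA request")
  lb <- model$reactions$lb; ub <- model$reactions$ub
  # feasibility check once
  feas <- solve_flux_lp(rep(0, length(ids)), model$S, lb, ub)
  if (feas$status != "optimal")
    stop2("model '%s' is infeasible: no flux vector satisfies S v = 0 within bounds",
          model$id)
  res <- vapply(reactions, function(rid) {
    obj <- as.numeric(ids == rid)
    lo <- solve_flux_lp(obj, model$S, lb, ub, maximize = FALSE)
    hi <- solve_flux_lp(obj, model$S, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop2("FVA subproblem failed for reaction %s", rid)
    c(lo$objective, hi$objective)
  }, numeric(2))
  out <- data.frame(reaction = reactions, vmin = res[1, ], vmax = res[2, ],
                    row.names = NULL)
  attr(out, "tol") <- 1e-9
  out
}

#' Maximal production or consumption capability of a metabolite
#'
#' Temporarily adds a drain (`m ->`, production) or feed (`-> m`,
#' consumption) reaction with bounds \[0, 1e6\] and maximizes its flux; the
#' probe reaction is discarded afterwards.
#'
#' @param model `metabolic_model`.
#' @param metabolite metabolite id.
#' @param direction `"produce"` or `"consume"`.
#' @return Maximal probe flux (nonnegative scalar).
#' @export
metabolite_capability <- function(model, metabolite,
                                  direction = c("produce", "consume")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "metabolic_model"))
  if (!metabolite %in% model$metabolites$id)
    stop2("unknown metabolite '%s'", metabolite)
  coef <- if (direction == "produce") -1 else 1
  S <- cbind(model$S, probe = 0)
  S[metabolite, "probe"] <- coef
  n <- ncol(S)
  obj <- c(rep(0, n - 1), 1)
  lb <- c(model$reactions$lb, 0)
  ub <- c(model$reactions$ub, 1e6)
  res <- solve_flux_lp(obj, S, lb, ub, maximize = TRUE)
  if (res$status != "optimal")
    stop2("capability LP infeasible for %s", metabolite)
  max(0, res$objective)
}

#' Call perturbed reactions from two FVA results
#'
#' A reaction is called `min_flux` when its minimum flux moved by more than
#' `epsilon * max(1, baseline range)`, `max_flux` analogously for the
#' maximum, `both` when both moved, `none` otherwise.
#'
#' @param baseline,perturbed data.frames from [run_fva()] over the same
#'   reactions.
#' @param epsilon relative tolerance (default 0.01).
#' @return data.frame `reaction`, `call`, `dmin`, `dmax`.
#' @export
diff_fva <- function(baseline, perturbed, epsilon = 0.01) {
  if (!setequal(baseline$reaction, perturbed$reaction))
    stop2("baseline and perturbed FVA cover different reactions")
  perturbed <- perturbed[match(baseline$reaction, perturbed$reaction), ]
  rng <- pmax(1, baseline$vmax - baseline$vmin)
  dmin <- abs(perturbed$vmin - baseline$vmin)
  dmax <- abs(perturbed$vmax - baseline$vmax)
  hit_min <- dmin > epsilon * rng
  hit_max <- dmax > epsilon * rng
  call <- ifelse(hit_min & hit_max, "both",
                 ifelse(hit_min, "min_flux",
                        ifelse(hit_max, "max_flux", "none")))
  data.frame(reaction = baseline$reaction, call = call,
             dmin = dmin, dmax = dmax, row.names = NULL)
}

#' Subgroup-specific perturbation calls
#'
#' Reactions called (anything but `none`) in `calls_a` but not in `calls_b`.
#'
#' @param calls_a,calls_b data.frames from [diff_fva()].
#' @return Subset of `calls_a` rows.
#' @export
subgroup_specific_calls <- function(calls_a, calls_b) {
  hit_a <- calls_a$reaction[calls_a$call != "none"]
  hit_b <- calls_b$reaction[calls_b$call != "none"]
  calls_a[calls_a$reaction %in% setdiff(hit_a, hit_b), , drop = FALSE]
}

# ---- perturbation network -------------------------------------------------

#' Build the reaction-metabolite perturbation network
#'
#' Directed bipartite graph over the called reactions and their substrate/
#' product metabolites: edges run substrate -> reaction and reaction ->
#' product. Node attributes: `kind` (reaction/metabolite), `change`
#' (min_flux/max_flux/both/none), `color` (red = minimum flux moved,
#' green = maximum flux moved, orange = both, light blue = no call, i.e.
#' metabolites) and `size` = outdegree.
#'
#' @param calls data.frame from [diff_fva()] (or a subgroup-specific subset).
#' @param model `metabolic_model` supplying stoichiometry.
#' @return An `igraph` graph (empty, with a warning, if no calls).
#' @export
build_perturbation_network <- function(calls, model) {
  stopifnot(inherits(model, "metabolic_model"))
  hit <- calls[calls$call != "none", , drop = FALSE]
  if (nrow(hit) == 0) {
    warn2("no perturbation calls: returning empty network")
    return(igraph::make_empty_graph(directed = TRUE))
  }
  edges <- character(0)
  mets <- character(0)
  for (i in seq_len(nrow(hit))) {
    rid <- hit$reaction[i]
    col <- model$S[, rid]
    subs <- rownames(model$S)[col < 0]
    prods <- rownames(model$S)[col > 0]
    mets <- c(mets, subs, prods)
    for (s in subs) edges <- c(edges, s, rid)
    for (p in prods) edges <- c(edges, rid, p)
  }
  mets <- unique(mets)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(hit$reaction, mets),
                     kind = c(rep("reaction", nrow(hit)),
                              rep("metabolite", length(mets))),
                     change = c(hit$call, rep("none", length(mets))))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  colmap <- c(min_flux = "red", max_flux = "green", both = "orange",
              none = "lightblue")
  igraph::V(g)$color <- unname(colmap[igraph::V(g)$change])
  igraph::V(g)$size <- igraph::degree(g, mode = "out")
  g
}

#' Write a perturbation network to GraphML
#'
#' @param graph `igraph` graph from [build_perturbation_network()].
#' @param path output file path.
#' @export
write_perturbation_network <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

# ---- IDH validation scenario ---------------------------------------------

#' Validate a model via the IDH-mutant 2-HG scenario
#'
#' Mutant IDH converts alpha-ketoglutarate + NADPH to the oncometabolite
#' 2-hydroxyglutarate (2-HG). With the mutant reaction disabled the network
#' must be unable to produce 2-HG; enabling it opens a production capability
#' limited by substrate supply.
#'
#' @param model an `idh`-variant toy model (must contain reaction
#'   `IDH1MUT` and metabolite `hg2_c`).
#' @param enabled_bounds bounds given to the mutant reaction in the enabled
#'   state (default `c(0, 10)`).
#' @return list with `capability_disabled`, `capability_enabled`, and the
#'   FVA interval of the mutant reaction in the enabled model.
#' @export
idh_validation_scenario <- function(model, enabled_bounds = c(0, 10)) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!"hg2_c" %in% model$metabolites$id)
    stop2("model lacks the 2-HG species 'hg2_c'")
  if (!"IDH1MUT" %in% model$reactions$id)
    stop2("model lacks the mutant reaction 'IDH1MUT'")
  set_bounds <- function(m, lo, hi) {
    i <- match("IDH1MUT", m$reactions$id)
    m$reactions$lb[i] <- lo; m$reactions$ub[i] <- hi
    m
  }
  off <- set_bounds(model, 0, 0)
  on <- set_bounds(model, enabled_bounds[1], enabled_bounds[2])
  cap_off <- metabolite_capability(off, "hg2_c", "produce")
  cap_on <- metabolite_capability(on, "hg2_c", "produce")
  fva_on <- run_fva(on, "IDH1MUT")
  list(capability_disabled = cap_off,
       capability_enabled = cap_on,
       mutant_fva = fva_on)
}
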