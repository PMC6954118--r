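#' @name bbm_compiler
#' @title Compiling a network into a bipartite Boolean model
#'
#' @description
#' The compiler assigns one Boolean update expression to every target of the
#' bipartite model. Targets come in three kinds: *state targets* (one per
#' elemental state, plus one per generic component), *reaction targets* (one
#' per elemental reaction, after bidirectional splitting and degradation
#' expansion) and *input targets*.
#'
#' The reaction update rule requires the strict contingencies to be
#' satisfied and the reacting components to be present:
#' \deqn{R_i(t+1) = K(R_i; t) \cap L(R_i; t)}
#' where \eqn{K(R_i)} is the conjunction over reacting components (each
#' component being the conjunction over its sites of the disjunction of
#' states on the site) and \eqn{L(R_i)} conjoins the required contingencies
#' with the negated inhibitory ones.
#'
#' The state update rule encodes the reaction-type hierarchy
#' synthesis > degradation > production > consumption:
#' \deqn{S_i(t+1) = \Sigma(S_i) \cup \Big(K(S_i) \cap \bigcap_{deg}
#'   \overline{R'_k} \cap \big[\bigcup_{prod} R'_l \cup (S_i \cap
#'   \bigcap_{cons} \overline{R'_m})\big]\Big)}
#' A primed reaction \eqn{R' = R \cap (\mathrm{source\ states})} couples the
#' reaction target with its source states: a reaction that is eligible to
#' fire still does nothing without its substrate. \eqn{\Sigma} is the
#' synthesis term: for neutral states, the union of primed synthesis
#' reactions; for states one production step away from neutral, the primed
#' synthesis reactions of the neutral counterpart conjoined with the primed
#' producers of the state itself. States further than one production step
#' from their synthesised neutral state are rejected with an error.
#'
#' With *source-state smoothing* (the default), each producing primed
#' reaction widens its source-state check to "present now or produced in
#' this step": every source state \eqn{S_j} becomes
#' \eqn{S_j(t) \cup S_j(t+1)}, where \eqn{S_j(t+1)} is the full non-smoothed
#' state update expression of \eqn{S_j} expanded in time-\eqn{t} targets
#' (one level, no recursion). Smoothing removes the spurious out-of-phase
#' oscillations caused by alternating source-state depletion in
#' modification and interaction cycles, at the price of larger update
#' expressions.
NULL

#' Compilation options
#'
#' @param smoothing apply source-state smoothing to producing reactions in
#'   the state update rule (default `TRUE`).
#' @param k_plus,k_minus policy for the quantitative contingencies:
#'   `"ignore"` (default) drops them like `"0"`; `"strict"` folds `K+` in as
#'   required (`!`) and `K-` as absolutely inhibitory (`x`).
#' @return a `compile_options` object.
#' @export
compile_options <- function(smoothing = TRUE,
                            k_plus = c("ignore", "strict"),
                            k_minus = c("ignore", "strict")) {
  structure(list(smoothing = isTRUE(smoothing),
                 k_plus = match.arg(k_plus),
                 k_minus = match.arg(k_minus)),
            class = "compile_options")
}

# ---- compiler context ------------------------------------------------------
# All expression builders work at the level of original names: states by
# state name, reactions by reaction name, inputs as "[Name]". The final
# compile pass renames every reference to its sanitised symbol.

ctx_new <- function(net, opts) {
  list(net = net, opts = opts, memo = new.env(parent = emptyenv()))
}

input_ref <- function(name) bx_ref(paste0("[", name, "]"))

state_targets_of <- function(net)
  Filter(function(s) s$variant != "input", net$states)

# sites of a component: unique "component site" keys, declaration order
component_sites <- function(net, cc) {
  keys <- character(0)
  for (s in state_targets_of(net))
    for (cr in s$carriers)
      if (identical(cr$component, cc) && !is.na(cr$site))
        keys <- c(keys, paste(cr$component, cr$site))
  unique(keys)
}

states_on_site <- function(net, key) {
  Filter(function(s) key %in% state_sites(s), state_targets_of(net))
}

#' Component presence expression
#'
#' For a component carrying states: the conjunction over its sites of the
#' disjunction of the states living on each site (a site always holds
#' exactly one of its states, so component presence is equivalent to some
#' state being present on every site). For a generic (site-less) component:
#' a reference to its own component state target.
#'
#' @param net an `rxncon_network`.
#' @param component component name.
#' @return a `bool_expr` over state names.
#' @export
component_expression <- function(net, component) {
  sites <- component_sites(net, component)
  if (length(sites) == 0L) {
    if (is.null(net$states[[component]]))
      stop("undeclared component '", component, "'")
    return(bx_ref(component))
  }
  bx_and(lapply(sites, function(key)
    bx_or(lapply(states_on_site(net, key), function(s) bx_ref(s$name)))))
}

#' Reacting-components expression K(R)
#'
#' Conjunction of [component_expression()] over the components reacting in
#' the reaction; TRUE for reactions with no reacting components (pure
#' synthesis).
#'
#' @param net an `rxncon_network`.
#' @param reaction reaction name.
#' @return a `bool_expr`.
#' @export
reacting_components <- function(net, reaction) {
  r <- net$reactions[[reaction]]
  if (is.null(r)) stop("undeclared reaction '", reaction, "'")
  bx_and(lapply(r$reacting_components, function(cc)
    component_expression(net, cc)))
}

#' Carrier-components expression K(S)
#'
#' Conjunction of [component_expression()] over the components carrying the
#' state (two for bond states, one otherwise; the state itself for generic
#' component states).
#'
#' @param net an `rxncon_network`.
#' @param state state name.
#' @return a `bool_expr`.
#' @export
carrier_components <- function(net, state) {
  s <- net$states[[state]]
  if (is.null(s)) stop("undeclared state '", state, "'")
  if (s$variant == "component") return(bx_ref(s$name))
  bx_and(lapply(state_components(s), function(cc)
    component_expression(net, cc)))
}

#' Primed reaction R'
#'
#' A reaction together with its source states: the reaction target conjoined
#' with every state the reaction consumes. With `guards`, the effect-specific
#' variant: the reaction target conjoined with the given guard states (used
#' for the conditional production effects of degradation reactions).
#'
#' @param net an `rxncon_network`.
#' @param reaction reaction name.
#' @param guards optional character vector of guard state names overriding
#'   the reaction's consumed set.
#' @return a `bool_expr`.
#' @export
primed_reaction <- function(net, reaction, guards = NULL) {
  r <- net$reactions[[reaction]]
  if (is.null(r)) stop("undeclared reaction '", reaction, "'")
  if (is.null(guards)) guards <- reaction_consumed(r)
  bx_and(c(list(bx_ref(r$name)), lapply(guards, bx_ref)))
}

effects_on <- function(net, state, mode) {
  out <- list()
  for (r in net$reactions)
    for (e in r$effects)
      if (e$mode == mode && identical(e$state$name, state))
        out[[length(out) + 1L]] <- list(reaction = r$name, guards = e$guards)
  out
}

#' Synthesis term
#'
#' Whether a state is directly or indirectly synthesised. Neutral states:
#' the union of primed synthesis reactions. Non-neutral states one
#' production step from neutral: the primed synthesis reactions of the
#' neutral counterpart conjoined with the primed producers of the state.
#' Generic component states follow the neutral branch. FALSE when nothing
#' synthesises the state.
#'
#' @param net an `rxncon_network`.
#' @param state state name.
#' @return a `bool_expr`.
#' @export
synthesis_term <- function(net, state) {
  s <- net$states[[state]]
  if (is.null(s)) stop("undeclared state '", state, "'")
  syn_union <- function(st)
    bx_or(lapply(effects_on(net, st, "synthesis"), function(e)
      primed_reaction(net, e$reaction, e$guards)))
  if (s$neutral || s$variant == "component") return(syn_union(state))
  ncp <- vapply(neutral_counterpart(s), function(n) n$name, "")
  syn_part <- bx_or(lapply(ncp, syn_union))
  if (syn_part$kind == "const" && !syn_part$value) return(bx_const(FALSE))
  producers <- effects_on(net, state, "production")
  direct <- Filter(function(e) {
    r <- net$reactions[[e$reaction]]
    any(ncp %in% reaction_consumed(r)) || length(reaction_consumed(r)) == 0L
  }, producers)
  if (length(producers) > 0L && length(direct) == 0L)
    stop("state '", state, "' is more than one production step from its ",
         "neutral counterpart; the one-step synthesis term does not cover it")
  prod_part <- bx_or(lapply(producers, function(e)
    primed_reaction(net, e$reaction, e$guards)))
  bx_and(syn_part, prod_part)
}

#' Contingency expression L(R)
#'
#' Conjunction of all required (`!`) effectors with the negation of every
#' absolutely inhibitory (`x`) effector. Quantitative contingencies are
#' folded in as required/inhibitory under the `strict` policies and dropped
#' under `ignore`; `0` and `?` never enter the expression. Nested Boolean
#' effectors translate structurally.
#'
#' @param net an `rxncon_network`.
#' @param reaction reaction name.
#' @param opts a [compile_options()] object.
#' @return a `bool_expr`.
#' @export
contingency_expression <- function(net, reaction, opts = compile_options()) {
  parts <- list()
  for (ct in net$contingencies) {
    if (!identical(ct$target, reaction)) next
    eff_type <- switch(ct$ctype,
      "!" = "!", "x" = "x",
      "K+" = if (opts$k_plus == "strict") "!" else NA,
      "K-" = if (opts$k_minus == "strict") "x" else NA,
      "0" = NA, "?" = NA)
    if (is.na(eff_type)) next
    parts[[length(parts) + 1L]] <-
      if (eff_type == "!") ct$effector else bx_not(ct$effector)
  }
  bx_and(parts)
}

#' Reaction target update rule
#'
#' `K(R) AND L(R)`; clamped reactions compile to the clamp constant instead.
#'
#' @inheritParams contingency_expression
#' @return a `bool_expr`.
#' @export
reaction_update <- function(net, reaction, opts = compile_options()) {
  clamp <- if (reaction %in% names(net$clamps)) net$clamps[[reaction]] else NA
  if (!is.na(clamp)) return(bx_const(clamp))
  bx_and(reacting_components(net, reaction),
         contingency_expression(net, reaction, opts))
}

#' Smoothed producer expression
#'
#' The source-state-smoothed form of a producing primed reaction: the
#' reaction target conjoined with, for each source state, "present now or
#' produced in this step" — the disjunction of the state and its full
#' non-smoothed update expression, expanded one level in time-t targets.
#'
#' @param net an `rxncon_network`.
#' @param reaction producing reaction name.
#' @param guards character vector of the effect's source-state names.
#' @param ctx internal compiler context (memoises the one-level expansions);
#'   created automatically when absent.
#' @return a `bool_expr`.
#' @export
smoothed_producer <- function(net, reaction, guards,
                              ctx = ctx_new(net, compile_options())) {
  bx_and(c(list(bx_ref(reaction)),
           lapply(guards, function(g)
             bx_or(bx_ref(g), state_update_ns(ctx, g)))))
}

# memoised non-smoothed state update (used by the smoothing expansion)
state_update_ns <- function(ctx, state) {
  key <- paste0("ns:", state)
  if (!is.null(ctx$memo[[key]])) return(ctx$memo[[key]])
  e <- state_update_impl(ctx, state, smoothing = FALSE)
  ctx$memo[[key]] <- e
  e
}

state_update_impl <- function(ctx, state, smoothing) {
  net <- ctx$net
  s <- net$states[[state]]
  if (is.null(s)) stop("undeclared state '", state, "'")
  sigma <- synthesis_term(net, state)
  degraders <- lapply(effects_on(net, state, "degradation"), function(e)
    bx_not(primed_reaction(net, e$reaction, e$guards)))
  producers <- lapply(effects_on(net, state, "production"), function(e)
    if (smoothing) smoothed_producer(net, e$reaction, e$guards, ctx)
    else primed_reaction(net, e$reaction, e$guards))
  consumers <- lapply(effects_on(net, state, "consumption"), function(e)
    bx_not(primed_reaction(net, e$reaction, e$guards)))
  persist <- bx_and(c(list(bx_ref(state)), consumers))
  bx_or(sigma,
        bx_and(c(list(carrier_components(net, state)),
                 degraders,
                 list(bx_or(bx_or(producers), persist)))))
}

#' State target update rule
#'
#' The full state update (see [bbm_compiler]): the synthesis term, or —
#' carriers present, not degraded — produced by some primed reaction (with
#' optional smoothing) or already true and not consumed.
#'
#' @param net an `rxncon_network`.
#' @param state state name.
#' @param opts a [compile_options()] object.
#' @return a `bool_expr`.
#' @export
state_update <- function(net, state, opts = compile_options()) {
  state_update_impl(ctx_new(net, opts), state, smoothing = opts$smoothing)
}

# ---- full model ------------------------------------------------------------

bx_rename <- function(e, map) {
  switch(e$kind,
    const = e,
    ref = {
      sym <- map[[e$sym]]
      if (is.null(sym)) stop("no symbol for target '", e$sym, "'")
      bx_ref(sym)
    },
    and = bx("and", args = lapply(e$args, bx_rename, map = map)),
    or = bx("or", args = lapply(e$args, bx_rename, map = map)),
    not = bx("not", arg = bx_rename(e$arg, map))
  )
}

#' Compile a network into a bipartite Boolean model
#'
#' Builds one update rule per state, reaction and input target. Inputs with
#' no output link get an identity self-update, so values set by the user
#' persist; inputs declared as outputs get the linking expression. The
#' compilation is a pure function of the network and the options: target
#' order and symbol assignment are deterministic.
#'
#' @param net an `rxncon_network`.
#' @param opts a [compile_options()] object.
#' @return an object of class `bbm` with fields `targets` (data frame:
#'   `symbol`, `kind` in state/reaction/input, `name`, `neutral`), `rules`
#'   (named list of `bool_expr` keyed by symbol), `init` (the default
#'   initial vector, named logical) and `options`.
#' @export
compile_bbm <- function(net, opts = compile_options()) {
  stopifnot(inherits(net, "rxncon_network"))
  diags <- validate_network(net)
  blocking <- grepl("undeclared reaction|synthesis-path depth", diags)
  if (any(blocking))
    stop("network validation failed:\n  ",
         paste(diags[blocking], collapse = "\n  "))

  states <- state_targets_of(net)
  names_in_order <- c(vapply(states, function(s) s$name, ""),
                      vapply(net$reactions, function(r) r$name, ""),
                      if (length(net$inputs)) paste0("[", net$inputs, "]"))
  names_in_order <- unname(names_in_order)
  kinds <- c(rep("state", length(states)),
             rep("reaction", length(net$reactions)),
             rep("input", length(net$inputs)))
  neutral <- c(vapply(states, function(s)
    s$neutral || s$variant == "component", TRUE),
    rep(FALSE, length(net$reactions) + length(net$inputs)))

  raw_syms <- sanitise_symbol(names_in_order)
  syms <- raw_syms
  while (anyDuplicated(syms)) {
    d <- which(duplicated(syms))
    for (i in d) {
      k <- 2L
      while (paste0(raw_syms[i], "_", k) %in% syms) k <- k + 1L
      syms[i] <- paste0(raw_syms[i], "_", k)
    }
  }
  map <- as.list(syms)
  names(map) <- names_in_order

  ctx <- ctx_new(net, opts)
  rules <- vector("list", length(syms))
  names(rules) <- syms
  for (i in seq_along(names_in_order)) {
    nm <- names_in_order[i]
    e <- switch(kinds[i],
      state = state_update_impl(ctx, nm, smoothing = opts$smoothing),
      reaction = reaction_update(net, nm, opts),
      input = {
        inp <- sub("^\\[(.*)\\]$", "\\1", nm)
        link <- net$output_links[[inp]]
        if (is.null(link)) bx_ref(nm) else link
      })
    rules[[syms[i]]] <- bx_rename(e, map)
  }

  targets <- data.frame(symbol = syms, kind = kinds, name = names_in_order,
                        neutral = neutral, stringsAsFactors = FALSE)
  m <- structure(list(targets = targets, rules = rules, options = opts,
                      symbol_map = map),
                 class = "bbm")
  m$init <- default_initial_state(m)
  m
}

#' Default initial state vector
#'
#' All neutral elemental states (unbound binding domains and neutral
#' modifications) true, all generic component states true, all other
#' targets false — with one exception: a target whose update rule is a
#' clamped constant is initialised to that constant, so clamped targets
#' never change value.
#'
#' @param m a `bbm` model.
#' @return named logical vector over the model's target symbols.
#' @export
default_initial_state <- function(m) {
  stopifnot(inherits(m, "bbm"))
  v <- m$targets$neutral
  names(v) <- m$targets$symbol
  for (i in seq_along(v)) {
    rule <- m$rules[[m$targets$symbol[i]]]
    if (rule$kind == "const") v[i] <- rule$value
  }
  v
}

#' @export
print.bbm <- function(x, ...) {
  k <- table(factor(x$targets$kind, levels = c("state", "reaction", "input")))
  cat("<bbm> ", nrow(x$targets), " targets (", k[["state"]], " state, ",
      k[["reaction"]], " reaction, ", k[["input"]], " input); smoothing ",
      if (x$options$smoothing) "on" else "off", "\n", sep = "")
  invisible(x)
}
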