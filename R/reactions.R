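#' @name elemental_reactions
#' @title Elemental reactions and skeleton rules
#'
#' @description
#' An elemental reaction is a decontextualised reaction event. Its effect on
#' each elemental state is classified from the *skeleton rule* underlying the
#' reaction — a context-free rewrite with a left-hand side (LHS) and a
#' right-hand side (RHS) listing component patterns with attached states.
#' The four effect modes, each defined from the perspective of the state:
#'
#' * **production** — the state appears on the RHS, not on the LHS, but the
#'   component carrying it does appear on the LHS;
#' * **consumption** — the state appears on the LHS, not on the RHS, but the
#'   component carrying it does appear on the RHS;
#' * **synthesis** — the state appears on the RHS and the component carrying
#'   it does not appear on the LHS;
#' * **degradation** — the component carrying the state appears on the LHS,
#'   no state mutually exclusive with it appears on the LHS, and the
#'   component does not appear on the RHS.
#'
#' The modes form a strength hierarchy
#' synthesis > degradation > production > consumption, which the state
#' update rule of the compiler encodes.
NULL

#' Effect-mode hierarchy
#'
#' @return character vector of the four modes, strongest first.
#' @export
effect_modes <- function() c("synthesis", "degradation", "production", "consumption")

#' Compare two effect modes by strength
#' @param a,b mode names.
#' @return TRUE iff `a` is strictly stronger than `b`.
#' @export
mode_stronger <- function(a, b) {
  h <- effect_modes()
  match(a, h) < match(b, h)
}

new_effect <- function(state, mode, guards = character(0)) {
  stopifnot(inherits(state, "elemental_state"),
            mode %in% effect_modes())
  list(state = state, mode = mode, guards = guards)
}

#' Construct a skeleton rule
#'
#' @param lhs,rhs lists of component patterns, each created by
#'   [component_pattern()].
#' @return a `skeleton_rule` object.
#' @export
skeleton_rule <- function(lhs, rhs) {
  structure(list(lhs = lhs, rhs = rhs), class = "skeleton_rule")
}

#' @rdname skeleton_rule
#' @param component component name.
#' @param states list of `elemental_state` attached to the pattern
#'   (possibly empty: an unconstrained component).
#' @export
component_pattern <- function(component, states = list()) {
  list(component = component, states = states)
}

side_components <- function(side)
  unique(vapply(side, function(p) p$component, ""))

side_states <- function(side)
  unlist(lapply(side, function(p)
    vapply(p$states, function(s) s$name, "")), use.names = FALSE)

#' Classify the effects of a skeleton rule
#'
#' Applies the four mode definitions (see [elemental_reactions]) to every
#' state in `universe` carried by a component mentioned in the rule. A state
#' appearing unchanged on both sides yields no effect. Guards (the
#' effect-specific source states required for the reaction to actually fire)
#' are assigned afterwards: production and consumption effects are guarded by
#' the reaction's full consumed set, synthesis and degradation effects are
#' unguarded.
#'
#' @param rule a `skeleton_rule`.
#' @param universe list of all declared `elemental_state`s in the network.
#' @return list of effects, each `list(state, mode, guards)`.
#' @export
classify_effects <- function(rule, universe) {
  stopifnot(inherits(rule, "skeleton_rule"))
  lhs_comp <- side_components(rule$lhs)
  rhs_comp <- side_components(rule$rhs)
  lhs_states <- side_states(rule$lhs)
  rhs_states <- side_states(rule$rhs)
  lhs_state_objs <- unlist(lapply(rule$lhs, function(p) p$states),
                           recursive = FALSE)

  effects <- list()
  for (s in universe) {
    if (s$variant == "input") next
    comps <- state_components(s)
    if (!any(comps %in% c(lhs_comp, rhs_comp))) next
    on_lhs <- s$name %in% lhs_states
    on_rhs <- s$name %in% rhs_states
    mode <- NULL
    if (on_rhs && !on_lhs && any(comps %in% lhs_comp)) {
      mode <- "production"
    } else if (on_lhs && !on_rhs && any(comps %in% rhs_comp)) {
      mode <- "consumption"
    } else if (on_rhs && !any(comps %in% lhs_comp)) {
      mode <- "synthesis"
    } else if (!on_rhs && !on_lhs) {
      # degradation is assessed per carrier component
      for (cc in comps) {
        if (cc %in% lhs_comp && !(cc %in% rhs_comp)) {
          excl <- any(vapply(lhs_state_objs, function(ls)
            mutually_exclusive(s, ls), TRUE))
          if (!excl) { mode <- "degradation"; break }
        }
      }
    }
    if (!is.null(mode))
      effects <- c(effects, list(new_effect(s, mode)))
  }

  consumed <- vapply(Filter(function(e) e$mode == "consumption", effects),
                     function(e) e$state$name, "")
  lapply(effects, function(e) {
    if (e$mode %in% c("production", "consumption")) e$guards <- consumed
    e
  })
}

new_reaction <- function(name, reacting_components, effects,
                         bidirectional_origin = NA_character_,
                         row = NULL) {
  structure(list(name = name,
                 reacting_components = reacting_components,
                 effects = effects,
                 bidirectional_origin = bidirectional_origin,
                 row = row),
            class = "elemental_reaction")
}

#' @export
print.elemental_reaction <- function(x, ...) {
  cat("<elemental_reaction> ", x$name, "\n", sep = "")
  for (e in x$effects) {
    cat("  ", e$mode, ": ", e$state$name, sep = "")
    if (length(e$guards)) cat("  [if ", paste(e$guards, collapse = " & "), "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

reaction_consumed <- function(r)
  unique(vapply(Filter(function(e) e$mode == "consumption", r$effects),
                function(e) e$state$name, ""))

reaction_has_mode <- function(r, mode)
  any(vapply(r$effects, function(e) e$mode == mode, TRUE))

# --- built-in reaction-type shorthand ---------------------------------------
#
# The shorthand table maps the reaction types used in practice to skeleton
# rules. `subject`/`object` are the raw table cells; `universe` is the list
# of declared states (needed for syn/deg, whose rules mention unconstrained
# or fully-neutral components).

reaction_types <- function()
  c("p+", "p-", "pt", "ap", "ppi+", "ppi-", "ppi", "syn", "deg")

mod_states_for <- function(locus, label = "P") {
  cr <- parse_locus(locus)
  if (is.na(cr$site))
    stop("reaction needs a residue locus like A_[(r)], got '", locus, "'")
  list(neutral = new_state("modification", list(cr), "0", neutral = TRUE),
       modified = new_state("modification", list(cr), label))
}

bond_states_for <- function(locus1, locus2) {
  cr1 <- parse_locus(locus1); cr2 <- parse_locus(locus2)
  if (is.na(cr1$site) || is.na(cr2$site))
    stop("interaction needs domain loci like A_[d], got '",
         locus1, "', '", locus2, "'")
  list(free1 = new_state("empty_binding", list(cr1), neutral = TRUE),
       free2 = new_state("empty_binding", list(cr2), neutral = TRUE),
       bond = new_state("bond", list(cr1, cr2)))
}

# States implied by one (already ppi-split) reaction row; used to build the
# state universe before skeleton rules are classified.
implied_states <- function(type, subject, object) {
  switch(type,
    "p+" = , "p-" = unname(mod_states_for(object)),
    "ap" = unname(mod_states_for(object)),
    "pt" = c(unname(mod_states_for(subject)), unname(mod_states_for(object))),
    "ppi+" = , "ppi-" = unname(bond_states_for(subject, object)),
    "syn" = , "deg" = list(),
    stop("unknown reaction type '", type, "'")
  )
}

# Skeleton rule for one reaction row given the full state universe.
shorthand_rule <- function(type, subject, object, universe) {
  subj_comp <- if (nzchar(subject) && subject != "-")
    parse_locus(subject)$component else NULL
  switch(type,
    "p+" = , "p-" = {
      ms <- mod_states_for(object)
      tgt <- state_components(ms$neutral)
      before <- if (type == "p+") ms$neutral else ms$modified
      after <- if (type == "p+") ms$modified else ms$neutral
      lhs <- list(component_pattern(tgt, list(before)))
      rhs <- list(component_pattern(tgt, list(after)))
      if (!is.null(subj_comp) && !identical(subj_comp, tgt)) {
        lhs <- c(list(component_pattern(subj_comp)), lhs)
        rhs <- c(list(component_pattern(subj_comp)), rhs)
      }
      skeleton_rule(lhs, rhs)
    },
    "ap" = {
      ms <- mod_states_for(object)
      tgt <- state_components(ms$neutral)
      skeleton_rule(list(component_pattern(tgt, list(ms$neutral))),
                    list(component_pattern(tgt, list(ms$modified))))
    },
    "pt" = {
      donor <- mod_states_for(subject)
      acceptor <- mod_states_for(object)
      dc <- state_components(donor$neutral)
      ac <- state_components(acceptor$neutral)
      skeleton_rule(
        list(component_pattern(dc, list(donor$modified)),
             component_pattern(ac, list(acceptor$neutral))),
        list(component_pattern(dc, list(donor$neutral)),
             component_pattern(ac, list(acceptor$modified))))
    },
    "ppi+" = , "ppi-" = {
      bs <- bond_states_for(subject, object)
      c1 <- state_components(bs$free1); c2 <- state_components(bs$free2)
      free_side <- if (identical(c1, c2))
        list(component_pattern(c1, list(bs$free1, bs$free2)))
      else
        list(component_pattern(c1, list(bs$free1)),
             component_pattern(c2, list(bs$free2)))
      bound_side <- if (identical(c1, c2))
        list(component_pattern(c1, list(bs$bond)))
      else
        list(component_pattern(c1, list(bs$bond)),
             component_pattern(c2, list(bs$bond)))
      if (type == "ppi+") skeleton_rule(free_side, bound_side)
      else skeleton_rule(bound_side, free_side)
    },
    "syn" = {
      # RHS: the synthesised component in all-neutral form (or bare if generic)
      neutrals <- Filter(function(s)
        s$neutral && object %in% state_components(s), universe)
      if (length(neutrals) == 0L) {
        comp_state <- Filter(function(s)
          s$variant == "component" && s$name == object, universe)
        neutrals <- comp_state
      }
      lhs <- if (!is.null(subj_comp)) list(component_pattern(subj_comp)) else list()
      rhs0 <- list(component_pattern(object, neutrals))
      if (!is.null(subj_comp))
        rhs0 <- c(list(component_pattern(subj_comp)), rhs0)
      skeleton_rule(lhs, rhs0)
    },
    "deg" = {
      lhs <- list(component_pattern(object))
      rhs <- list()
      if (!is.null(subj_comp)) {
        lhs <- c(list(component_pattern(subj_comp)), lhs)
        rhs <- list(component_pattern(subj_comp))
      }
      skeleton_rule(lhs, rhs)
    },
    stop("unknown reaction type '", type, "'")
  )
}

# Components "reacting" in a shorthand reaction (the LHS components for
# synthesis; subject and object components otherwise).
shorthand_reacting <- function(type, subject, object) {
  subj <- if (nzchar(subject) && subject != "-")
    parse_locus(subject)$component else NULL
  obj <- if (nzchar(object) && object != "-")
    parse_locus(object)$component else NULL
  if (type == "syn") return(unique(c(subj)))
  unique(c(subj, obj))
}
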