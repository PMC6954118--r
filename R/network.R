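#' @name rxncon_network
#' @title Reaction-contingency networks and the model-document dialect
#'
#' @description
#' A reaction-contingency network couples a list of elemental reactions
#' (each carrying its effects on elemental states) with a list of
#' contingencies (constraints attaching Boolean combinations of states and
#' inputs to reactions). The structure is bipartite: reactions act on states
#' through effects, and states act on reactions through contingencies.
#'
#' The plain-text model-document dialect has two tables, tab- or
#' comma-separated, introduced by `[reactions]` and `[contingencies]`
#' section headers. Lines starting with `#` and blank lines are ignored.
#'
#' `[reactions]` columns: `id, type, subject, object, effects`.
#' `type` is one of the built-in shorthands `p+` (phosphorylation), `p-`
#' (dephosphorylation), `pt` (phosphotransfer), `ap`
#' (autophosphorylation), `ppi+`/`ppi-` (association / dissociation),
#' `ppi` (bidirectional interaction, split at parse time into `id+` and
#' `id-`), `syn` (synthesis) and `deg` (degradation) — or `explicit`, in
#' which case the `effects` column lists the effects directly as
#' `mode:state;mode:state;...`, optionally with per-effect guards as
#' `mode:state if guard1&guard2`. An empty subject is written `-`.
#'
#' `[contingencies]` columns: `target, type, effector`. `type` is one of
#' `!` (required), `x` (absolutely inhibitory), `K+` (stimulating), `K-`
#' (inhibitory), `0` (no effect), `?` (unknown, treated as `0`), or the
#' structural row kinds: `AND`/`OR`/`NOT` define a named Boolean node
#' (target `<name>`, effector `member1;member2;...`), `clamp` fixes a
#' reaction target to the constant `0` or `1`, and `out` (target an input
#' in square brackets) assigns the input target an update expression,
#' turning the input into an output. Effector leaves are state names,
#' inputs in square brackets (e.g. `[Turgor]`), or Boolean-node references
#' in angle brackets (e.g. `<complex>`).
NULL

split_row <- function(line) {
  sep <- if (grepl("\t", line, fixed = TRUE)) "\t" else ","
  trimws(strsplit(line, sep, fixed = TRUE)[[1]])
}

new_contingency <- function(target, ctype, effector)
  structure(list(target = target, ctype = ctype, effector = effector),
            class = "contingency")

# Resolve an effector cell to a bool_expr over state/input names.
# `bool_defs` is a named list of raw rows for <name> Boolean nodes.
resolve_effector <- function(cell, bool_defs, stack = character(0)) {
  cell <- trimws(cell)
  if (grepl("^<.*>$", cell)) {
    nm <- sub("^<(.*)>$", "\\1", cell)
    if (nm %in% stack)
      stop("cyclic Boolean-node definition involving <", nm, ">")
    def <- bool_defs[[nm]]
    if (is.null(def))
      stop("undefined Boolean node <", nm, ">")
    members <- lapply(strsplit(def$members, ";", fixed = TRUE)[[1]],
                      resolve_effector, bool_defs = bool_defs,
                      stack = c(stack, nm))
    return(switch(def$op,
      AND = bx_and(members),
      OR = bx_or(members),
      NOT = {
        if (length(members) != 1L)
          stop("NOT node <", nm, "> must have exactly one member")
        bx_not(members[[1]])
      }))
  }
  # leaf: a state name or [input]; referenced by original name
  bx_ref(cell)
}

parse_effect_cell <- function(cell) {
  entries <- strsplit(cell, ";", fixed = TRUE)[[1]]
  lapply(entries, function(en) {
    en <- trimws(en)
    guard_part <- character(0)
    if (grepl(" if ", en, fixed = TRUE)) {
      halves <- strsplit(en, " if ", fixed = TRUE)[[1]]
      en <- trimws(halves[1])
      guard_part <- trimws(strsplit(halves[2], "&", fixed = TRUE)[[1]])
    }
    m <- regmatches(en, regexec("^([a-z]+):(.*)$", en))[[1]]
    if (length(m) != 3L || !(m[2] %in% effect_modes()))
      stop("cannot parse effect entry '", en, "'")
    list(mode = m[2], state_name = trimws(m[3]), guards = guard_part)
  })
}

#' Parse a model document
#'
#' Parses the two-table dialect described under [rxncon_network] into a
#' validated network. Bidirectional `ppi` rows are split into forward
#' (`id+`) and reverse (`id-`) reactions, and degradation reactions are
#' expanded (see [expand_degradations]) so that every degradation reaction
#' degrades all states of its component and conditionally releases bond
#' partners.
#'
#' @param text the document, as a single string or character vector of lines.
#' @return an object of class `rxncon_network`.
#' @seealso [read_rxncon()] to read from a file, [serialise_rxncon()] for
#'   the inverse, [validate_network()] for diagnostics.
#' @export
parse_rxncon <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  lineno <- which(keep)

  section <- ""
  rx_rows <- list(); ct_rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[reactions\\]$", ln, ignore.case = TRUE)) {
      section <- "reactions"; next
    }
    if (grepl("^\\[contingencies\\]$", ln, ignore.case = TRUE)) {
      section <- "contingencies"; next
    }
    cells <- split_row(ln)
    if (section == "reactions") {
      if (identical(tolower(cells[1]), "id")) next  # header row
      if (length(cells) < 4L)
        stop("line ", lineno[i], ": reaction row needs id, type, subject, object")
      rx_rows[[length(rx_rows) + 1L]] <- list(
        id = cells[1], type = cells[2], subject = cells[3],
        object = cells[4],
        effects = if (length(cells) >= 5L) cells[5] else "",
        line = lineno[i])
    } else if (section == "contingencies") {
      if (identical(tolower(cells[1]), "target")) next
      if (length(cells) < 3L)
        stop("line ", lineno[i], ": contingency row needs target, type, effector")
      ct_rows[[length(ct_rows) + 1L]] <- list(
        target = cells[1], ctype = cells[2], effector = cells[3],
        line = lineno[i])
    } else {
      stop("line ", lineno[i], ": content before any [reactions]/[contingencies] section")
    }
  }
  if (section == "" && length(lines))
    stop("document has no [reactions] section")

  build_network(rx_rows, ct_rows)
}

#' @rdname parse_rxncon
#' @param path path to a model document file.
#' @export
read_rxncon <- function(path) {
  if (!file.exists(path)) stop("no such model document: ", path)
  parse_rxncon(readLines(path, warn = FALSE))
}

build_network <- function(rx_rows, ct_rows) {
  # split bidirectional interactions
  split_rows <- list()
  for (row in rx_rows) {
    if (identical(row$type, "ppi")) {
      fwd <- row; fwd$type <- "ppi+"; fwd$id <- paste0(row$id, "+")
      fwd$origin <- "forward"
      rev <- row; rev$type <- "ppi-"; rev$id <- paste0(row$id, "-")
      rev$origin <- "reverse"
      split_rows <- c(split_rows, list(fwd, rev))
    } else {
      row$origin <- NA_character_
      split_rows <- c(split_rows, list(row))
    }
  }
  ids <- vapply(split_rows, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate reaction name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  # ---- state universe --------------------------------------------------
  states <- list()
  add_state <- function(s) {
    if (is.null(states[[s$name]])) states[[s$name]] <<- s
  }
  explicit_rows <- Filter(function(r) identical(r$type, "explicit"), split_rows)
  typed_rows <- Filter(function(r) !identical(r$type, "explicit"), split_rows)
  for (row in typed_rows)
    for (s in implied_states(row$type, row$subject, row$object)) add_state(s)
  for (row in explicit_rows)
    for (en in parse_effect_cell(row$effects)) {
      add_state(parse_state(en$state_name))
      for (g in en$guards) add_state(parse_state(g))
    }

  # generic components: subjects/objects (and syn/deg objects) with no states
  sited_components <- unique(unlist(lapply(states, state_components)))
  mention_components <- unique(unlist(lapply(split_rows, function(row) {
    out <- character(0)
    for (cell in c(row$subject, row$object))
      if (nzchar(cell) && cell != "-" && !identical(row$type, "explicit"))
        out <- c(out, parse_locus(cell)$component)
    out
  })))
  for (cc in setdiff(mention_components, sited_components))
    add_state(new_state("component", list(carrier(cc))))

  # ---- reactions -------------------------------------------------------
  universe <- unname(states)
  reactions <- list()
  for (row in split_rows) {
    if (identical(row$type, "explicit")) {
      consumed <- character(0)
      entries <- parse_effect_cell(row$effects)
      for (en in entries)
        if (en$mode == "consumption") consumed <- c(consumed, en$state_name)
      effects <- lapply(entries, function(en) {
        guards <- if (length(en$guards)) en$guards
                  else if (en$mode %in% c("production", "consumption")) consumed
                  else character(0)
        new_effect(states[[en$state_name]], en$mode, guards)
      })
      reacting <- unique(unlist(lapply(effects, function(e)
        state_components(e$state))))
      if (reaction_has_mode_list(effects, "synthesis"))
        reacting <- setdiff(reacting, unlist(lapply(
          Filter(function(e) e$mode == "synthesis", effects),
          function(e) state_components(e$state))))
      rxn <- new_reaction(row$id, reacting, effects, row$origin, row)
    } else {
      rule <- shorthand_rule(row$type, row$subject, row$object, universe)
      effects <- classify_effects(rule, universe)
      rxn <- new_reaction(row$id,
                          shorthand_reacting(row$type, row$subject, row$object),
                          effects, row$origin, row)
    }
    reactions[[rxn$name]] <- rxn
  }

  # ---- contingencies ---------------------------------------------------
  bool_defs <- list()
  for (row in ct_rows)
    if (row$ctype %in% c("AND", "OR", "NOT")) {
      nm <- sub("^<(.*)>$", "\\1", row$target)
      bool_defs[[nm]] <- list(op = row$ctype, members = row$effector)
    }

  contingencies <- list()
  clamps <- logical(0)
  output_links <- list()
  inputs <- character(0)
  note_inputs <- function(e) {
    refs <- bx_refs(e)
    br <- refs[grepl("^\\[.*\\]$", refs)]
    inputs <<- unique(c(inputs, sub("^\\[(.*)\\]$", "\\1", br)))
  }
  for (row in ct_rows) {
    if (row$ctype %in% c("AND", "OR", "NOT")) next
    if (identical(row$ctype, "clamp")) {
      if (!row$effector %in% c("0", "1"))
        stop("line ", row$line, ": clamp effector must be 0 or 1")
      clamps[[row$target]] <- identical(row$effector, "1")
      next
    }
    if (identical(row$ctype, "out")) {
      if (!grepl("^\\[.*\\]$", row$target))
        stop("line ", row$line, ": 'out' target must be an input like [Turgor]")
      nm <- sub("^\\[(.*)\\]$", "\\1", row$target)
      eff <- resolve_effector(row$effector, bool_defs)
      output_links[[nm]] <- eff
      inputs <- unique(c(inputs, nm))
      note_inputs(eff)
      next
    }
    if (!row$ctype %in% c("!", "x", "K+", "K-", "0", "?"))
      stop("line ", row$line, ": unknown contingency type '", row$ctype, "'")
    eff <- resolve_effector(row$effector, bool_defs)
    note_inputs(eff)
    contingencies[[length(contingencies) + 1L]] <-
      new_contingency(row$target, row$ctype, eff)
  }

  # closure: every non-input effector leaf must name a declared state
  for (ct in contingencies)
    for (ref in bx_refs(ct$effector))
      if (!grepl("^\\[.*\\]$", ref) && is.null(states[[ref]]))
        stop("contingency on '", ct$target,
             "' references undeclared state '", ref, "'")

  net <- structure(list(states = states,
                        reactions = reactions,
                        contingencies = contingencies,
                        inputs = inputs,
                        clamps = clamps,
                        output_links = output_links,
                        source = list(reactions = rx_rows,
                                      contingencies = ct_rows)),
                   class = "rxncon_network")
  expand_degradations(net)
}

reaction_has_mode_list <- function(effects, mode)
  any(vapply(effects, function(e) e$mode == mode, TRUE))

#' Network components and their sites
#'
#' @param net an `rxncon_network`.
#' @return data frame with columns `component`, `site` (NA for generic
#'   components), `site_kind`.
#' @export
network_components <- function(net) {
  rows <- list()
  for (s in net$states) {
    if (s$variant == "input") next
    for (cr in s$carriers)
      rows[[length(rows) + 1L]] <-
        data.frame(component = cr$component, site = cr$site,
                   site_kind = cr$site_kind, stringsAsFactors = FALSE)
  }
  df <- unique(do.call(rbind, rows))
  rownames(df) <- NULL
  df[order(match(df$component, df$component)), , drop = FALSE]
}

#' @export
print.rxncon_network <- function(x, ...) {
  n_state <- sum(vapply(x$states, function(s) s$variant != "input", TRUE))
  cat("<rxncon_network> ", length(x$reactions), " reactions, ",
      n_state, " states, ", length(x$contingencies), " contingencies, ",
      length(x$inputs), " input(s)\n", sep = "")
  invisible(x)
}

#' Expand degradation reactions
#'
#' Every degradation reaction of a component X degrades all states carried
#' by X. For each degraded bond state X--Y with a partner component Y, a
#' conditional production effect is added: the degradation of the dimer
#' releases the partner's empty binding domain, guarded by the bond state
#' itself. If a degradation reaction is constrained by a single required
#' contingency whose effector is a top-level OR, the reaction is duplicated
#' once per disjunct, each duplicate gated by one disjunct. The operation
#' is idempotent; [parse_rxncon()] applies it automatically.
#'
#' @param net an `rxncon_network`.
#' @return the expanded network.
#' @export
expand_degradations <- function(net) {
  for (nm in names(net$reactions)) {
    r <- net$reactions[[nm]]
    degs <- Filter(function(e) e$mode == "degradation", r$effects)
    if (length(degs) == 0L) next
    # components wholly degraded by this reaction
    deg_names <- vapply(degs, function(e) e$state$name, "")
    comp_states <- function(cc) vapply(
      Filter(function(s) s$variant != "input" && cc %in% state_components(s),
             net$states), function(s) s$name, "")
    cand <- unique(unlist(lapply(degs, function(e) state_components(e$state))))
    degraded_comps <- Filter(function(cc)
      all(comp_states(cc) %in% deg_names), cand)
    existing <- vapply(r$effects, function(e)
      paste(e$mode, e$state$name), "")
    for (j in seq_along(r$effects)) {
      e <- r$effects[[j]]
      if (e$mode != "degradation" || e$state$variant != "bond") next
      partners <- Filter(function(cr)
        !(cr$component %in% degraded_comps), e$state$carriers)
      if (length(partners) == 0L) next
      # a surviving bond partner turns the event into a consumption of the
      # bond (the partner component persists on the product side) plus a
      # conditional production of the partner's empty binding domain, both
      # guarded by the bond itself
      r$effects[[j]] <- new_effect(e$state, "consumption", e$state$name)
      for (cr in partners) {
        rel <- new_state("empty_binding", list(cr), neutral = TRUE)
        key <- paste("production", rel$name)
        if (key %in% existing) next
        if (is.null(net$states[[rel$name]]))
          net$states[[rel$name]] <- rel
        r$effects <- c(r$effects,
                       list(new_effect(rel, "production", e$state$name)))
        existing <- c(existing, key)
      }
    }
    net$reactions[[nm]] <- r
  }

  # duplication per top-level OR disjunct of a required contingency
  new_reactions <- list(); new_contingencies <- list()
  dup_done <- FALSE
  for (ct in net$contingencies) {
    r <- net$reactions[[ct$target]]
    if (!is.null(r) && reaction_has_mode(r, "degradation") &&
        identical(ct$ctype, "!") && ct$effector$kind == "or") {
      for (k in seq_along(ct$effector$args)) {
        dup <- r
        dup$name <- paste0(r$name, "@", k)
        new_reactions[[dup$name]] <- dup
        new_contingencies[[length(new_contingencies) + 1L]] <-
          new_contingency(dup$name, "!", ct$effector$args[[k]])
        if (r$name %in% names(net$clamps))
          net$clamps[[dup$name]] <- net$clamps[[r$name]]
      }
      net$reactions[[r$name]] <- NULL
      net$clamps <- net$clamps[names(net$clamps) != r$name]
      dup_done <- TRUE
    } else {
      new_contingencies[[length(new_contingencies) + 1L]] <- ct
    }
  }
  if (dup_done) {
    net$reactions <- c(net$reactions, new_reactions)
    # retarget any other contingencies of the duplicated reactions
    dup_bases <- unique(sub("@[0-9]+$", "", names(new_reactions)))
    final <- list()
    for (ct in new_contingencies) {
      if (ct$target %in% dup_bases) {
        for (dn in names(new_reactions)[sub("@[0-9]+$", "",
                                            names(new_reactions)) == ct$target])
          final[[length(final) + 1L]] <-
            new_contingency(dn, ct$ctype, ct$effector)
      } else final[[length(final) + 1L]] <- ct
    }
    net$contingencies <- final
  } else {
    net$contingencies <- new_contingencies
  }
  net
}

#' Validate a network
#'
#' Reports diagnostics without raising errors: contingencies targeting
#' undeclared reactions, components never referenced by any reaction, and
#' non-neutral states whose every production route starts from another
#' non-neutral state (unsupported by the one-step synthesis term; see the
#' compiler documentation).
#'
#' @param net an `rxncon_network`.
#' @return character vector of diagnostics (empty when the network is clean).
#' @export
validate_network <- function(net) {
  diags <- character(0)
  for (ct in net$contingencies)
    if (is.null(net$reactions[[ct$target]]))
      diags <- c(diags, paste0("contingency targets undeclared reaction '",
                               ct$target, "'"))
  for (nm in names(net$clamps))
    if (is.null(net$reactions[[nm]]))
      diags <- c(diags, paste0("clamp targets undeclared reaction '", nm, "'"))

  acted <- unique(unlist(lapply(net$reactions, function(r)
    c(r$reacting_components,
      unlist(lapply(r$effects, function(e) state_components(e$state)))))))
  comps <- unique(unlist(lapply(net$states, function(s)
    if (s$variant == "input") NULL else state_components(s))))
  for (cc in setdiff(comps, acted))
    diags <- c(diags, paste0("component '", cc,
                             "' is not referenced by any reaction"))

  # synthesis-path depth: when a state's neutral counterpart is synthesised,
  # the synthesis term needs some producer of the state to consume that
  # neutral counterpart (states one step from neutral); otherwise the
  # one-step synthesis term cannot express the synthesis path
  synthesised <- unique(unlist(lapply(net$reactions, function(r)
    vapply(Filter(function(e) e$mode == "synthesis", r$effects),
           function(e) e$state$name, ""))))
  for (s in net$states) {
    if (s$neutral || !s$variant %in% c("modification", "bond")) next
    ncp <- vapply(neutral_counterpart(s), function(n) n$name, "")
    if (!any(ncp %in% synthesised)) next
    producers <- Filter(function(r) any(vapply(r$effects, function(e)
      e$mode == "production" && identical(e$state$name, s$name), TRUE)),
      net$reactions)
    if (length(producers) == 0L) next
    ok <- any(vapply(producers, function(r)
      any(ncp %in% reaction_consumed(r)) ||
        length(reaction_consumed(r)) == 0L, TRUE))
    if (!ok)
      diags <- c(diags, paste0("state '", s$name,
        "' is producible only from non-neutral states ",
        "(unsupported synthesis-path depth)"))
  }
  diags
}

#' Serialise a network back to the model-document dialect
#'
#' Re-emits the source rows the network was parsed from, so that
#' `parse_rxncon(serialise_rxncon(net))` reproduces the network exactly.
#'
#' @param net an `rxncon_network` produced by [parse_rxncon()].
#' @return character scalar (the document).
#' @export
serialise_rxncon <- function(net) {
  out <- c("[reactions]", "id\ttype\tsubject\tobject\teffects")
  for (row in net$source$reactions)
    out <- c(out, paste(row$id, row$type, row$subject, row$object,
                        row$effects, sep = "\t"))
  out <- c(out, "", "[contingencies]", "target\ttype\teffector")
  for (row in net$source$contingencies)
    out <- c(out, paste(row$target, row$ctype, row$effector, sep = "\t"))
  paste0(paste(out, collapse = "\n"), "\n")
}
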