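#' @name elemental_states
#' @title Elemental states
#'
#' @description
#' An elemental state is a single site-resolved observable on a molecule:
#' a covalent modification at a specific residue, a bond at a specific
#' domain, the neutral (unmodified / unbound) complement of either, the
#' bare presence of a component with no sites ("generic" component state),
#' or an external input. State-name grammar:
#'
#' * `A_[(r)]-{P}` — modification `P` at residue `r` of component `A`;
#'   the tag `{0}` denotes the neutral, unmodified state.
#' * `A_[d]--B_[e]` — bond between domain `d` of `A` and domain `e` of `B`
#'   (the two carriers may belong to the same component for intra-molecular
#'   bonds).
#' * `A_[d]--0` — empty (unbound) binding domain; neutral.
#' * `A` — generic component state for a component with no sites.
#' * `[Turgor]` — input.
NULL

carrier <- function(component, site = NA_character_,
                    site_kind = NA_character_) {
  list(component = component, site = site, site_kind = site_kind)
}

new_state <- function(variant, carriers, label = NULL, neutral = FALSE) {
  if (variant == "bond" && length(carriers) == 2L) {
    key <- vapply(carriers, function(cr) paste(cr$component, cr$site), "")
    carriers <- carriers[order(key)]  # canonical carrier order
  }
  s <- structure(list(variant = variant, carriers = carriers,
                      label = label, neutral = neutral),
                 class = "elemental_state")
  s$name <- state_name_of(s)
  s
}

state_name_of <- function(s) {
  loc <- function(cr) {
    if (is.na(cr$site)) return(cr$component)
    if (identical(cr$site_kind, "residue"))
      paste0(cr$component, "_[(", cr$site, ")]")
    else paste0(cr$component, "_[", cr$site, "]")
  }
  switch(s$variant,
    modification = paste0(loc(s$carriers[[1]]), "-{", s$label, "}"),
    bond = paste0(loc(s$carriers[[1]]), "--", loc(s$carriers[[2]])),
    empty_binding = paste0(loc(s$carriers[[1]]), "--0"),
    component = s$carriers[[1]]$component,
    input = paste0("[", s$label, "]")
  )
}

#' @export
print.elemental_state <- function(x, ...) {
  cat("<elemental_state> ", x$name,
      if (x$neutral) " (neutral)" else "", "\n", sep = "")
  invisible(x)
}

# Parse one site locus "Comp_[(r)]" or "Comp_[d]"; returns a carrier.
parse_locus <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z][A-Za-z0-9]*)_\\[\\(([A-Za-z0-9]+)\\)\\]$", text))[[1]]
  if (length(m) == 3L) return(carrier(m[2], m[3], "residue"))
  m <- regmatches(text, regexec("^([A-Za-z][A-Za-z0-9]*)_\\[([A-Za-z0-9]+)\\]$", text))[[1]]
  if (length(m) == 3L) return(carrier(m[2], m[3], "domain"))
  if (grepl("^[A-Za-z][A-Za-z0-9]*$", text)) return(carrier(text))
  stop("cannot parse site locus '", text, "'")
}

#' Parse a state name
#'
#' @param text a state name in the grammar described under
#'   [elemental_states].
#' @return an `elemental_state`.
#' @export
parse_state <- function(text) {
  text <- trimws(text)
  if (grepl("^\\[[A-Za-z][A-Za-z0-9_]*\\]$", text)) {
    nm <- sub("^\\[(.*)\\]$", "\\1", text)
    return(new_state("input", list(carrier(nm)), label = nm))
  }
  m <- regmatches(text, regexec("^(.*)-\\{([A-Za-z0-9]+)\\}$", text))[[1]]
  if (length(m) == 3L) {
    cr <- parse_locus(m[2])
    if (is.na(cr$site)) stop("modification state needs a site: '", text, "'")
    return(new_state("modification", list(cr), label = m[3],
                     neutral = identical(m[3], "0")))
  }
  if (grepl("--", text, fixed = TRUE)) {
    halves <- strsplit(text, "--", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("cannot parse bond state '", text, "'")
    cr1 <- parse_locus(halves[1])
    if (is.na(cr1$site)) stop("bond state needs a domain: '", text, "'")
    if (identical(halves[2], "0"))
      return(new_state("empty_binding", list(cr1), neutral = TRUE))
    cr2 <- parse_locus(halves[2])
    if (is.na(cr2$site)) stop("bond state needs a domain: '", text, "'")
    return(new_state("bond", list(cr1, cr2)))
  }
  if (grepl("^[A-Za-z][A-Za-z0-9]*$", text))
    return(new_state("component", list(carrier(text))))
  stop("cannot parse state name '", text, "'")
}

#' Neutral counterpart of a non-neutral state
#'
#' The neutral (unmodified / unbound) state living on the same site(s).
#' For a modification it is the `{0}` state of the residue; for a bond it
#' is the pair of empty-binding states, one per carrier domain.
#'
#' @param s a non-neutral `elemental_state` of variant modification or bond.
#' @return a list of `elemental_state` (length 1 for modifications,
#'   2 for bonds; 1 for intra-molecular bonds of a single domain pair with
#'   distinct domains still yields 2 empty-binding states).
#' @export
neutral_counterpart <- function(s) {
  stopifnot(inherits(s, "elemental_state"))
  if (s$neutral || s$variant %in% c("input", "component"))
    stop("state '", s$name, "' has no neutral counterpart")
  if (s$variant == "modification")
    return(list(new_state("modification", s$carriers, label = "0",
                          neutral = TRUE)))
  lapply(s$carriers, function(cr)
    new_state("empty_binding", list(cr), neutral = TRUE))
}

#' Mutual exclusivity of two elemental states
#'
#' Two distinct states are mutually exclusive on a molecule if and only if
#' they share a (component, site) carrier: every site holds exactly one of
#' its states at a time.
#'
#' @param s1,s2 `elemental_state` objects.
#' @return logical scalar; `FALSE` for identical states.
#' @export
mutually_exclusive <- function(s1, s2) {
  stopifnot(inherits(s1, "elemental_state"), inherits(s2, "elemental_state"))
  if (identical(s1$name, s2$name)) return(FALSE)
  locs <- function(s) vapply(s$carriers, function(cr)
    paste(cr$component, cr$site), "")
  l1 <- locs(s1); l2 <- locs(s2)
  l1 <- l1[!grepl(" NA$", l1)]; l2 <- l2[!grepl(" NA$", l2)]
  any(l1 %in% l2)
}

state_components <- function(s)
  unique(vapply(s$carriers, function(cr) cr$component, ""))

state_sites <- function(s) {
  keep <- !vapply(s$carriers, function(cr) is.na(cr$site), TRUE)
  vapply(s$carriers[keep], function(cr) paste(cr$component, cr$site), "")
}

#' Sanitise a name into a BoolNet-compatible symbol
#'
#' Maps arbitrary state/reaction names to `[A-Za-z0-9_]` symbols:
#' `+`/`-` become `_plus`/`_minus` where they carry meaning, bond `--`
#' becomes `__`, and remaining punctuation collapses to `_`.
#'
#' @param name character vector of names.
#' @return character vector of symbols (not yet de-collided).
#' @export
sanitise_symbol <- function(name) {
  s <- name
  s <- gsub("--0", "__0", s, fixed = TRUE)
  s <- gsub("--", "__", s, fixed = TRUE)
  s <- gsub("-\\{([A-Za-z0-9]+)\\}", "_\\1", s)
  s <- gsub("\\+", "_plus", s)
  s <- gsub("-", "_minus", s)
  s <- gsub("[^A-Za-z0-9_]+", "_", s)
  s <- gsub("_+", "_", s)
  s <- gsub("^_|_$", "", s)
  ifelse(grepl("^[0-9]", s), paste0("x", s), s)
}
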