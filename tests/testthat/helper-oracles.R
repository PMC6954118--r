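# Hand-coded next-state oracle for the modification motif, written directly
# from the verbal hierarchy (synthesis wins; then component presence and
# degradation; a produced state turns/stays on even while consumed; an
# unproduced state persists until consumed). Independent of the compiler's
# expression builders: used to cross-check the compiled update rules by
# exhaustive truth-table comparison.
mod_motif_next <- function(a0, ap, syn, deg, fwd, rev) {
  present <- a0 || ap
  next_a0 <- if (syn) TRUE
    else if (!present || deg) FALSE
    else if (rev && ap) TRUE           # produced by dephosphorylation
    else a0 && !(fwd && a0)            # persists unless consumed
  next_ap <- if (syn && fwd && a0) TRUE  # synthesised neutral feeds p+
    else if (!present || deg) FALSE
    else if (fwd && a0) TRUE
    else ap && !(rev && ap)
  c(a0 = next_a0, ap = next_ap)
}

# all 2^n assignments over `vars`, as a list of named logical vectors
all_assignments <- function(vars) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(vars)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

# random bool_expr generator for round-trip properties
random_expr <- function(vars, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.15)
      return(bx_const(stats::runif(1) < 0.5))
    return(bx_ref(sample(vars, 1)))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") return(bx_not(random_expr(vars, depth - 1)))
  n <- sample(2:3, 1)
  args <- lapply(seq_len(n), function(i) random_expr(vars, depth - 1))
  if (op == "and") bx_and(args) else bx_or(args)
}

write_doc <- function(text) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
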