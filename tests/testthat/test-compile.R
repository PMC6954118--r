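# A two-site network used by several cases: component A with a
# phosphosite and a binding domain, partner B, generic kinase K.
two_site_net <- function() {
  parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "bind\tppi\tA_[d]\tB_[e]\n"))
}

test_that("component expressions group states by site", {
  net <- modification_motif()
  expect_identical(bx_deparse(component_expression(net, "A")),
                   "(A_[(r)]-{0} | A_[(r)]-{P})")
  # generic component: its own state target
  net2 <- two_site_net()
  expect_identical(bx_deparse(component_expression(net2, "K")), "K")
  # two sites: conjunction over sites of disjunction over states
  expect_identical(
    bx_deparse(component_expression(net2, "A")),
    "((A_[(r)]-{0} | A_[(r)]-{P}) & (A_[d]--0 | A_[d]--B_[e]))")
})

test_that("reacting and carrier components compose component expressions", {
  net <- two_site_net()
  expect_identical(
    bx_deparse(reacting_components(net, "kin")),
    "(K & (A_[(r)]-{0} | A_[(r)]-{P}) & (A_[d]--0 | A_[d]--B_[e]))")
  # bond states are carried by both components
  expect_identical(
    bx_deparse(carrier_components(interaction_motif(), "A_[d]--B_[e]")),
    "((A_[d]--0 | A_[d]--B_[e]) & (B_[e]--0 | A_[d]--B_[e]))")
  expect_identical(bx_deparse(carrier_components(net, "K")), "K")
  # a synthesis-only reaction has no reacting components: empty conjunction
  expect_true(reacting_components(modification_motif(), "syn")$value)
})

test_that("primed reactions conjoin the reaction with its source states", {
  net <- modification_motif()
  expect_identical(bx_deparse(primed_reaction(net, "p+")),
                   "(p+ & A_[(r)]-{0})")
  expect_identical(bx_deparse(primed_reaction(net, "syn")), "syn")
  # effect-specific variant: conditional release production of the
  # degradation reaction is primed with the degraded bond
  inet <- interaction_motif()
  rel <- Filter(function(e)
    e$mode == "production" && e$state$name == "B_[e]--0",
    inet$reactions[["deg"]]$effects)[[1]]
  expect_identical(bx_deparse(primed_reaction(inet, "deg", rel$guards)),
                   "(deg & A_[d]--B_[e])")
})

test_that("synthesis terms distinguish neutral and one-step states", {
  net <- modification_motif()
  expect_identical(bx_deparse(synthesis_term(net, "A_[(r)]-{0}")), "syn")
  expect_identical(bx_deparse(synthesis_term(net, "A_[(r)]-{P}")),
                   "(syn & p+ & A_[(r)]-{0})")
  # no synthesis route: the empty union
  net2 <- two_site_net()
  expect_false(synthesis_term(net2, "A_[(r)]-{P}")$value)
})

test_that("contingency expressions honour types and policies", {
  doc <- paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "aux\tp-\tK\tA_[(r)]\n",
    "\n[contingencies]\ntarget\ttype\teffector\n",
    "kin\t!\tA_[(r)]-{0}\n",
    "kin\tx\t[Stress]\n",
    "kin\t0\tA_[(r)]-{P}\n",
    "kin\t?\tA_[(r)]-{P}\n",
    "aux\tK+\tA_[(r)]-{P}\n")
  net <- parse_rxncon(doc)
  expect_identical(bx_deparse(contingency_expression(net, "kin")),
                   "(A_[(r)]-{0} & ![Stress])")
  # no contingencies -> TRUE
  expect_true(contingency_expression(modification_motif(), "p+")$value)
  # quantitative policy: ignored by default, folded in when strict
  expect_true(contingency_expression(net, "aux")$value)
  strict <- compile_options(k_plus = "strict")
  expect_identical(bx_deparse(contingency_expression(net, "aux", strict)),
                   "A_[(r)]-{P}")
})

test_that("reaction updates conjoin components and contingencies", {
  net <- hog_model()
  expect_identical(
    bx_deparse(reaction_update(net, "sln1_ap")),
    "((Sln1_[(HK)]-{0} | Sln1_[(HK)]-{P}) & [Turgor])")
  # clamped reactions compile to constants, bypassing the rule
  mnet <- modification_motif(fwd = TRUE)
  expect_true(reaction_update(mnet, "p+")$value)
  expect_false(reaction_update(mnet, "deg")$value)
})

test_that("the non-smoothed state update matches the derived form", {
  # a pure two-reaction modification cycle (no synthesis/degradation)
  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "p+\tp+\t-\tA_[(r)]\n",
    "p-\tp-\t-\tA_[(r)]\n"))
  opts <- compile_options(smoothing = FALSE)
  expect_identical(
    bx_deparse(state_update(net, "A_[(r)]-{P}", opts)),
    paste0("((A_[(r)]-{0} | A_[(r)]-{P}) & ((p+ & A_[(r)]-{0}) | ",
           "(A_[(r)]-{P} & !(p- & A_[(r)]-{P}))))"))
  # a state nothing acts on persists gated by its carriers
  lone <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "bind\tppi+\tA_[d]\tB_[e]\n"))
  # B_[e]--0 is consumed by bind but A_[d]--B_[e] has no consumer/degrader:
  expect_identical(
    bx_deparse(state_update(lone, "A_[d]--B_[e]", opts)),
    paste0("((A_[d]--0 | A_[d]--B_[e]) & (B_[e]--0 | A_[d]--B_[e]) & ",
           "((bind & A_[d]--0 & B_[e]--0) | A_[d]--B_[e]))"))
})

test_that("compiled motif rules reproduce the hand-coded truth table", {
  # exhaustive: all 2^4 clamp settings x 2^2 state assignments
  tf <- c(FALSE, TRUE)
  opts <- compile_options(smoothing = FALSE)
  for (syn in tf) for (deg in tf) for (fwd in tf) for (rev in tf) {
    m <- compile_bbm(modification_motif(syn, deg, fwd, rev), opts)
    for (a0 in tf) for (ap in tf) {
      v <- m$init
      v[["A_r_0"]] <- a0; v[["A_r_P"]] <- ap
      nxt <- step_bbm(m, v)
      oracle <- mod_motif_next(a0, ap, syn, deg, fwd, rev)
      expect_identical(unname(nxt[["A_r_0"]]), unname(oracle[["a0"]]),
        label = sprintf("a0 next, cfg s%d d%d f%d r%d from (%d,%d)",
                        syn, deg, fwd, rev, a0, ap))
      expect_identical(unname(nxt[["A_r_P"]]), unname(oracle[["ap"]]),
        label = sprintf("ap next, cfg s%d d%d f%d r%d from (%d,%d)",
                        syn, deg, fwd, rev, a0, ap))
    }
  }
})

test_that("degrading the dimer releases the partner's unbound state", {
  m <- compile_bbm(interaction_motif(deg = TRUE),
                   compile_options(smoothing = FALSE))
  v <- m$init
  v[["A_d_0"]] <- FALSE; v[["A_d_B_e"]] <- TRUE; v[["B_e_0"]] <- FALSE
  nxt <- step_bbm(m, v)
  expect_true(nxt[["B_e_0"]])
})

test_that("smoothing widens producer source checks by one step", {
  net <- modification_motif(fwd = TRUE, rev = TRUE)
  # a producer with no source states is unchanged
  syn_net <- modification_motif(syn = TRUE)
  expect_identical(bx_deparse(smoothed_producer(syn_net, "syn", character(0))),
                   "syn")
  # block III smoothed from a single initiated state reaches both-true
  m <- compile_bbm(net, compile_options(smoothing = TRUE))
  v <- m$init; v[["A_r_0"]] <- TRUE; v[["A_r_P"]] <- FALSE
  res <- simulate_to_attractor(m, v)
  expect_identical(res$period, 1L)
  expect_true(res$attractor[[1]][["A_r_0"]])
  expect_true(res$attractor[[1]][["A_r_P"]])
})

test_that("compilation is deterministic and counts targets correctly", {
  m1 <- compile_bbm(modification_motif())
  expect_identical(table(m1$targets$kind)[["state"]], 2L)
  expect_identical(table(m1$targets$kind)[["reaction"]], 4L)
  m2 <- compile_bbm(interaction_motif())
  expect_identical(table(m2$targets$kind)[["state"]], 3L)
  expect_identical(table(m2$targets$kind)[["reaction"]], 4L)
  # byte-identical output for identical input
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_boolnet(compile_bbm(hog_model(TRUE)), f1)
  write_boolnet(compile_bbm(hog_model(TRUE)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the default initial vector sets neutral and generic targets", {
  m <- compile_bbm(modification_motif())
  expect_true(m$init[["A_r_0"]])
  expect_false(m$init[["A_r_P"]])
  mi <- compile_bbm(interaction_motif())
  expect_true(mi$init[["A_d_0"]])
  expect_true(mi$init[["B_e_0"]])
  expect_false(mi$init[["A_d_B_e"]])
  # generic components are true, inputs false
  mh <- compile_bbm(hog_model())
  expect_true(mh$init[["Phos"]])
  expect_false(mh$init[["Turgor"]])
  # clamped targets are initialised at their clamp value
  mc <- compile_bbm(modification_motif(fwd = TRUE))
  expect_true(mc$init[["p_plus"]])
  expect_false(mc$init[["p_minus"]])
})

test_that("inputs default to identity and accept output links", {
  m <- compile_bbm(hog_model(cyclic = FALSE))
  expect_identical(bx_deparse(m$rules[["Turgor"]]), "Turgor")
  mc <- compile_bbm(hog_model(cyclic = TRUE))
  expect_identical(bx_deparse(mc$rules[["Turgor"]]), "Hot1_S_P")
})

test_that("states cannot outlive their carriers (monotone gate)", {
  # with no synthesis, clearing a state's carriers at t forces the state
  # false at t+1, whatever else is active
  set.seed(7)
  m <- compile_bbm(interaction_motif(deg = TRUE, fwd = TRUE, rev = TRUE),
                   compile_options(smoothing = TRUE))
  for (i in 1:50) {
    v <- m$init
    v[c("A_d_0", "A_d_B_e", "B_e_0")] <- stats::runif(3) < 0.5
    # clear all carriers of the bond
    v[c("A_d_0", "A_d_B_e", "B_e_0")] <- FALSE
    expect_false(step_bbm(m, v)[["A_d_B_e"]])
  }
})

test_that("synthesis dominates every removal term", {
  # whenever the synthesis term evaluates true at t, the state is true at
  # t+1 regardless of degradation or consumption
  m_net <- modification_motif(syn = TRUE, deg = TRUE, fwd = TRUE, rev = TRUE)
  m <- compile_bbm(m_net, compile_options(smoothing = FALSE))
  sigma0 <- synthesis_term(m_net, "A_[(r)]-{0}")
  sigmap <- synthesis_term(m_net, "A_[(r)]-{P}")
  ren <- function(e) rxnbool:::bx_rename(e, m$symbol_map)
  s0 <- ren(sigma0); sp <- ren(sigmap)
  for (v in all_assignments(c("A_r_0", "A_r_P"))) {
    w <- m$init
    w[names(v)] <- v
    nxt <- step_bbm(m, w)
    if (bx_eval(s0, w)) expect_true(nxt[["A_r_0"]])
    if (bx_eval(sp, w)) expect_true(nxt[["A_r_P"]])
  }
})

test_that("deeper-than-one-step synthesis paths are rejected", {
  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\teffects\n",
    "mk\tsyn\t-\tA\t\n",
    "kin\tp+\tK\tA_[(r)]\t\n",
    "kin2\texplicit\t-\t-\t",
    "consumption:A_[(r)]-{P};production:A_[(r)]-{PP}\n"))
  expect_error(synthesis_term(net, "A_[(r)]-{PP}"),
               "more than one production step")
  expect_error(compile_bbm(net), "validation failed")
})
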