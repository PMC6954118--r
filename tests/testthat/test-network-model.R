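test_that("state names parse into the five variants and print back", {
  cases <- list(
    list("A_[(r)]-{P}", "modification", FALSE),
    list("A_[(r)]-{0}", "modification", TRUE),
    list("A_[d]--B_[e]", "bond", FALSE),
    list("A_[d]--0", "empty_binding", TRUE),
    list("Ptc", "component", FALSE),
    list("[Turgor]", "input", FALSE))
  for (cs in cases) {
    s <- parse_state(cs[[1]])
    expect_identical(s$variant, cs[[2]])
    expect_identical(s$neutral, cs[[3]])
    expect_identical(s$name, cs[[1]])
  }
  # bond carrier order is canonical: both spellings denote the same state
  expect_identical(parse_state("B_[e]--A_[d]")$name, "A_[d]--B_[e]")
  expect_error(parse_state("A-{P}"), "needs a site")
})

test_that("neutral counterparts live on the same sites", {
  expect_identical(neutral_counterpart(parse_state("A_[(r)]-{P}"))[[1]]$name,
                   "A_[(r)]-{0}")
  bond_ncp <- neutral_counterpart(parse_state("A_[d]--B_[e]"))
  expect_setequal(vapply(bond_ncp, function(s) s$name, ""),
                  c("A_[d]--0", "B_[e]--0"))
  expect_error(neutral_counterpart(parse_state("A_[(r)]-{0}")),
               "no neutral counterpart")
  expect_error(neutral_counterpart(parse_state("[Turgor]")),
               "no neutral counterpart")
})

test_that("mutual exclusivity means sharing a (component, site) locus", {
  expect_true(mutually_exclusive(parse_state("A_[(r)]-{0}"),
                                 parse_state("A_[(r)]-{P}")))
  expect_true(mutually_exclusive(parse_state("A_[d]--0"),
                                 parse_state("A_[d]--B_[e]")))
  expect_false(mutually_exclusive(parse_state("A_[(r1)]-{P}"),
                                  parse_state("A_[d1]--B_[d2]")))
  expect_false(mutually_exclusive(parse_state("A_[(r)]-{P}"),
                                  parse_state("A_[(r)]-{P}")))
  # every non-neutral state excludes each of its neutral counterparts
  for (nm in c("A_[(r)]-{P}", "A_[d]--B_[e]")) {
    s <- parse_state(nm)
    for (n in neutral_counterpart(s))
      expect_true(mutually_exclusive(s, n))
  }
})

test_that("skeleton-rule classification applies the four mode definitions", {
  a0 <- parse_state("A_[(r)]-{0}")
  ap <- parse_state("A_[(r)]-{P}")
  universe <- list(a0, ap)

  # phosphorylation: A(r~0) -> A(r~P)
  eff <- classify_effects(
    skeleton_rule(list(component_pattern("A", list(a0))),
                  list(component_pattern("A", list(ap)))), universe)
  modes <- vapply(eff, function(e) e$mode, "")
  names(modes) <- vapply(eff, function(e) e$state$name, "")
  expect_identical(modes[["A_[(r)]-{P}"]], "production")
  expect_identical(modes[["A_[(r)]-{0}"]], "consumption")
  # consumption effects are their own guards
  cons <- eff[[which(modes == "consumption")]]
  expect_true(cons$state$name %in% cons$guards)

  # synthesis: {} -> A(r~0)
  eff <- classify_effects(
    skeleton_rule(list(), list(component_pattern("A", list(a0)))), universe)
  expect_identical(vapply(eff, function(e) e$mode, ""), "synthesis")
  expect_identical(eff[[1]]$state$name, "A_[(r)]-{0}")
  expect_length(eff[[1]]$guards, 0L)

  # degradation: A (unconstrained) -> {}: every state of A is degraded
  eff <- classify_effects(
    skeleton_rule(list(component_pattern("A")), list()), universe)
  expect_setequal(vapply(eff, function(e) e$state$name, ""),
                  c("A_[(r)]-{0}", "A_[(r)]-{P}"))
  expect_true(all(vapply(eff, function(e) e$mode == "degradation", TRUE)))

  # a state appearing unchanged on both sides yields no effect
  eff <- classify_effects(
    skeleton_rule(list(component_pattern("A", list(ap))),
                  list(component_pattern("A", list(ap)))), universe)
  expect_length(eff, 0L)
})

test_that("the effect-mode hierarchy is encoded and queryable", {
  expect_identical(effect_modes(),
                   c("synthesis", "degradation", "production", "consumption"))
  expect_true(mode_stronger("synthesis", "degradation"))
  expect_true(mode_stronger("degradation", "production"))
  expect_true(mode_stronger("production", "consumption"))
  expect_false(mode_stronger("consumption", "synthesis"))
})

test_that("a one-line phosphorylation entry defines the elemental pair", {
  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "\n[contingencies]\n"))
  expect_length(net$contingencies, 0L)
  r <- net$reactions[["kin"]]
  modes <- vapply(r$effects, function(e) paste(e$mode, e$state$name), "")
  expect_setequal(modes, c("production A_[(r)]-{P}",
                           "consumption A_[(r)]-{0}"))
  # generic kinase K gets its own component state
  expect_identical(net$states[["K"]]$variant, "component")
})

test_that("the modification motif document yields the four-reaction network", {
  net <- modification_motif()
  expect_length(net$reactions, 4L)
  non_component <- Filter(function(s)
    !s$variant %in% c("component", "input"), net$states)
  expect_length(non_component, 2L)
})

test_that("bidirectional interactions split into forward and reverse", {
  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "bind\tppi\tA_[d]\tB_[e]\n"))
  expect_setequal(names(net$reactions), c("bind+", "bind-"))
  expect_identical(net$reactions[["bind+"]]$bidirectional_origin, "forward")
  expect_identical(net$reactions[["bind-"]]$bidirectional_origin, "reverse")
  prod_fwd <- Filter(function(e) e$mode == "production",
                     net$reactions[["bind+"]]$effects)
  expect_identical(prod_fwd[[1]]$state$name, "A_[d]--B_[e]")
})

test_that("duplicate reaction names are rejected with the offending id", {
  expect_error(parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\nkin\tp-\tP\tA_[(r)]\n")),
    "duplicate reaction name.*kin")
})

test_that("degradation expands to all states plus guarded partner release", {
  net <- interaction_motif()
  deg <- net$reactions[["deg"]]
  key <- vapply(deg$effects, function(e) paste(e$mode, e$state$name), "")
  expect_setequal(key, c("degradation A_[d]--0",
                         "consumption A_[d]--B_[e]",
                         "production B_[e]--0"))
  rel <- deg$effects[[which(key == "production B_[e]--0")]]
  expect_identical(rel$guards, "A_[d]--B_[e]")
  bond <- deg$effects[[which(key == "consumption A_[d]--B_[e]")]]
  expect_identical(bond$guards, "A_[d]--B_[e]")

  # idempotence
  again <- expand_degradations(net)
  expect_identical(
    lapply(again$reactions, function(r) r$effects),
    lapply(net$reactions, function(r) r$effects))

  # a degradation with no bonds and no contingencies is left alone
  net2 <- modification_motif()
  key2 <- vapply(net2$reactions[["deg"]]$effects,
                 function(e) paste(e$mode, e$state$name), "")
  expect_setequal(key2, c("degradation A_[(r)]-{0}",
                          "degradation A_[(r)]-{P}"))
})

test_that("degradation gated by a top-level OR is duplicated per disjunct", {
  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "phos\tp-\tK\tA_[(r)]\n",
    "degA\tdeg\t-\tA\n",
    "\n[contingencies]\ntarget\ttype\teffector\n",
    "<either>\tOR\tA_[(r)]-{P};A_[(r)]-{0}\n",
    "degA\t!\t<either>\n"))
  expect_setequal(grep("^degA", names(net$reactions), value = TRUE),
                  c("degA@1", "degA@2"))
  gates <- vapply(Filter(function(ct) grepl("^degA", ct$target),
                         net$contingencies),
                  function(ct) bx_deparse(ct$effector), "")
  expect_setequal(gates, c("A_[(r)]-{P}", "A_[(r)]-{0}"))
})

test_that("validation reports diagnostics without raising", {
  expect_length(validate_network(modification_motif()), 0L)
  expect_length(validate_network(interaction_motif()), 0L)
  expect_length(validate_network(hog_model()), 0L)

  net <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "\n[contingencies]\ntarget\ttype\teffector\n",
    "nosuch\t!\tA_[(r)]-{P}\n"))
  diags <- validate_network(net)
  expect_length(diags, 1L)
  expect_match(diags, "undeclared reaction 'nosuch'")

  # a doubly-modified state producible only from a non-neutral state,
  # in a system where the neutral state is synthesised
  net2 <- parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\teffects\n",
    "mk\tsyn\t-\tA\t\n",
    "kin\tp+\tK\tA_[(r)]\t\n",
    "kin2\texplicit\t-\t-\t",
    "consumption:A_[(r)]-{P};production:A_[(r)]-{PP}\n"))
  expect_match(validate_network(net2), "synthesis-path depth", all = FALSE)
})

test_that("contingency effectors must reference declared states", {
  expect_error(parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "\n[contingencies]\ntarget\ttype\teffector\n",
    "kin\t!\tB_[(z)]-{P}\n")),
    "undeclared state")
})

test_that("parsed networks survive a serialise/parse round trip", {
  for (net in list(modification_motif(TRUE, FALSE, TRUE, FALSE),
                   interaction_motif(FALSE, TRUE, TRUE, TRUE),
                   hog_model(TRUE))) {
    net2 <- parse_rxncon(serialise_rxncon(net))
    expect_identical(names(net2$states), names(net$states))
    expect_identical(names(net2$reactions), names(net$reactions))
    expect_identical(lapply(net2$reactions, function(r) r$effects),
                     lapply(net$reactions, function(r) r$effects))
    expect_identical(net2$clamps, net$clamps)
    expect_identical(length(net2$contingencies), length(net$contingencies))
  }
})

test_that("cyclic Boolean-node definitions are rejected", {
  expect_error(parse_rxncon(paste0(
    "[reactions]\nid\ttype\tsubject\tobject\n",
    "kin\tp+\tK\tA_[(r)]\n",
    "\n[contingencies]\ntarget\ttype\teffector\n",
    "<a>\tAND\t<b>;A_[(r)]-{P}\n",
    "<b>\tOR\t<a>;A_[(r)]-{0}\n",
    "kin\t!\t<a>\n")),
    "cyclic Boolean-node definition")
})
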