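test_that("the published root-SCN equations parse into nine single-bodied rules", {
  g <- root_scn()
  expect_s3_class(g, "grn")
  expect_identical(g$genes, sort(c(
    "PLT", "AUXINS", "IAA", "ARF", "SHR",
    "SCR", "JKD", "MGP", "WOX"
  ), method = "radix"))
  expect_true(all(vapply(g$rules, function(r) r$type == "equations", logical(1))))
  expect_true(all(vapply(g$rules, function(r) length(r$bodies) == 1L, logical(1))))
})

test_that("duplicate left-hand sides merge into a multi-body rule", {
  g <- parse_equations("A := B; A := ~B; B := A;")
  expect_length(g$rules$A$bodies, 2L)
  # the two bodies disagree at every state, so A is indeterminate everywhere
  for (s in 0:3) {
    expect_identical(allowed_next_values(g, s, "A"), c(0L, 1L))
  }
  expect_false(is_deterministic(g))
})

test_that("identity and constant-persistence rules behave as written", {
  g <- parse_equations("A := A;")
  expect_identical(allowed_next_values(g, 0, "A"), 0L)
  expect_identical(allowed_next_values(g, 1, "A"), 1L)
  expect_true(is_deterministic(g))
})

test_that("equation parser reports undeclared genes and syntax errors with position", {
  expect_error(parse_equations("A := B;"), "unknown gene 'B'")
  expect_error(parse_equations("A := ;"), "line 1")
  expect_error(parse_equations("A := B &\n& C;"), "line 2")
  expect_error(parse_equations(""), "empty")
  expect_error(parse_equations("// only a comment\n"), "empty")
})

test_that("the ': =' spelling used in the published listing is accepted", {
  g1 <- parse_equations("A: = A;")
  g2 <- parse_equations("A := A;")
  expect_identical(g1$rules$A$bodies, g2$rules$A$bodies)
})

test_that("table dialect parses the starred SCR table and resolves stars to both values", {
  g <- root_scn("root_scn_scr_star.tables")
  # the starred row: SHR=1, SCR=1, JKD=0, MGP=1
  st <- c(
    ARF = 0, AUXINS = 0, IAA = 0, JKD = 0, MGP = 1, PLT = 0, SCR = 1,
    SHR = 1, WOX = 0
  )
  expect_identical(allowed_next_values(g, st, "SCR"), c(0L, 1L))
  # a determinate row: all regulators on
  st2 <- st
  st2[["JKD"]] <- 1
  expect_identical(allowed_next_values(g, st2, "SCR"), 1L)
})

test_that("a zero-regulator table gives a constant rule", {
  g <- parse_tables("table A :\n: 1\n")
  expect_identical(allowed_next_values(g, 0, "A"), 1L)
  expect_identical(allowed_next_values(g, 1, "A"), 1L)
})

test_that("the SCR table with star resolved to 0 equals the published expression", {
  star0 <- root_scn("root_scn_scr_star0.eq")
  printed <- root_scn()
  star <- root_scn("root_scn_scr_star.tables")
  # pointwise over all 512 states, vectorised
  scr_allow <- function(g) {
    grnctl:::gene_allow(g, "SCR", grnctl:::all_state_values(g))
  }
  a_star0 <- scr_allow(star0)
  a_eq <- scr_allow(printed)
  a_star <- scr_allow(star)
  expect_identical(a_star0, a_eq)
  # star-to-0: wherever the printed equation allows a value, the starred
  # table allows it too (the star only widens)
  expect_true(all(!a_eq$a1 | a_star$a1))
  expect_true(all(!a_eq$a0 | a_star$a0))
})

test_that("table parser rejects malformed tables", {
  expect_error(parse_tables("table A : B\n0 : 1\n1 : 0\n"), "unknown gene 'B'")
  expect_error(
    parse_tables("table A : A\n0 : 1\n"),
    "missing rows"
  )
  expect_error(
    parse_tables("table A : A\n0 : 1\n0 : 0\n"),
    "duplicated table row"
  )
  expect_error(
    parse_tables("table A : A\n0 : 1\n1 : 2\n"),
    "expected a table row"
  )
})

test_that("perturbation clamps a rule everywhere and the last clamp wins", {
  g <- root_scn()
  ko <- perturb(g, "JKD", 0)
  for (s in c(0, 137, 255, 511)) {
    expect_identical(allowed_next_values(ko, s, "JKD"), 0L)
  }
  both <- perturb(perturb(g, "PLT", 1), "PLT", 0)
  expect_identical(allowed_next_values(both, 511, "PLT"), 0L)
  expect_error(perturb(g, "FAS", 1), "unknown gene")
})

test_that("SHR loss of function leaves one Auxin-active stable state (all downstream off)", {
  m <- grn_model(perturb(root_scn(), "SHR", 0), "asynchronous")
  td <- tidy(steady_states(m))
  active <- td[td$AUXINS == 1 & td$stability == "stable", ]
  expect_identical(nrow(active), 1L)
  # the CEpI-like profile: auxin pathway on, everything SHR-dependent off
  expect_identical(
    unlist(active[1, c("PLT", "ARF", "IAA", "SHR", "SCR", "JKD", "MGP", "WOX")]),
    c(PLT = 1L, ARF = 1L, IAA = 0L, SHR = 0L, SCR = 0L, JKD = 0L, MGP = 0L, WOX = 0L)
  )
})

test_that("serialization round-trips preserve the rule function pointwise", {
  nets <- list(
    root_scn(),
    root_scn("root_scn_scr_star.tables"),
    parse_equations("A := B; A := ~B; B := A;"),
    perturb(parse_equations("A := A; B := A;"), "B", 1),
    random_grn(4, k = 2, star_prob = 0.3, seed = 11)
  )
  # pointwise allowed-value comparison, vectorised over all 2^n states
  allow_table <- function(g) {
    values <- grnctl:::all_state_values(g)
    lapply(stats::setNames(g$genes, g$genes), function(gene) {
      grnctl:::gene_allow(g, gene, values)
    })
  }
  same_rule_function <- function(g1, g2) {
    expect_identical(g1$genes, g2$genes)
    expect_identical(allow_table(g1), allow_table(g2))
  }
  for (g in nets) {
    same_rule_function(g, parse_equations(as_equations_text(g)))
    same_rule_function(g, parse_tables(as_tables_text(g)))
  }
})

test_that("determinism detection matches per-state allowed-value counts", {
  for (seed in 1:5) {
    g <- random_grn(4, k = 2, star_prob = ifelse(seed %% 2 == 0, 0, 0.3), seed = seed)
    singleton_everywhere <- all(vapply(0:15, function(s) {
      all(vapply(g$genes, function(gene) {
        length(allowed_next_values(g, s, gene)) == 1L
      }, logical(1)))
    }, logical(1)))
    expect_identical(is_deterministic(g), singleton_everywhere)
  }
})

test_that("JSON export carries genes and rules in both forms", {
  js <- jsonlite::fromJSON(grn_to_json(root_scn("root_scn_scr_star.tables")),
    simplifyVector = FALSE
  )
  expect_named(js, c("genes", "rules"))
  expect_length(js$rules, 9L)
  scr <- js$rules[[which(vapply(js$rules, `[[`, "", "target") == "SCR")]]
  expect_identical(scr$regulators, list("SHR", "SCR", "JKD", "MGP"))
  expect_identical(sum(unlist(scr$outputs) == "*"), 1L)
})
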