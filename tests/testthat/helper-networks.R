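# Shared fixtures: published root stem-cell-niche model, toy networks, and
# the formula battery used by the differential tests.

root_scn_path <- function(file = "root_scn.eq") {
  system.file("extdata", file, package = "grnctl")
}

root_scn <- function(file = "root_scn.eq") {
  read_grn(root_scn_path(file))
}

# expected expression profiles of the four Auxin-active stable states
# (cell types of the root stem-cell niche)
root_scn_profiles <- function() {
  tibble::tribble(
    ~cell_type, ~PLT, ~AUXINS, ~ARF, ~IAA, ~SHR, ~SCR, ~JKD, ~MGP, ~WOX,
    "QC", 1, 1, 1, 0, 1, 1, 1, 0, 1,
    "vascular", 1, 1, 1, 0, 1, 0, 0, 0, 0,
    "CEI", 1, 1, 1, 0, 1, 1, 1, 1, 0,
    "CEpI", 1, 1, 1, 0, 0, 0, 0, 0, 0
  )
}

root_scn_profile_indices <- function(grn) {
  prof <- root_scn_profiles()
  vapply(seq_len(nrow(prof)), function(i) {
    state_index(grn, unlist(prof[i, grn$genes]))
  }, numeric(1))
}

toy_swap <- function() parse_equations("A := B; B := A;") # two 2-cycles (sync)
toy_negate <- function() parse_equations("A := ~A;") # one 2-cycle
toy_copy <- function() parse_equations("A := A; B := A;") # fixed points only
toy_flip_flop <- function() parse_equations("A := A; A := ~A;") # all-star 1 gene
toy_three_cycle <- function() parse_equations("A := C; B := A; C := B;")

members <- function(set) as.numeric(sort(grnctl:::ss_members(set)))

set_equal <- function(set, indices) {
  identical(members(set), as.numeric(sort(indices)))
}

# formula battery: every operator, state literals, and downarrow nesting to
# depth two (gene names as in random_grn(): g01, g02, ...)
formula_battery <- function(n_genes) {
  g1 <- "g01"
  g2 <- sprintf("g%02d", min(2, n_genes))
  g3 <- sprintf("g%02d", min(3, n_genes))
  k <- 2^n_genes - 1
  c(
    "true", "false",
    g1,
    paste0("not ", g1),
    paste0(g1, " and ", g2),
    paste0(g1, " or not ", g2),
    paste0(g1, " implies ", g2),
    "#0", paste0("EF #", k),
    paste0("EX ", g1),
    paste0("AX (", g1, " or ", g2, ")"),
    paste0("EF (", g1, " and ", g2, ")"),
    paste0("AF ", g1),
    paste0("EG ", g1),
    paste0("AG (", g1, " or ", g2, ")"),
    paste0("E[", g1, " U ", g2, "]"),
    paste0("A[", g1, " U ", g2, "]"),
    paste0("EY ", g1),
    paste0("EX EY ", g3),
    paste0("AG (", g1, " implies EF ", g2, ")"),
    "down s . EX s",
    "down s . AX s",
    "down s . EX EF s",
    "down s . EX ((not s) and EX s)",
    "down s . EX down t . EY (s and EX (not t))",
    paste0("down s . EF ((not s) and ", g1, ")"),
    paste0("down s . EX down t . EY (t and s and ", g1, ")")
  )
}

random_model_pair <- function(n, k, star_prob, seed, mode) {
  g <- random_grn(n, k = k, star_prob = star_prob, seed = seed)
  list(
    grn = g,
    bdd = grn_model(g, mode, "bdd"),
    digraph = oracle_digraph(g, mode)
  )
}
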