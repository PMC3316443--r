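#' Random Boolean networks with indeterminations
#'
#' Generates a network of `n_genes` genes, each regulated by `k` regulators
#' drawn uniformly without replacement (self-regulation allowed), with a
#' uniformly random truth-table output column in which each row is
#' independently replaced by a star (indetermination) with probability
#' `star_prob`. With a fixed `seed` the result is reproducible;
#' `random_net_text()` is byte-identical for a fixed seed.
#'
#' @param n_genes Number of genes (`>= 1`).
#' @param k Regulators per gene (`0 <= k <= n_genes`).
#' @param star_prob Per-row probability of an indeterminate output.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return `random_grn()`: a [grn]; `random_net_text()`: table-dialect
#'   source text.
#' @export
random_grn <- function(n_genes, k = 2, star_prob = 0, seed = NULL) {
  stopifnot(n_genes >= 1, k >= 0, k <= n_genes, star_prob >= 0, star_prob <= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  genes <- sprintf("g%02d", seq_len(n_genes))
  rules <- lapply(genes, function(g) {
    regs <- sort(sample(genes, k), method = "radix")
    nrows <- 2L^k
    outputs <- sample(c(0L, 1L), nrows, replace = TRUE)
    starred <- stats::runif(nrows) < star_prob
    outputs[starred] <- 2L
    list(type = "table", regulators = regs, outputs = outputs)
  })
  names(rules) <- genes
  new_grn(rules)
}

#' @rdname random_grn
#' @export
random_net_text <- function(n_genes, k = 2, star_prob = 0, seed = NULL) {
  as_tables_text(random_grn(n_genes, k, star_prob, seed))
}
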