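#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a query result
#'
#' One row per enumerated satisfying state: `state_index` plus one 0/1
#' column per gene, in canonical gene order.
#'
#' @param x A `grn_query`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.grn_query <- function(x, ...) {
  x$states
}

#' @rdname tidy.grn_query
#' @export
glance.grn_query <- function(x, ...) {
  tibble::tibble(
    query = x$query, formula = x$formula, mode = x$mode,
    backend = x$backend, count = x$count, n_genes = x$n,
    n_states = 2^x$n, model_hash = x$model_hash
  )
}

#' Tidy a steady-state report
#'
#' One row per steady state with a `stability` column (`"stable"` or
#' `"unstable"`).
#'
#' @param x A `steady_state_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.steady_state_report <- function(x, ...) {
  stable <- state_tibble(x$genes, ss_members(x$stable))
  unstable <- state_tibble(x$genes, ss_members(x$unstable))
  dplyr::bind_rows(
    dplyr::mutate(stable, stability = "stable"),
    dplyr::mutate(unstable, stability = "unstable")
  )
}

#' @rdname tidy.steady_state_report
#' @export
glance.steady_state_report <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_genes = x$n, n_states = 2^x$n,
    n_stable = ss_size(x$stable), n_unstable = ss_size(x$unstable)
  )
}

query_profile_plot <- function(states, genes, fill_lab = "active") {
  long <- tidyr::pivot_longer(states,
    cols = dplyr::all_of(genes),
    names_to = "gene", values_to = "value"
  )
  long$gene <- factor(long$gene, levels = genes)
  long$state <- factor(long$state_index, levels = sort(unique(long$state_index)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$state,
    fill = factor(.data$value)
  )) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = c("0" = "grey95", "1" = "#2c7fb8"),
      name = fill_lab
    ) +
    ggplot2::labs(x = NULL, y = "state index") +
    ggplot2::theme_minimal()
}

#' Plot the gene-activation profiles of a query result
#'
#' A tile map with one row per satisfying state and one column per gene.
#'
#' @param object A `grn_query` or `steady_state_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_query <- function(object, ...) {
  query_profile_plot(object$states, object$genes) +
    ggplot2::ggtitle(object$query)
}

#' @rdname autoplot.grn_query
#' @export
autoplot.steady_state_report <- function(object, ...) {
  td <- tidy(object)
  if (nrow(td) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::theme_void() +
      ggplot2::ggtitle("no steady states"))
  }
  query_profile_plot(td, object$genes) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stability),
      scales = "free_y", space = "free_y"
    ) +
    ggplot2::ggtitle(paste0("steady states (", object$mode, " mode)"))
}

#' Plot the state-transition graph
#'
#' Draws the full transition graph of a (small) model, with attractor-cycle
#' states highlighted. Intended for models of up to about ten genes.
#'
#' @param model A [grn_model()].
#' @param highlight Optional `state_set` or `grn_query` to highlight
#'   (defaults to the cycle states of [attractor_states()]).
#' @return A ggplot object.
#' @export
plot_state_graph <- function(model, highlight = NULL) {
  if (model$n > 10) {
    stop("state graph plotting is limited to 10 genes (", 2^model$n,
      " states)",
      call. = FALSE
    )
  }
  ed <- relation_edges(model$relation)
  g <- igraph::graph_from_edgelist(cbind(ed$from + 1, ed$to + 1), directed = TRUE)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    state_index = seq_len(nrow(lay)) - 1,
    x = lay[, 1], y = lay[, 2]
  )
  hl <- if (is.null(highlight)) attractor_states(model)$set else as_target_set(model, highlight)
  nodes$highlighted <- vapply(nodes$state_index, function(s) ss_contains(hl, s), logical(1))
  edges <- tibble::tibble(
    x = nodes$x[ed$from + 1], y = nodes$y[ed$from + 1],
    xend = nodes$x[ed$to + 1], yend = nodes$y[ed$to + 1]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70",
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$highlighted),
      size = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "#d95f02"),
      name = "on attractor"
    ) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(paste0(
      "state-transition graph (", model$mode, " mode, ",
      2^model$n, " states)"
    ))
}

#' @importFrom rlang .data
NULL
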