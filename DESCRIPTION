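Package: grnctl
Title: Branching-Time Model Checking for Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A set-returning model checker for Boolean gene regulatory
    networks with indeterminations (non-deterministic rule outputs).
    Networks are read from equation or truth-table files, turned into a
    total state-transition relation under synchronous or asynchronous
    update semantics, and queried with Computation-Tree Logic extended
    with hybrid-logic state variables (the downarrow binder), the past
    operator EY, and numeric state literals. Queries return the full set
    of satisfying states, supporting steady-state, attractor,
    basin-of-attraction and perturbation analyses. Includes a symbolic
    binary-decision-diagram backend, an explicit-state backend, an
    independent brute-force oracle for differential testing, a random
    network generator, canned biological query recipes, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
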