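#' Build an analysis object from reported coefficients
#'
#' Constructs a `falcon_analysis` directly from previously reported
#' three-model coefficients (with their p-values, coefficient-change
#' p-values and within-pair predictor correlations), bypassing model
#' fitting. This reproduces decompositions and conclusions from printed
#' coefficient tables, e.g. when auditing a published MZ-twin analysis of
#' mammogram risk scores.
#'
#' @param predictor,outcome Trait names.
#' @param forward,reverse Named lists with `beta_self`, `beta_cotwin`,
#'   `beta_self_prime`, `beta_cotwin_prime`, `rho`, and optionally
#'   `p_beta_self`, `p_beta_cotwin`, `p_beta_self_prime`,
#'   `p_beta_cotwin_prime`, `change_p_self`, `change_p_cotwin`,
#'   `se_beta_self`, ... (same naming).
#' @param alpha,similar_tol Decision-rule parameters.
#' @param adjust_for Optional label recording a third-score adjustment.
#' @return A `falcon_analysis`.
#' @export
analysis_from_coefficients <- function(predictor, outcome, forward, reverse,
                                       alpha = 0.05, similar_tol = 0.25,
                                       adjust_for = NULL) {
  build_dir <- function(cf, pred, out) {
    terms <- c("beta_self", "beta_cotwin", "beta_self_prime",
               "beta_cotwin_prime")
    pick <- function(prefix) {
      v <- vapply(terms, function(tm) {
        as.numeric(cf[[paste0(prefix, tm)]] %||% NA_real_)
      }, numeric(1))
      names(v) <- terms
      v
    }
    triplet <- falcon_triplet(
      cf$beta_self, cf$beta_cotwin, cf$beta_self_prime,
      cf$beta_cotwin_prime, se = pick("se_"), p = pick("p_"))
    dec <- decompose(triplet, rho = cf$rho,
                     change_p_self = as.numeric(cf$change_p_self %||% NA),
                     change_p_cotwin = as.numeric(cf$change_p_cotwin %||% NA))
    list(predictor = pred, outcome = out, triplet = triplet,
         bootstrap = NULL, rho = cf$rho, decomposition = dec)
  }
  fwd <- build_dir(forward, predictor, outcome)
  rev <- build_dir(reverse, outcome, predictor)
  conclusions <- infer_conclusion(fwd, rev, alpha = alpha,
                                  similar_tol = similar_tol)
  structure(
    list(predictor = predictor, outcome = outcome, adjust_for = adjust_for,
         forward = fwd, reverse = rev, conclusions = conclusions,
         summary = attr(conclusions, "summary"), alpha = alpha,
         similar_tol = similar_tol, B = NA_integer_, seed = NA_integer_,
         n_pairs = NA_integer_),
    class = "falcon_analysis"
  )
}

#' Summary causal graph from a set of analyses
#'
#' Collects every analysis direction labelled `causation` or `combination`
#' into a weighted directed graph: one edge per causal direction, weighted
#' by the causal effect size and annotated with the causal fraction and the
#' familial-confounding fraction. Familial-confounding relationships are
#' deliberately not drawn; the graph metadata records this.
#'
#' @param analyses A `falcon_analysis` or list of them.
#' @return A `falcon_graph`: list with `nodes` (character), `edges`
#'   (tibble `from`, `to`, `causal_effect`, `pr`, `confounding_fraction`)
#'   and `metadata`.
#' @export
export_graph <- function(analyses) {
  if (inherits(analyses, "falcon_analysis")) analyses <- list(analyses)
  nodes <- character(0)
  edges <- list()
  for (an in analyses) {
    nodes <- union(nodes, c(an$predictor, an$outcome))
    for (nm in c("forward", "reverse")) {
      lab <- an$conclusions$label[an$conclusions$direction == nm]
      if (lab %in% c("causation", "combination")) {
        d <- an[[nm]]
        edges[[length(edges) + 1]] <- tibble::tibble(
          from = d$predictor, to = d$outcome,
          causal_effect = d$decomposition$causal_effect,
          pr = d$decomposition$pr,
          confounding_fraction = d$decomposition$confounding_fraction,
          label = lab
        )
      }
    }
  }
  if (length(edges) == 0) {
    warn("no direction labelled causation/combination; graph is empty")
    edges <- tibble::tibble(from = character(0), to = character(0),
                            causal_effect = numeric(0), pr = numeric(0),
                            confounding_fraction = numeric(0),
                            label = character(0))
  } else {
    edges <- dplyr::bind_rows(edges)
  }
  structure(
    list(nodes = sort(nodes), edges = edges,
         metadata = list(
           note = paste("familial confounding between score pairs is",
                        "omitted from the diagram"),
           weight = "causal_effect")),
    class = "falcon_graph"
  )
}

#' @export
print.falcon_graph <- function(x, ...) {
  cat("<falcon_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " causal edge(s)\n", sep = "")
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' Serialise a causal graph
#'
#' `graph_to_dot()` renders Graphviz DOT with edge thickness proportional
#' to the causal effect size; `write_graph_json()`/`graph_from_json()`
#' serialise the graph losslessly to JSON, so DOT rendered from the JSON
#' round trip is identical to DOT rendered from the original.
#'
#' @param graph A [export_graph()] result.
#' @param path Output file.
#' @return `graph_to_dot()` returns a character vector of DOT lines;
#'   the writers return `path` invisibly.
#' @export
graph_to_dot <- function(graph) {
  lines <- c("digraph falcon {", "  rankdir=LR;")
  lines <- c(lines, sprintf("  \"%s\";", graph$nodes))
  if (nrow(graph$edges) > 0) {
    e <- graph$edges
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [penwidth=%.2f, label=\"Pr %.0f%%, effect %.3f\"];",
      e$from, e$to, 0.5 + 6 * abs(e$causal_effect), 100 * e$pr,
      e$causal_effect))
  }
  c(lines, "}")
}

#' @rdname graph_to_dot
#' @export
write_graph_dot <- function(graph, path) {
  writeLines(graph_to_dot(graph), path)
  invisible(path)
}

#' @rdname graph_to_dot
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges,
         metadata = graph$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname graph_to_dot
#' @export
graph_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- tibble::as_tibble(x$edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(0), to = character(0),
                            causal_effect = numeric(0), pr = numeric(0),
                            confounding_fraction = numeric(0),
                            label = character(0))
  }
  structure(list(nodes = x$nodes, edges = edges, metadata = x$metadata),
            class = "falcon_graph")
}

#' Causal-graph plot
#'
#' Circular-layout rendering of a [export_graph()] result with arrow width
#' proportional to the causal effect size.
#'
#' @param object A `falcon_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.falcon_graph <- function(object, ...) {
  n <- length(object$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble::tibble(node = object$nodes, x = cos(th), y = sin(th))
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$node)) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::theme_void()
  if (nrow(object$edges) > 0) {
    e <- dplyr::left_join(object$edges, layout, by = c(from = "node"))
    e <- dplyr::left_join(e, layout, by = c(to = "node"),
                          suffix = c("", "_to"))
    shrink <- 0.12
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(
        x = .data$x + shrink * (.data$x_to - .data$x),
        y = .data$y + shrink * (.data$y_to - .data$y),
        xend = .data$x_to - shrink * (.data$x_to - .data$x),
        yend = .data$y_to - shrink * (.data$y_to - .data$y),
        linewidth = abs(.data$causal_effect)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in")),
      colour = "steelblue", alpha = 0.8, show.legend = FALSE)
  }
  p
}

#' Read a pipeline run configuration
#'
#' Parses a YAML or JSON run configuration with fields: `input` (either
#' `csv:` path or `simulate:` sim-config fields), `traits`, optional
#' `transforms` (per-trait `shift`/`lambda` forcing the normalising
#' transform), `covariates`, `analyses` (list of
#' `predictor`/`outcome`/`adjust_for`, or `coefficients:` with
#' `forward:`/`reverse:` reported coefficient sets), `B`, `alpha`, `seed`.
#'
#' @param path Configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate/read, risk-score construction, the correlation
#' table, and every configured ICE FALCON analysis, then writes a report
#' bundle: `correlations.tsv`, one Table-style TSV per analysis,
#' `decompositions.json`, the causal graph as DOT and JSON, and a run log
#' recording seeds, bootstrap size, dropped pairs and package versions.
#' Rerunning with the same configuration and seed reproduces every numeric
#' output byte for byte.
#'
#' @param config A list (see [read_run_config()]) or a path to a YAML/JSON
#'   configuration file.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a list with `data`, `scores`, `correlations`,
#'   `analyses` (named list of `falcon_analysis`), and `graph`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  log_lines <- c("icefalcon pipeline run",
                 paste0("seed: ", seed),
                 paste0("icefalcon version: ",
                        as.character(packageVersion("icefalcon"))),
                 paste0("R version: ", R.version$major, ".",
                        R.version$minor))

  data <- NULL
  scores <- NULL
  correlations <- NULL
  traits <- config$traits
  fitted <- vapply(config$analyses %||% list(),
                   function(a) is.null(a$coefficients), logical(1))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  if (any(fitted) || !is.null(config$input)) {
    data <- stage("input", {
      if (!is.null(config$input$csv)) {
        read_pairs(config$input$csv)
      } else if (!is.null(config$input$simulate)) {
        simulate_pairs(as_sim_config(config$input$simulate), seed = seed)
      } else {
        abort("config$input must provide 'csv' or 'simulate'")
      }
    })
    traits <- traits %||% setdiff(names(data),
                                  c("pair_id", "twin_index", "age",
                                    "stratifier"))
    transforms <- config$transforms
    if (!is.null(transforms) && !identical(transforms, "identity")) {
      transforms <- purrr::imap(transforms, function(tr, nm) {
        transform_spec(nm, shift = tr$shift %||% 0,
                       lambda = tr$lambda %||% 1)
      })
    }
    n_raw <- length(unique(data$pair_id))
    scores <- stage("risk_scores", {
      risk_scores(data, traits, covariates = config$covariates %||% "age",
                  transforms = transforms)
    })
    n_used <- length(unique(scores$pair_id))
    log_lines <- c(log_lines,
                   paste0("pairs read: ", n_raw),
                   paste0("pairs analysed (complete): ", n_used),
                   paste0("pairs dropped: ", n_raw - n_used))
    correlations <- stage("correlations", twin_correlations(scores, traits))
  }

  analyses <- list()
  for (i in seq_along(config$analyses %||% list())) {
    a <- config$analyses[[i]]
    nm <- paste0(a$predictor, "_vs_", a$outcome,
                 if (!is.null(a$adjust_for)) paste0("_adj_", a$adjust_for))
    analyses[[nm]] <- stage(paste0("analysis ", nm), {
      if (!is.null(a$coefficients)) {
        analysis_from_coefficients(
          a$predictor, a$outcome,
          forward = a$coefficients$forward,
          reverse = a$coefficients$reverse,
          alpha = config$alpha %||% 0.05,
          adjust_for = a$adjust_for)
      } else {
        run_pair_analysis(
          scores, a$predictor, a$outcome, adjust_for = a$adjust_for,
          B = config$B %||% 1000, seed = seed + i,
          alpha = config$alpha %||% 0.05)
      }
    })
    rho_src <- if (is.null(a$adjust_for)) {
      "age-adjusted predictor score"
    } else {
      paste0("predictor score adjusted for age and ", a$adjust_for)
    }
    log_lines <- c(log_lines, paste0(
      "analysis ", nm, ": B = ", analyses[[nm]]$B,
      ", seed = ", analyses[[nm]]$seed,
      ", rho computed on ", rho_src))
  }
  graph <- if (length(analyses) > 0) export_graph(analyses) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(correlations)) {
      write_correlations(correlations, file.path(out_dir,
                                                 "correlations.tsv"))
    }
    for (nm in names(analyses)) {
      utils::write.table(
        format_falcon_table(analyses[[nm]]),
        file.path(out_dir, paste0("analysis_", nm, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    decs <- purrr::map(analyses, function(an) {
      list(forward = as.list(an$forward$decomposition),
           reverse = as.list(an$reverse$decomposition),
           summary = an$summary)
    })
    jsonlite::write_json(decs, file.path(out_dir, "decompositions.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(graph)) {
      write_graph_dot(graph, file.path(out_dir, "graph.dot"))
      write_graph_json(graph, file.path(out_dir, "graph.json"))
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(data = data, scores = scores, correlations = correlations,
                 analyses = analyses, graph = graph, log = log_lines))
}
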