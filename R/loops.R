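# Causal-loop-diagram analysis.
#
# A causal loop diagram is a signed influence digraph: link sign +1 means the
# target moves in the same direction as the source, -1 the opposite.  A
# feedback loop is an elementary circuit; its polarity is the product of its
# link signs: reinforcing (+1, amplifying) or balancing (-1, counteracting).

#' Construct a signed influence digraph
#'
#' @param nodes Character vector of variable names.
#' @param links Data frame with columns `source`, `target`, `sign` (+1/-1).
#'   At most one link per ordered pair; self-links are not allowed.
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(nodes, links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(links)))
  links$sign <- as.numeric(links$sign)
  if (nrow(links)) {
    if (!all(links$sign %in% c(-1, 1)))
      stop("link signs must be +1 or -1", call. = FALSE)
    if (any(links$source == links$target))
      stop("self-links are not allowed", call. = FALSE)
    bad <- setdiff(c(links$source, links$target), nodes)
    if (length(bad))
      stop(sprintf("link endpoint(s) not in node set: %s",
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
    key <- paste(links$source, links$target, sep = "\r")
    if (anyDuplicated(key))
      stop("at most one link per ordered (source, target) pair", call. = FALSE)
  }
  structure(list(nodes = as.character(nodes), links = links),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph> %d nodes, %d signed links\n",
              length(x$nodes), nrow(x$links)))
  invisible(x)
}

link_sign <- function(graph, from, to) {
  i <- which(graph$links$source == from & graph$links$target == to)
  if (length(i) == 0L) return(NA_real_)
  graph$links$sign[[i]]
}

#' Polarity of one feedback loop
#'
#' @param cycle Character vector of nodes forming an elementary circuit (the
#'   closing link from the last node back to the first is implicit).
#' @param graph A [causal_graph()] containing every consecutive link.
#' @return `"reinforcing"` if the product of link signs is +1, `"balancing"`
#'   if -1.  Invariant under cyclic rotation of `cycle`.
#' @export
loop_polarity <- function(cycle, graph) {
  stopifnot(inherits(graph, "causal_graph"), length(cycle) >= 1L)
  from <- cycle
  to <- c(cycle[-1L], cycle[[1L]])
  signs <- mapply(function(f, s) link_sign(graph, f, s), from, to)
  if (anyNA(signs)) {
    i <- which(is.na(signs))[[1L]]
    stop(sprintf("no link %s -> %s in graph", from[[i]], to[[i]]), call. = FALSE)
  }
  if (prod(signs) > 0) "reinforcing" else "balancing"
}

canonical_cycle <- function(cycle) {
  i <- which(cycle == min(cycle))[[1L]]
  if (i == 1L) cycle else c(cycle[i:length(cycle)], cycle[seq_len(i - 1L)])
}

#' Enumerate all elementary feedback loops of a signed digraph
#'
#' Johnson-style elementary-circuit enumeration with deterministic ordering:
#' every elementary circuit is returned exactly once, in canonical form
#' (rotated to start at its lexicographically smallest node), with its
#' polarity attached, sorted by canonical form.
#'
#' @param graph A [causal_graph()].
#' @return List of `feedback_loop` objects: `list(cycle=, polarity=, length=)`.
#' @export
enumerate_loops <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  if (n == 0L || nrow(graph$links) == 0L) return(list())
  idx <- stats::setNames(seq_len(n), nodes)
  adj_full <- lapply(seq_len(n), function(i) {
    tg <- graph$links$target[graph$links$source == nodes[[i]]]
    sort(unname(idx[tg]))
  })

  cycles <- list()
  for (s in seq_len(n)) {
    adj <- lapply(adj_full, function(v) v[v >= s])
    if (length(adj[[s]]) == 0L) next
    blocked <- rep(FALSE, n)
    bsets <- lapply(seq_len(n), function(i) integer(0))
    stack <- integer(0)

    unblock <- function(u) {
      blocked[u] <<- FALSE
      while (length(bsets[[u]])) {
        w <- bsets[[u]][[1L]]
        bsets[[u]] <<- bsets[[u]][-1L]
        if (blocked[[w]]) unblock(w)
      }
    }
    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- nodes[stack]
          found <- TRUE
        } else if (!blocked[[w]]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) unblock(v)
      else for (w in adj[[v]]) if (!(v %in% bsets[[w]]))
        bsets[[w]] <<- c(bsets[[w]], v)
      stack <<- stack[-length(stack)]
      found
    }
    circuit(s)
  }

  loops <- lapply(cycles, function(cy) {
    cy <- canonical_cycle(cy)
    structure(list(cycle = cy, polarity = loop_polarity(cy, graph),
                   length = length(cy)),
              class = "feedback_loop")
  })
  keys <- vapply(loops, function(l) paste(l$cycle, collapse = "\x1f"), character(1))
  loops[order(keys)]
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf("<feedback_loop> [%s] %s (length %d)\n",
              paste(x$cycle, collapse = " -> "), x$polarity, x$length))
  invisible(x)
}

#' Audit a graph against an expected feedback-loop inventory
#'
#' Each expected entry names a loop by its node set and polarity.  Nodes in
#' `ignore` (typically flow variables interposed between causal-loop nodes by
#' the stock-flow translation) are collapsed out of every enumerated cycle
#' before node-set comparison; polarity is always the full cycle's sign
#' product, which pass-through chains preserve.
#'
#' @param graph A [causal_graph()].
#' @param expected List of entries `list(name=, nodes=, polarity=)` with
#'   `polarity` in `c("reinforcing", "balancing")`.
#' @param ignore Character vector of pass-through node names.
#' @return Data frame of class `loop_audit` with columns `name`, `status`
#'   (`found-with-matching-polarity`, `found-wrong-polarity`, `absent`),
#'   `expected_polarity`, `found_polarity`; attribute `passed` is `TRUE` iff
#'   all entries match.
#' @export
audit_expected_loops <- function(graph, expected, ignore = character(0)) {
  loops <- enumerate_loops(graph)
  collapsed <- lapply(loops, function(l) sort(setdiff(l$cycle, ignore)))
  res <- lapply(expected, function(e) {
    want <- sort(setdiff(e$nodes, ignore))
    hits <- which(vapply(collapsed, function(cs)
      length(cs) == length(want) && all(cs == want), logical(1)))
    if (length(hits) == 0L)
      return(list(name = e$name, status = "absent",
                  expected_polarity = e$polarity, found_polarity = NA_character_))
    pols <- vapply(loops[hits], `[[`, character(1), "polarity")
    if (e$polarity %in% pols)
      list(name = e$name, status = "found-with-matching-polarity",
           expected_polarity = e$polarity, found_polarity = e$polarity)
    else
      list(name = e$name, status = "found-wrong-polarity",
           expected_polarity = e$polarity, found_polarity = pols[[1L]])
  })
  out <- data.frame(
    name = vapply(res, `[[`, character(1), "name"),
    status = vapply(res, `[[`, character(1), "status"),
    expected_polarity = vapply(res, `[[`, character(1), "expected_polarity"),
    found_polarity = vapply(res, `[[`, character(1), "found_polarity"),
    stringsAsFactors = FALSE
  )
  attr(out, "passed") <- all(out$status == "found-with-matching-polarity")
  class(out) <- c("loop_audit", "data.frame")
  out
}

#' Extract the signed influence digraph of a stock-flow model
#'
#' One signed link per direct dependency: every variable referenced in a
#' flow/auxiliary expression links to the variable it defines (sign read from
#' the per-link annotation in the model specification), and every flow links to its stock(s)
#' with sign + for an inflow and - for an outflow.  Parameters are exogenous
#' converters and do not appear as graph nodes.
#'
#' @param spec A valid [sd_model()] whose flow/auxiliary dependencies on other
#'   model variables all carry sign annotations.
#' @return A [causal_graph()] over the stocks, flows and auxiliaries.
#' @export
extract_causal_graph <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  var_nodes <- c(names(spec$stocks), names(spec$flows), names(spec$auxiliaries))
  src <- character(0); tgt <- character(0); sgn <- numeric(0)
  unannotated <- character(0)
  for (eq in c(spec$flows, spec$auxiliaries)) {
    d <- expr_deps(sd_parse_expr(eq$expression))
    for (v in intersect(d$vars, var_nodes)) {
      s <- eq$signs[[v]]
      if (is.null(s)) {
        unannotated <- c(unannotated, sprintf("%s -> %s", v, eq$name))
      } else {
        src <- c(src, v); tgt <- c(tgt, eq$name); sgn <- c(sgn, s)
      }
    }
  }
  if (length(unannotated))
    stop(sprintf("unannotated dependency link(s), add sign annotations for: %s",
                 paste(unannotated, collapse = "; ")), call. = FALSE)
  for (f in spec$flows) {
    if (f$sink %in% names(spec$stocks)) {
      src <- c(src, f$name); tgt <- c(tgt, f$sink); sgn <- c(sgn, 1)
    }
    if (f$source %in% names(spec$stocks)) {
      src <- c(src, f$name); tgt <- c(tgt, f$source); sgn <- c(sgn, -1)
    }
  }
  causal_graph(var_nodes,
               data.frame(source = src, target = tgt, sign = sgn,
                          stringsAsFactors = FALSE))
}

#' Export a causal graph (and optionally its loops) in DOT format
#'
#' Negative links are labelled "-"; links that lie only on balancing loops are
#' drawn dashed, links on at least one reinforcing loop solid.
#'
#' @param graph A [causal_graph()].
#' @param loops Optional output of [enumerate_loops()] used for edge styling.
#' @param path Optional file to write to.
#' @return The DOT document as a character scalar (invisibly if `path` given).
#' @export
export_dot <- function(graph, loops = NULL, path = NULL) {
  edge_key <- function(f, t) paste(f, t, sep = "\r")
  on_reinf <- character(0); on_bal <- character(0)
  for (l in if (is.null(loops)) list() else loops) {
    ks <- edge_key(l$cycle, c(l$cycle[-1L], l$cycle[[1L]]))
    if (l$polarity == "reinforcing") on_reinf <- c(on_reinf, ks)
    else on_bal <- c(on_bal, ks)
  }
  lines <- c("digraph causal_loop_diagram {", "  rankdir=LR;")
  for (nd in sort(graph$nodes))
    lines <- c(lines, sprintf("  \"%s\";", nd))
  ord <- order(graph$links$source, graph$links$target)
  for (i in ord) {
    f <- graph$links$source[[i]]; t <- graph$links$target[[i]]
    k <- edge_key(f, t)
    style <- if (k %in% on_bal && !(k %in% on_reinf)) ", style=dashed" else ""
    lab <- if (graph$links$sign[[i]] < 0) "label=\"-\"" else "label=\"+\""
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [%s%s];", f, t, lab, style))
  }
  lines <- c(lines, "}")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Write a feedback-loop report as JSON
#'
#' @param loops Output of [enumerate_loops()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_loops_json <- function(loops, path) {
  doc <- lapply(loops, function(l)
    list(cycle = l$cycle, polarity = l$polarity, length = l$length))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
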